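#' Lipid species
#'
#' A `lipid_species` describes a lipid at the shorthand level used in
#' LC-MS lipidomics: a class label (e.g. PC, TAG, Cer), the total number
#' of acyl-chain carbons `n` and double bonds `d`, and optionally the
#' per-chain composition. sn-positions, double-bond positions and
#' cis/trans geometry are deliberately not encoded: they are not evident
#' from mobility-resolved MS/MS data at this level.
#'
#' Supported classes and their category:
#' * GL (glycerolipids): MAG, DAG, TAG
#' * GP (glycerophospholipids): PC, PE, PA, PS, PI, PG, LPC (plus
#'   oxidised variants via `ox`)
#' * SP (sphingolipids): Cer, SM, HexCer (sphingoid base counted in
#'   `carbons`/`doublebonds`; d-type base with two hydroxyls)
#' * ST (sterols): CE, Chol
#'
#' @param class class label.
#' @param carbons total acyl (or acyl + sphingoid) carbons.
#' @param doublebonds total double bonds.
#' @param chains optional list of `c(carbons, doublebonds)` per chain; for
#'   SP classes the first chain is the sphingoid base. Chain totals must
#'   match `carbons`/`doublebonds`.
#' @param ether `TRUE` for ether/plasmalogen-linked PC/PE (O-/P-
#'   substituents; one ester oxygen replaced by an ether linkage).
#' @param ox number of additional oxygens for oxidised GP classes (0-2).
#' @return object of class `lipid_species`.
#' @examples
#' lipid_species("PC", 32, 1)
#' lipid_species("PG", 32, 2, chains = list(c(16, 1), c(16, 1)))
#' @export
lipid_species <- function(class, carbons, doublebonds, chains = NULL,
                          ether = FALSE, ox = 0) {
  class <- as.character(class)
  if (!class %in% names(.CLASS_TEMPLATES))
    stop("unsupported lipid class: ", class)
  n <- as.integer(carbons); d <- as.integer(doublebonds)
  if (n < 0 || d < 0) stop("carbons and double bonds must be >= 0")
  if (d > n / 2) stop("implausible unsaturation: d > n/2")
  if (!is.null(chains)) {
    cn <- sum(vapply(chains, `[`, numeric(1), 1))
    cd <- sum(vapply(chains, `[`, numeric(1), 2))
    if (cn != n || cd != d)
      stop("chain totals (", cn, ":", cd, ") do not match species totals (",
           n, ":", d, ")")
    k <- .CLASS_TEMPLATES[[class]]$n_chains
    if (!is.na(k) && length(chains) != k)
      stop(class, " requires ", k, " chains")
  }
  if (ether && !class %in% c("PC", "PE", "LPC"))
    stop("ether/plasmalogen variants are only supported for PC, PE, LPC")
  if (ox > 0 && .CLASS_TEMPLATES[[class]]$category != "GP")
    stop("oxidised variants are only supported for GP classes")
  structure(list(class = class,
                 category = .CLASS_TEMPLATES[[class]]$category,
                 carbons = n, doublebonds = d,
                 chains = chains, ether = isTRUE(ether),
                 ox = as.integer(ox)),
            class = "lipid_species")
}

# Formula templates per class as a function of total acyl carbons n and
# double bonds d. Verified against reference compositions (tripalmitin
# C51H98O6, DPPC C40H80NO8P, DPPE C37H74NO8P, ...). SP classes assume a
# d-type (dihydroxy) sphingoid base; its carbons/double bonds are part of
# n and d.
.CLASS_TEMPLATES <- list(
  MAG  = list(category = "GL", n_chains = 1,
              f = function(n, d) chem_formula(C = n + 3, H = 2 * n + 6 - 2 * d, O = 4)),
  DAG  = list(category = "GL", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 3, H = 2 * n + 4 - 2 * d, O = 5)),
  TAG  = list(category = "GL", n_chains = 3,
              f = function(n, d) chem_formula(C = n + 3, H = 2 * n + 2 - 2 * d, O = 6)),
  PC   = list(category = "GP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 8, H = 2 * n + 16 - 2 * d, N = 1, O = 8, P = 1)),
  PE   = list(category = "GP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 5, H = 2 * n + 10 - 2 * d, N = 1, O = 8, P = 1)),
  PA   = list(category = "GP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 3, H = 2 * n + 5 - 2 * d, O = 8, P = 1)),
  PS   = list(category = "GP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 6, H = 2 * n + 10 - 2 * d, N = 1, O = 10, P = 1)),
  PI   = list(category = "GP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 9, H = 2 * n + 15 - 2 * d, O = 13, P = 1)),
  PG   = list(category = "GP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 6, H = 2 * n + 11 - 2 * d, O = 10, P = 1)),
  LPC  = list(category = "GP", n_chains = 1,
              f = function(n, d) chem_formula(C = n + 8, H = 2 * n + 18 - 2 * d, N = 1, O = 7, P = 1)),
  Cer  = list(category = "SP", n_chains = 2,
              f = function(n, d) chem_formula(C = n, H = 2 * n + 1 - 2 * d, N = 1, O = 3)),
  SM   = list(category = "SP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 5, H = 2 * n + 13 - 2 * d, N = 2, O = 6, P = 1)),
  HexCer = list(category = "SP", n_chains = 2,
              f = function(n, d) chem_formula(C = n + 6, H = 2 * n + 11 - 2 * d, N = 1, O = 8)),
  CE   = list(category = "ST", n_chains = 1,
              f = function(n, d) chem_formula(C = n + 27, H = 2 * n + 44 - 2 * d, O = 2)),
  Chol = list(category = "ST", n_chains = 0,
              f = function(n, d) chem_formula(C = 27, H = 46, O = 1))
)

#' Supported lipid classes
#' @return data.frame with columns `class`, `category`, `n_chains`.
#' @export
lipid_classes <- function() {
  data.frame(class = names(.CLASS_TEMPLATES),
             category = vapply(.CLASS_TEMPLATES, `[[`, "", "category"),
             n_chains = vapply(.CLASS_TEMPLATES, function(x)
               as.integer(x$n_chains), integer(1)),
             row.names = NULL)
}

#' Elemental formula of a lipid species
#'
#' Applies the class template (e.g. TAG n:d -> C(n+3) H(2n+2-2d) O6),
#' then the ether correction (-O +2H) and oxidation (+O per `ox`).
#' Deterministic: the same species always yields the same formula.
#'
#' @param species a `lipid_species`.
#' @return a `chem_formula`.
#' @examples
#' format(formula_from_species(lipid_species("TAG", 48, 1)))  # "C51H96O6"
#' @export
formula_from_species <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  tpl <- .CLASS_TEMPLATES[[species$class]]
  f <- tpl$f(species$carbons, species$doublebonds)
  if (species$ether)
    f <- f - chem_formula(O = 1) + chem_formula(H = 2)
  if (species$ox > 0)
    f <- f + chem_formula(O = species$ox)
  f
}

#' Shorthand name of a species
#'
#' Species level: `"PC 32:1"`. Chain level: `"PG 16:1_16:1"`; sphingoid
#' bases are prefixed with `d` (`"Cer d18:1_26:0"`). Ether lipids carry an
#' `O-` prefix on the composition.
#'
#' @param species a `lipid_species`.
#' @param level `"species"` or `"chain"` (chain requires `chains`).
#' @return character name.
#' @export
species_name <- function(species, level = c("species", "chain")) {
  level <- match.arg(level)
  if (species$class == "Chol") return("Chol")
  pre <- if (species$ether) "O-" else ""
  oxs <- if (species$ox > 0) paste0(";O", if (species$ox > 1) species$ox else "") else ""
  if (level == "chain" && !is.null(species$chains)) {
    parts <- vapply(seq_along(species$chains), function(i) {
      ch <- species$chains[[i]]
      base <- if (species$category == "SP" && i == 1) "d" else ""
      paste0(base, ch[1], ":", ch[2])
    }, character(1))
    paste0(species$class, " ", pre, paste(parts, collapse = "_"), oxs)
  } else {
    paste0(species$class, " ", pre, species$carbons, ":",
           species$doublebonds, oxs)
  }
}

#' @export
format.lipid_species <- function(x, ...) {
  species_name(x, if (is.null(x$chains)) "species" else "chain")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format(x), " [", x$category, "]\n", sep = "")
  invisible(x)
}

#' Parse a shorthand lipid name
#'
#' Accepts species-level (`"PC 32:1"`) and chain-level
#' (`"PG 16:1_16:1"`, `"Cer d18:1_26:0"`) names. A trailing `@` on a
#' chain (uncharacterised-chain marker) is accepted and stripped.
#'
#' @param name shorthand string.
#' @return a `lipid_species`.
#' @export
parse_lipid_name <- function(name) {
  name <- trimws(name)
  if (name == "Chol") return(lipid_species("Chol", 0, 0))
  m <- regmatches(name, regexec("^([A-Za-z]+)\\s+(O-)?(.+)$", name))[[1]]
  if (length(m) == 0) stop("cannot parse lipid name: ", name)
  cls <- m[2]; ether <- m[3] == "O-"; comp <- m[4]
  ox <- 0L
  if (grepl(";O", comp, fixed = TRUE)) {
    oxs <- sub("^.*;O", "", comp)
    ox <- if (oxs == "") 1L else as.integer(oxs)
    comp <- sub(";O.*$", "", comp)
  }
  if (grepl("_", comp, fixed = TRUE)) {
    parts <- strsplit(comp, "_", fixed = TRUE)[[1]]
    parts <- sub("@$", "", parts)
    parts <- sub("^d", "", parts)
    chains <- lapply(strsplit(parts, ":", fixed = TRUE), as.integer)
    n <- sum(vapply(chains, `[`, integer(1), 1))
    d <- sum(vapply(chains, `[`, integer(1), 2))
    lipid_species(cls, n, d, chains = chains, ether = ether, ox = ox)
  } else {
    nd <- as.integer(strsplit(comp, ":", fixed = TRUE)[[1]])
    lipid_species(cls, nd[1], nd[2], ether = ether, ox = ox)
  }
}
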