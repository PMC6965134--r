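#' Load the fragment-rule table
#'
#' Rules are shipped as an editable TSV (see
#' `system.file("extdata", "fragment_rules.tsv", package = "timspasef")`)
#' and drive both the MS/MS simulator and the annotation engine. Entries
#' flagged `configurable` (the N''-type glycosphingolipid/ceramide
#' fragments) mark sites intended for user adjustment.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return data.frame of rules.
#' @export
load_fragment_rules <- function(path = system.file(
  "extdata", "fragment_rules.tsv", package = "timspasef")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$adduct[is.na(tab$adduct)] <- ""
  tab$formula[is.na(tab$formula)] <- ""
  tab$required <- tab$required == 1
  tab$configurable <- tab$configurable == 1
  tab
}

.rule_cache <- new.env(parent = emptyenv())

default_fragment_rules <- function() {
  if (is.null(.rule_cache$tab)) .rule_cache$tab <- load_fragment_rules()
  .rule_cache$tab
}

# m/z of a fragment cation/anion given its composition (charge +-1)
.fragment_ion_mz <- function(formula, polarity) {
  z <- if (polarity == "positive") 1 else -1
  monoisotopic_mass(formula) - z * .ELECTRON_MASS
}

# free fatty acid of an acyl chain (c carbons, b double bonds)
.chain_acid_formula <- function(c, b) chem_formula(C = c, H = 2 * c - 2 * b, O = 2)
# carboxylate anion composition RCOO-
.chain_carboxylate_mz <- function(c, b)
  monoisotopic_mass(chem_formula(C = c, H = 2 * c - 1 - 2 * b, O = 2)) +
  .ELECTRON_MASS
# sphingoid [LCB+H-2H2O]+ ion of a d-type base (c carbons, b double bonds)
.sphingoid_ion_mz <- function(c, b)
  monoisotopic_mass(chem_formula(C = c, H = 2 * c - 2 * b, N = 1)) -
  .ELECTRON_MASS

#' Expected fragments of a lipid ion
#'
#' Applies the fragment-rule table to one species/adduct pair and
#' returns the theoretical fragment m/z values: head-group diagnostic
#' ions, fixed neutral losses (relative to the precursor m/z),
#' chain-parameterised fragments (fatty-acid neutral losses in positive
#' mode, carboxylate anions in negative mode) and sphingoid N''-type
#' fragments. Chain-parameterised entries are only produced when the
#' species carries a chain composition.
#'
#' @param species a `lipid_species`.
#' @param adduct adduct name or table row (polarity must match).
#' @param polarity `"positive"` or `"negative"`.
#' @param rules rule table from [load_fragment_rules()].
#' @param adducts adduct table.
#' @return data.frame with columns `mz`, `kind`, `label`, `required`,
#'   `chain` (chain index or `NA`). Zero rows (with a warning) when no
#'   rule covers the class/polarity combination.
#' @examples
#' sp <- lipid_species("PC", 34, 1)
#' expected_fragments(sp, "[M+H]+", "positive")
#' @export
expected_fragments <- function(species, adduct, polarity,
                               rules = default_fragment_rules(),
                               adducts = default_adducts()) {
  stopifnot(inherits(species, "lipid_species"))
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (is.character(adduct)) adduct <- adduct_spec(adduct, adducts)
  if (adduct$polarity != polarity)
    stop("adduct ", adduct$name, " is not a ", polarity, "-mode adduct")
  prec_mz <- mz_of_adduct(formula_from_species(species), adduct)
  sel <- rules$polarity == polarity &
    (rules$scope == paste0("class:", species$class) |
       rules$scope == paste0("category:", species$category)) &
    (rules$adduct == "" | rules$adduct == adduct$name)
  sel <- rules[sel, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("no fragment rules for ", species$class, " in ", polarity,
            " mode")
    return(data.frame(mz = numeric(0), kind = character(0),
                      label = character(0), required = logical(0),
                      chain = integer(0)))
  }
  out <- list()
  for (i in seq_len(nrow(sel))) {
    r <- sel[i, ]
    if (r$kind == "diagnostic") {
      out[[length(out) + 1]] <- data.frame(
        mz = .fragment_ion_mz(r$formula, polarity), kind = r$kind,
        label = r$label, required = r$required, chain = NA_integer_)
    } else if (r$kind == "neutral_loss") {
      out[[length(out) + 1]] <- data.frame(
        mz = prec_mz - monoisotopic_mass(r$formula), kind = r$kind,
        label = r$label, required = r$required, chain = NA_integer_)
    } else if (r$kind %in% c("chain_nl", "chain_carboxylate", "n_type")) {
      if (is.null(species$chains)) next
      idx <- seq_along(species$chains)
      if (r$kind == "n_type") idx <- 1L  # sphingoid base is chain 1
      if (r$kind == "chain_carboxylate" && species$category == "SP")
        idx <- setdiff(idx, 1L)          # carboxylate from the N-acyl chain
      for (j in idx) {
        ch <- species$chains[[j]]
        mzf <- switch(r$kind,
          chain_nl = {
            loss <- monoisotopic_mass(.chain_acid_formula(ch[1], ch[2]))
            if (grepl("NH4", adduct$name, fixed = TRUE))
              loss <- loss + monoisotopic_mass(chem_formula(N = 1, H = 3))
            prec_mz - loss
          },
          chain_carboxylate = .chain_carboxylate_mz(ch[1], ch[2]),
          n_type = .sphingoid_ion_mz(ch[1], ch[2]))
        out[[length(out) + 1]] <- data.frame(
          mz = mzf, kind = r$kind,
          label = paste0(r$label, " ", ch[1], ":", ch[2]),
          required = r$required, chain = j)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(mz = numeric(0), kind = character(0),
                      label = character(0), required = logical(0),
                      chain = integer(0)))
  res <- do.call(rbind, out)
  res[res$mz > 0, , drop = FALSE]
}
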