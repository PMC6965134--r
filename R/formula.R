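#' Elemental formulas
#'
#' A `chem_formula` is a named integer vector of element counts over the
#' elements supported by the package (C, H, N, O, P, S, Na, Cl, K). All
#' counts are non-negative; subtraction that would drive a count negative
#' is an error, so adduct and neutral-loss arithmetic can never produce an
#' impossible composition silently.
#'
#' @param ... element counts, e.g. `chem_formula(C = 51, H = 96, O = 6)`.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula(C = 51, H = 96, O = 6)
#' parse_chem_formula("C51H96O6")
#' @export
chem_formula <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- numeric(0)
  bad <- setdiff(names(counts), .ELEMENTS)
  if (length(bad) > 0)
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  x <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  x[names(counts)] <- as.integer(round(counts))
  structure(x, class = "chem_formula")
}

#' Parse a Hill-style formula string
#'
#' @param s a string such as `"C51H96O6"` or `"C2H8NO4P"`.
#' @return A `chem_formula`.
#' @export
parse_chem_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  s <- gsub("[[:space:]]", "", s)
  if (s == "") return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", s)
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  counts <- tapply(n, el, sum)
  do.call(chem_formula, as.list(counts))
}

#' @export
format.chem_formula <- function(x, ...) {
  ord <- c("C", "H", setdiff(.ELEMENTS, c("C", "H")))
  n <- unclass(x)[ord]
  n <- n[n > 0]
  if (length(n) == 0) return("")
  paste0(names(n), ifelse(n == 1, "", n), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (", round(monoisotopic_mass(x), 5),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  structure(as.integer(unclass(e1) + unclass(e2)) |>
              stats::setNames(.ELEMENTS), class = "chem_formula")
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  out <- unclass(e1) - unclass(e2)
  if (any(out < 0))
    stop("formula subtraction would produce negative count(s): ",
         paste(names(out)[out < 0], collapse = ", "))
  structure(as.integer(out) |> stats::setNames(.ELEMENTS),
            class = "chem_formula")
}

formula_multiply <- function(f, k) {
  stopifnot(k >= 0, k == round(k))
  structure(as.integer(unclass(f) * k) |> stats::setNames(.ELEMENTS),
            class = "chem_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the IUPAC monoisotopic atomic mass.
#'
#' @param formula a `chem_formula` or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C51H96O6")  # 804.72069
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_chem_formula(formula)
  sum(unclass(f) * .ATOMIC_MASS[.ELEMENTS])
}

as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_chem_formula(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a chem_formula")
}

#' Isotope envelope of a formula
#'
#' Aggregated isotope pattern by nominal mass shift (M, M+1, M+2, ...),
#' computed by exact polynomial convolution of the per-element isotope
#' distributions (C, H, N, O, S, Cl, K heavy isotopes). Abundances are
#' normalised to the base (most abundant) peak.
#'
#' @param formula a `chem_formula` or formula string.
#' @param n_peaks number of peaks to return (>= 1).
#' @return data.frame with columns `shift` (nominal), `mass_offset`
#'   (abundance-weighted exact mass offset from the monoisotopic peak, Da)
#'   and `abundance` (base peak = 1).
#' @export
isotope_pattern <- function(formula, n_peaks = 4) {
  stopifnot(n_peaks >= 1)
  f <- as_chem_formula(formula)
  nmax <- as.integer(n_peaks + 2)
  # distribution over nominal shift; track probability and probability-
  # weighted exact mass offset jointly
  p <- c(1, rep(0, nmax))          # P(shift = k)
  pm <- rep(0, nmax + 1)           # E[mass offset ; shift = k] * P
  for (el in .ELEMENTS) {
    cnt <- unclass(f)[[el]]
    if (cnt == 0) next
    iso <- .ISOTOPES[[el]]
    if (nrow(iso) == 1) next
    # single-atom distribution
    ap <- rep(0, nmax + 1)
    am <- rep(0, nmax + 1)
    for (i in seq_len(nrow(iso))) {
      k <- iso$shift[i] + 1
      if (k > nmax + 1) next
      ap[k] <- ap[k] + iso$ab[i]
      am[k] <- am[k] + iso$ab[i] * (iso$mass[i] - iso$mass[1])
    }
    # raise to cnt by repeated convolution (binary exponentiation)
    rp <- c(1, rep(0, nmax)); rm <- rep(0, nmax + 1)
    bp <- ap; bm <- am
    n <- cnt
    conv <- function(pa, ma, pb, mb) {
      np <- rep(0, nmax + 1); nm <- rep(0, nmax + 1)
      for (k in 0:nmax) {
        if (pa[k + 1] == 0 && ma[k + 1] == 0) next
        jmax <- nmax - k
        idx <- 0:jmax
        np[k + 1 + idx] <- np[k + 1 + idx] + pa[k + 1] * pb[idx + 1]
        nm[k + 1 + idx] <- nm[k + 1 + idx] + pa[k + 1] * mb[idx + 1] +
          ma[k + 1] * pb[idx + 1]
      }
      list(p = np, m = nm)
    }
    while (n > 0) {
      if (n %% 2 == 1) {
        r <- conv(rp, rm, bp, bm); rp <- r$p; rm <- r$m
      }
      n <- n %/% 2
      if (n > 0) {
        b <- conv(bp, bm, bp, bm); bp <- b$p; bm <- b$m
      }
    }
    r <- conv(p, pm, rp, rm); p <- r$p; pm <- r$m
  }
  shift <- 0:(n_peaks - 1)
  prob <- p[shift + 1]
  moff <- shift * .ISOTOPE_SPACING
  moff[prob > 0] <- pm[shift + 1][prob > 0] / prob[prob > 0]
  base <- max(prob)
  keep <- prob > 0
  data.frame(shift = shift[keep],
             mass_offset = moff[keep],
             abundance = prob[keep] / base)
}

#' Signed mass error in parts per million
#'
#' @param measured_mz,theoretical_mz m/z values; `theoretical_mz` must be
#'   strictly positive.
#' @return `1e6 * (measured - theoretical) / theoretical`.
#' @export
ppm_error <- function(measured_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (measured_mz - theoretical_mz) / theoretical_mz
}
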