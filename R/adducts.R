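#' Load an adduct table
#'
#' Adducts are shipped as an editable TSV (see
#' `system.file("extdata", "adducts.tsv", package = "timspasef")`). Each
#' row defines a name, polarity, signed charge, and the formulas added to
#' and removed from the neutral species.
#'
#' @param path path to a TSV file; defaults to the packaged table.
#' @return data.frame with columns `name`, `polarity`, `charge`,
#'   `formula_add`, `formula_sub`, `delta_mass` (Da, including the
#'   electron correction) and `mz_offset` (applied to the neutral mass).
#' @export
load_adducts <- function(path = system.file("extdata", "adducts.tsv",
                                            package = "timspasef")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  for (col in c("formula_add", "formula_sub"))
    if (is.null(tab[[col]])) tab[[col]] <- ""
  tab$formula_add[is.na(tab$formula_add)] <- ""
  tab$formula_sub[is.na(tab$formula_sub)] <- ""
  madd <- vapply(tab$formula_add, function(s)
    if (s == "") 0 else monoisotopic_mass(s), numeric(1))
  msub <- vapply(tab$formula_sub, function(s)
    if (s == "") 0 else monoisotopic_mass(s), numeric(1))
  tab$delta_mass <- madd - msub - tab$charge * .ELECTRON_MASS
  tab$mz_offset <- tab$delta_mass / abs(tab$charge)
  rownames(tab) <- tab$name
  tab
}

.adduct_cache <- new.env(parent = emptyenv())

default_adducts <- function() {
  if (is.null(.adduct_cache$tab)) .adduct_cache$tab <- load_adducts()
  .adduct_cache$tab
}

#' Look up one adduct by name
#' @param name adduct label such as `"[M+H]+"`.
#' @param adducts adduct table from [load_adducts()].
#' @return single-row data.frame.
#' @export
adduct_spec <- function(name, adducts = default_adducts()) {
  if (!name %in% adducts$name)
    stop("unknown adduct: ", name)
  adducts[adducts$name == name, , drop = FALSE]
}

#' m/z of an ionised species
#'
#' Computes `(M + delta - z * m_e) / |z|` for the neutral monoisotopic
#' mass `M`, where `delta` is the adduct's formula gain/loss and the
#' electron count is corrected per charge. Subtractive adducts (e.g.
#' `[M-H]-`, `[M-CH3]-`) validate that the removed atoms exist in the
#' species formula.
#'
#' @param species_formula a `chem_formula`, formula string, or a neutral
#'   monoisotopic mass in Da (numeric).
#' @param adduct an adduct name or a single-row adduct table entry.
#' @param adducts adduct table used to resolve names.
#' @return m/z (> 0).
#' @examples
#' mz_of_adduct("C51H96O6", "[M+Na]+")  # 827.70991
#' @export
mz_of_adduct <- function(species_formula, adduct,
                         adducts = default_adducts()) {
  if (is.character(adduct)) adduct <- adduct_spec(adduct, adducts)
  if (!inherits(species_formula, "chem_formula") &&
      is.numeric(species_formula)) {
    m <- species_formula
  } else {
    f <- as_chem_formula(species_formula)
    if (nzchar(adduct$formula_sub))
      invisible(f - parse_chem_formula(adduct$formula_sub))  # errors if negative
    m <- monoisotopic_mass(f)
  }
  mz <- (m + adduct$delta_mass) / abs(adduct$charge)
  if (any(mz <= 0)) stop("non-positive m/z")
  mz
}
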