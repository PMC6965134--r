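# Compilation of per-lipid consensus CCS values across runs, replicate
# quantification statistics, cross-library comparison, and putative
# assignment of unidentified features from the conformational landscape.

#' Compile a CCS library across runs
#'
#' Entries are keyed by (lipid name, adduct); the consensus CCS is the
#' median across runs and the dispersion the coefficient of variation
#' (sd/mean x 100). When a `group` column is present (e.g. instrument
#' or laboratory), an inter-group CV over group medians is reported as
#' well. Compilation is permutation-invariant and idempotent.
#'
#' @param runs either one data.frame with a `run` column or a list of
#'   per-run unique-lipid tables (from [deduplicate()] or compatible),
#'   each with columns `name`, `adduct`(s), `mz`, `ccs` and optionally
#'   `rt_s`, `level`, `group`.
#' @param mz_ppm_integrity maximum spread of m/z within one key before
#'   an integrity error is raised.
#' @return data.frame: `name`, `adduct`, `ccs` (median), `cv_pct`,
#'   `n_obs`, `mz`, `rt_s`, `runs`, and `inter_group_cv_pct` when
#'   groups are given. Single-observation entries carry `NA` CV and
#'   `flagged = TRUE`.
#' @export
compile_library <- function(runs, mz_ppm_integrity = 5) {
  if (is.data.frame(runs)) {
    stopifnot("run" %in% names(runs))
    tab <- runs
  } else {
    stopifnot(length(runs) >= 1)
    tab <- do.call(rbind, lapply(seq_along(runs), function(i) {
      x <- runs[[i]]
      x$run <- if (!is.null(x$run)) x$run else
        if (!is.null(names(runs))) names(runs)[i] else paste0("run", i)
      x
    }))
  }
  if (is.null(tab$adduct) && !is.null(tab$adducts))
    tab$adduct <- tab$adducts
  stopifnot(all(c("name", "adduct", "ccs", "mz") %in% names(tab)))
  key <- paste(tab$name, tab$adduct, sep = " | ")
  out <- lapply(sort(unique(key)), function(k) {
    g <- tab[key == k, , drop = FALSE]
    spread <- 1e6 * (max(g$mz) - min(g$mz)) / stats::median(g$mz)
    if (spread > mz_ppm_integrity)
      stop("integrity error: m/z spread ", round(spread, 2),
           " ppm for key ", k)
    n <- nrow(g)
    cv <- if (n >= 2) stats::sd(g$ccs) / mean(g$ccs) * 100 else NA_real_
    igcv <- NA_real_
    if (!is.null(g$group) && length(unique(g$group)) >= 2) {
      gm <- tapply(g$ccs, g$group, stats::median)
      igcv <- stats::sd(gm) / mean(gm) * 100
    }
    data.frame(name = g$name[1], adduct = g$adduct[1],
               ccs = stats::median(g$ccs), cv_pct = cv,
               inter_group_cv_pct = igcv, n_obs = n,
               mz = stats::median(g$mz),
               rt_s = if (!is.null(g$rt_s)) stats::median(g$rt_s)
                      else NA_real_,
               runs = paste(sort(unique(as.character(g$run))),
                            collapse = ";"),
               flagged = n < 2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Replicate quantification statistics
#'
#' Per-lipid coefficients of variation over non-missing intensities for
#' lipids quantified in at least `min_detected` replicates, the median
#' CV, the fraction of CVs below 20%, the number of lipids quantified
#' in N of the replicates, and data completeness (the filled fraction
#' of the matrix over lipids detected at least once).
#'
#' @param mat numeric matrix lipids x replicates, `NA` = not detected.
#' @param min_detected minimum replicates for a CV (default 3).
#' @return list: `cv_pct` (named per-lipid), `median_cv_pct`,
#'   `frac_cv_below_20`, `n_detected` (per lipid),
#'   `quantified_in_n` (table over N), `completeness_pct`,
#'   `complete_in_all`.
#' @export
quant_stats <- function(mat, min_detected = 3) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  det <- rowSums(!is.na(mat))
  seen <- det >= 1
  cvrows <- det >= max(2, min_detected)
  cv <- apply(mat[cvrows, , drop = FALSE], 1, function(x)
    stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE) * 100)
  list(cv_pct = cv,
       median_cv_pct = if (length(cv)) stats::median(cv) else NA_real_,
       frac_cv_below_20 = if (length(cv)) mean(cv < 20) else NA_real_,
       n_detected = det,
       quantified_in_n = table(factor(det[seen], levels = 1:ncol(mat))),
       completeness_pct = mean(!is.na(mat[seen, , drop = FALSE])) * 100,
       complete_in_all = sum(det == ncol(mat)))
}

#' Compare two CCS libraries
#'
#' Joins on (name, adduct) and reports the per-lipid relative deviation
#' `(A - B)/B x 100`, its median absolute value, the fraction within
#' +-1%, and the Pearson correlation.
#'
#' @param a,b libraries from [compile_library()] (or any table with
#'   `name`, `adduct`, `ccs`).
#' @return list: `per_lipid` (data.frame `name`, `adduct`, `ccs_a`,
#'   `ccs_b`, `dev_pct`), `median_abs_dev_pct`, `frac_within_1pct`,
#'   `pearson_r`, `n_shared`. `n_shared = 0` yields an empty report.
#' @export
compare_libraries <- function(a, b) {
  ka <- paste(a$name, a$adduct); kb <- paste(b$name, b$adduct)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) {
    return(list(per_lipid = data.frame(), median_abs_dev_pct = NA_real_,
                frac_within_1pct = NA_real_, pearson_r = NA_real_,
                n_shared = 0L))
  }
  ia <- match(shared, ka); ib <- match(shared, kb)
  dev <- (a$ccs[ia] - b$ccs[ib]) / b$ccs[ib] * 100
  list(per_lipid = data.frame(name = a$name[ia], adduct = a$adduct[ia],
                              ccs_a = a$ccs[ia], ccs_b = b$ccs[ib],
                              dev_pct = dev),
       median_abs_dev_pct = stats::median(abs(dev)),
       frac_within_1pct = mean(abs(dev) <= 1),
       pearson_r = if (length(shared) >= 3 &&
                       stats::sd(a$ccs[ia]) > 0 &&
                       stats::sd(b$ccs[ib]) > 0)
         stats::cor(a$ccs[ia], b$ccs[ib]) else NA_real_,
       n_shared = length(shared))
}

#' Putative assignment from the conformational landscape
#'
#' Within each (class, total acyl carbons) cluster of identified
#' lipids, CCS falls almost linearly with the double-bond count. An
#' unidentified feature receives a putative name when (a) its m/z
#' matches a database species within the precursor tolerance, (b) its
#' CCS lies within `ccs_tol_pct` of the cluster's linear trend at the
#' candidate's double-bond count (at least two identified cluster
#' members are required), and (c) when an externally predicted CCS is
#' supplied for the candidate, it deviates less than `pred_tol_pct`
#' from the measured value.
#'
#' @param features data.frame of unidentified features (`mz`, `ccs`,
#'   and optionally `rt_s`).
#' @param identified annotated lipids (`class`, `species_name` or
#'   `name`, `adduct`, `ccs`; needs `n`/`d` or parseable names).
#' @param db from [build_database()].
#' @param predicted optional table `name`, `adduct`, `ccs_pred`
#'   (machine-learning predictions supplied by the user).
#' @param config a [run_config()] (precursor tolerance).
#' @param ccs_tol_pct trend gate (percent of CCS).
#' @param pred_tol_pct predicted-CCS gate (percent).
#' @return `features` with added `putative_name`, `putative_adduct`,
#'   `trend_ccs`, `trend_dev_pct` (NA where unassigned).
#' @export
putative_assignment <- function(features, identified, db,
                                predicted = NULL,
                                config = run_config(),
                                ccs_tol_pct = 1, pred_tol_pct = 1) {
  nm <- if (!is.null(identified$species_name)) identified$species_name
        else identified$name
  sp <- lapply(nm, parse_lipid_name)
  id <- data.frame(class = vapply(sp, `[[`, "", "class"),
                   n = vapply(sp, function(s) as.numeric(s$carbons),
                              numeric(1)),
                   d = vapply(sp, function(s)
                     as.numeric(s$doublebonds), numeric(1)),
                   adduct = identified$adduct,
                   ccs = identified$ccs)
  features$putative_name <- NA_character_
  features$putative_adduct <- NA_character_
  features$trend_ccs <- NA_real_
  features$trend_dev_pct <- NA_real_
  if (nrow(features) == 0) return(features)
  for (i in seq_len(nrow(features))) {
    tol <- config$prec_ppm * 1e-6 * features$mz[i]
    lo <- findInterval(features$mz[i] - tol, db$mz) + 1
    hi <- findInterval(features$mz[i] + tol, db$mz)
    if (hi < lo) next
    cands <- db[lo:hi, , drop = FALSE]
    best <- NULL
    for (j in seq_len(nrow(cands))) {
      cd <- cands[j, ]
      cl <- id[id$class == cd$class & id$n == cd$n &
                 id$adduct == cd$adduct, , drop = FALSE]
      if (nrow(cl) < 2 || length(unique(cl$d)) < 2) next
      fit <- stats::lm(ccs ~ d, data = cl)
      trend <- unname(stats::predict(fit,
                                     newdata = data.frame(d = cd$d)))
      dev <- (features$ccs[i] - trend) / trend * 100
      if (abs(dev) > ccs_tol_pct) next
      if (!is.null(predicted)) {
        pr <- predicted$ccs_pred[predicted$name == cd$name &
                                   predicted$adduct == cd$adduct]
        if (length(pr) == 1 &&
            abs(pr - features$ccs[i]) / features$ccs[i] * 100 >
              pred_tol_pct) next
      }
      if (is.null(best) || abs(dev) < abs(best$dev)) {
        best <- list(name = cd$name, adduct = cd$adduct,
                     trend = trend, dev = dev)
      }
    }
    if (!is.null(best)) {
      features$putative_name[i] <- best$name
      features$putative_adduct[i] <- best$adduct
      features$trend_ccs[i] <- best$trend
      features$trend_dev_pct[i] <- best$dev
    }
  }
  features
}
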