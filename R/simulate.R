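# Ground-truth lipidome generation and frame rendering: the package's
# stand-in for the instrument and for real raw data.

# Class-specific CCS emulation: ccs = A + B * mz - D * d (+ 0.2% jitter).
# Slopes/intercepts chosen to land published class trends (PC 34:1 [M+H]+
# near 281 A^2, SM 34:1 near 269 A^2, TAG 48:1 [M+NH4]+ near 311 A^2) and
# the TAG-vs-DAG class offset of 54.7 A^2 at equal m/z.
.CCS_TREND <- list(
  TAG = c(A = 83.3, B = 0.28, D = 2.5),
  DAG = c(A = 28.6, B = 0.28, D = 2.5),   # TAG trend shifted by -54.7
  MAG = c(A = 60.0, B = 0.28, D = 2.5),
  PC  = c(A = 70.0, B = 0.28, D = 2.5),
  PE  = c(A = 67.0, B = 0.28, D = 2.5),
  PA  = c(A = 60.0, B = 0.28, D = 2.5),
  PS  = c(A = 62.0, B = 0.28, D = 2.5),
  PI  = c(A = 58.0, B = 0.28, D = 2.5),
  PG  = c(A = 63.0, B = 0.28, D = 2.5),
  LPC = c(A = 72.0, B = 0.28, D = 2.5),
  SM  = c(A = 74.0, B = 0.28, D = 2.5),
  Cer = c(A = 80.0, B = 0.28, D = 2.5),
  HexCer = c(A = 72.0, B = 0.28, D = 2.5),
  CE  = c(A = 100.0, B = 0.28, D = 2.5),
  Chol = c(A = 90.0, B = 0.28, D = 2.5)
)

# retention model: rt fraction of gradient = base + kn * n - kd * d
# (equivalent-carbon-number convention: retention grows with chain
# length, falls with unsaturation)
.RT_BASE <- c(TAG = 0.10, DAG = 0.12, MAG = 0.10, PC = 0.12, PE = 0.12,
              PA = 0.10, PS = 0.10, PI = 0.08, PG = 0.10, LPC = 0.05,
              SM = 0.10, Cer = 0.15, HexCer = 0.12, CE = 0.55,
              Chol = 0.45)
.RT_KN <- 0.013
.RT_KD <- 0.009

# fatty acyl pool (carbons:doublebonds -> sampling weight)
# odd-chain fatty acids are kept near their low physiological share
# (about 1% of total acyls in human plasma)
.FA_POOL <- data.frame(
  c = c(12, 14, 15, 16, 16, 17, 18, 18, 18, 18, 20, 20, 20, 20, 20,
        22, 22, 22, 22, 24, 24),
  b = c(0,  0,  0,  0,  1,  0,  0,  1,  2,  3,  0,  1,  3,  4,  5,
        0,  1,  5,  6,  0,  1),
  w = c(.02, .05, .01, .19, .07, .01, .09, .19, .11, .04, .01, .02,
        .03, .05, .02, .01, .02, .02, .03, .005, .015)
)
.SPHINGOID_POOL <- data.frame(c = c(18, 18, 18), b = c(1, 0, 2),
                              w = c(.8, .1, .1))
.CE_ACYL_MIN <- 14

# default class mixes (sampling weights) per polarity; TAG and sterols
# are not ionised in negative mode
.CLASS_MIX_POS <- c(TAG = .25, PC = .20, PE = .09, DAG = .05, SM = .08,
                    PI = .04, PS = .03, PG = .03, PA = .02, LPC = .06,
                    Cer = .05, HexCer = .02, CE = .06, MAG = .01,
                    Chol = .01)
.CLASS_MIX_NEG <- c(PC = .22, PE = .16, PI = .10, PS = .08, PG = .08,
                    PA = .06, LPC = .08, SM = .08, Cer = .10,
                    HexCer = .04)

# adduct relative yields per class
.ADDUCT_YIELDS <- list(
  positive = list(
    TAG = c("[M+NH4]+" = 1, "[M+Na]+" = 0.30),
    DAG = c("[M+NH4]+" = 1, "[M+Na]+" = 0.30),
    MAG = c("[M+NH4]+" = 1, "[M+Na]+" = 0.25),
    PC  = c("[M+H]+" = 1, "[M+Na]+" = 0.25),
    PE  = c("[M+H]+" = 1, "[M+Na]+" = 0.20),
    PA  = c("[M+H]+" = 0.4, "[M+Na]+" = 0.30),
    PS  = c("[M+H]+" = 0.6),
    PI  = c("[M+H]+" = 0.4, "[M+Na]+" = 0.20),
    PG  = c("[M+H]+" = 0.5, "[M+Na]+" = 0.20),
    LPC = c("[M+H]+" = 1, "[M+Na]+" = 0.20),
    SM  = c("[M+H]+" = 1, "[M+Na]+" = 0.20),
    Cer = c("[M+H]+" = 1),
    HexCer = c("[M+H]+" = 1),
    CE  = c("[M+NH4]+" = 1, "[M+Na]+" = 0.20),
    Chol = c("[M+H]+" = 0.5)
  ),
  negative = list(
    PC  = c("[M+HCOO]-" = 1, "[M-CH3]-" = 0.5),
    PE  = c("[M-H]-" = 1),
    PA  = c("[M-H]-" = 1),
    PS  = c("[M-H]-" = 1),
    PI  = c("[M-H]-" = 1),
    PG  = c("[M-H]-" = 1),
    LPC = c("[M+HCOO]-" = 1),
    SM  = c("[M+HCOO]-" = 0.5),
    Cer = c("[M-H]-" = 1, "[M+HCOO]-" = 0.3),
    HexCer = c("[M-H]-" = 1)
  )
)

.sample_chains <- function(class) {
  k <- .CLASS_TEMPLATES[[class]]$n_chains
  if (k == 0) return(NULL)
  cat <- .CLASS_TEMPLATES[[class]]$category
  chains <- list()
  if (cat == "SP") {
    i <- sample.int(nrow(.SPHINGOID_POOL), 1, prob = .SPHINGOID_POOL$w)
    chains[[1]] <- c(.SPHINGOID_POOL$c[i], .SPHINGOID_POOL$b[i])
    # N-acyl chain, often long and saturated
    j <- sample.int(nrow(.FA_POOL), 1, prob = .FA_POOL$w)
    acyl <- c(.FA_POOL$c[j] + sample(c(0, 2, 4, 6), 1,
                                     prob = c(.4, .25, .2, .15)),
              .FA_POOL$b[j])
    chains[[2]] <- acyl
  } else {
    for (i in seq_len(k)) {
      j <- sample.int(nrow(.FA_POOL), 1, prob = .FA_POOL$w)
      chains[[i]] <- c(.FA_POOL$c[j], .FA_POOL$b[j])
    }
    # keep a canonical order so duplicated compositions collapse
    ord <- order(vapply(chains, `[`, numeric(1), 1),
                 vapply(chains, `[`, numeric(1), 2))
    chains <- chains[ord]
  }
  chains
}

#' Generate a ground-truth lipidome
#'
#' Samples species from the supported classes, assigns per-chain
#' compositions from a fatty-acyl pool, log-normal abundances,
#' retention times following the equivalent-carbon-number convention
#' (within a class, retention increases with total carbons and
#' decreases with double bonds), and per-adduct CCS values following
#' class-specific affine trends in m/z with a near-linear per-double-bond
#' decrement (TAG vs DAG offset by 54.7 A^2). Mobilities derive from CCS
#' through the inverse Mason-Schamp conversion; adduct rows falling
#' outside the recorded m/z or mobility range are filtered out.
#'
#' @param n_species number of distinct species to draw (>= 1).
#' @param class_mix named weight vector over classes; defaults to a
#'   plasma-like mix for the configured polarity.
#' @param config a [run_config()]; supplies polarity, gradient, ranges
#'   and the seed (overridable via `seed`).
#' @param seed optional override of `config$seed`.
#' @return data.frame (one row per species x adduct) with columns
#'   documented in the package vignette; carries the ground-truth
#'   provenance used for recovery scoring.
#' @export
generate_lipidome <- function(n_species, class_mix = NULL,
                              config = run_config(), seed = NULL) {
  stopifnot(n_species >= 1)
  polarity <- config$polarity
  if (is.null(class_mix))
    class_mix <- if (polarity == "positive") .CLASS_MIX_POS else .CLASS_MIX_NEG
  if (length(class_mix) == 0 || sum(class_mix) <= 0)
    stop("class mix must contain at least one positive weight")
  if (!is.null(seed)) config$seed <- seed
  set.seed(config$seed %% .Machine$integer.max)

  yields <- .ADDUCT_YIELDS[[polarity]]
  class_mix <- class_mix[names(class_mix) %in% names(yields)]
  if (length(class_mix) == 0)
    stop("no class in the mix is ionisable in ", polarity, " mode")

  seen <- character(0)
  species <- vector("list", n_species)
  i <- 0; tries <- 0
  while (i < n_species && tries < n_species * 60) {
    tries <- tries + 1
    cls <- sample(names(class_mix), 1, prob = class_mix)
    chains <- .sample_chains(cls)
    # ether/plasmalogen PC and PE (about 15% of those classes in plasma)
    # and a small share of oxidised glycerophospholipids
    ether <- cls %in% c("PC", "PE") && stats::runif(1) < 0.15
    ox <- if (!ether && .CLASS_TEMPLATES[[cls]]$category == "GP" &&
              stats::runif(1) < 0.04) sample(1:2, 1, prob = c(.8, .2))
          else 0
    sp <- if (is.null(chains)) lipid_species(cls, 0, 0) else
      lipid_species(cls, sum(vapply(chains, `[`, numeric(1), 1)),
                    sum(vapply(chains, `[`, numeric(1), 2)),
                    chains = chains, ether = ether, ox = ox)
    # one entry per species-level name: chain isomers of the same n:d
    # share formula, retention and CCS trend and would be inseparable
    key <- species_name(sp, "species")
    if (key %in% seen) next
    seen <- c(seen, key)
    i <- i + 1
    species[[i]] <- sp
  }
  species <- species[seq_len(i)]
  n <- length(species)

  cls <- vapply(species, `[[`, "", "class")
  nn <- vapply(species, function(s) as.numeric(s$carbons), numeric(1))
  dd <- vapply(species, function(s) as.numeric(s$doublebonds), numeric(1))
  formulas <- vapply(species, function(s)
    format(formula_from_species(s)), character(1))
  mono <- vapply(formulas, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)

  # counts are arbitrary units kept consistent with the instrument's
  # printed thresholds (candidate threshold 100, scheduling target 4000,
  # feature thresholds 500/200): a median-abundance species near its
  # apex samples a few thousand counts per frame, so typical precursors
  # reach the 4000-count target within about two fragmentation events
  abundance <- stats::rlnorm(n, meanlog = log(2e4), sdlog = 1.8)
  rt_frac <- .RT_BASE[cls] + .RT_KN * nn - .RT_KD * dd +
    stats::rnorm(n, 0, 0.01)
  rt_s <- pmin(pmax(rt_frac, 0.04), 0.96) * config$gradient_s
  rt_fwhm_s <- stats::runif(n, config$rt_fwhm_s[1], config$rt_fwhm_s[2])
  mob_fwhm_ms <- stats::runif(n, config$mob_fwhm_ms[1],
                              config$mob_fwhm_ms[2])

  adducts <- default_adducts()
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    y <- yields[[cls[k]]]
    if (is.null(y)) next
    sp <- species[[k]]
    anames <- names(y)
    mzs <- vapply(anames, function(a)
      mz_of_adduct(mono[k], a, adducts), numeric(1))
    trend <- .CCS_TREND[[cls[k]]]
    ccs <- (trend[["A"]] + trend[["B"]] * mzs - trend[["D"]] * dd[k]) *
      exp(stats::rnorm(length(anames), 0, 0.002))
    rows[[k]] <- data.frame(
      species_id = k,
      name = species_name(sp, "species"),
      chain_name = species_name(sp, if (is.null(sp$chains)) "species"
                                else "chain"),
      class = cls[k], category = sp$category,
      carbons = nn[k], doublebonds = dd[k],
      chains = if (is.null(sp$chains)) NA_character_ else
        paste(vapply(sp$chains, function(ch)
          paste0(ch[1], ":", ch[2]), character(1)), collapse = "/"),
      formula = formulas[k], adduct = anames,
      z = abs(adducts[anames, "charge"]),
      mz = mzs, abundance = abundance[k] * y,
      rt_s = rt_s[k], rt_fwhm_s = rt_fwhm_s[k],
      ccs = ccs, mob_fwhm_ms = mob_fwhm_ms[k],
      polarity = polarity, row.names = NULL)
  }
  gt <- do.call(rbind, rows)
  gt$ook0 <- ccs_to_mobility(gt$ccs, gt$mz * gt$z, gt$z)
  keep <- gt$mz >= config$mz_range[1] & gt$mz <= config$mz_range[2] &
    gt$ook0 >= config$ook0_range[1] + 0.01 &
    gt$ook0 <= config$ook0_range[2] - 0.01
  gt <- gt[keep, , drop = FALSE]
  gt$entry_id <- seq_len(nrow(gt))
  rownames(gt) <- NULL
  attr(gt, "config") <- config
  gt
}

# mobility bin weights of one entry: integral of the gaussian profile
# over each bin, normalised to sum 1 over the kept bins
.mobility_bins <- function(scan_time_ms, fwhm_ms, bin_ms, ramp_ms) {
  sigma <- fwhm_ms / (2 * sqrt(2 * log(2)))
  lo <- max(0L, floor((scan_time_ms - 3 * sigma) / bin_ms))
  hi <- min(ceiling(ramp_ms / bin_ms) - 1L,
            ceiling((scan_time_ms + 3 * sigma) / bin_ms))
  if (hi < lo) return(NULL)
  b <- lo:hi
  w <- stats::pnorm((b + 1) * bin_ms, scan_time_ms, sigma) -
    stats::pnorm(b * bin_ms, scan_time_ms, sigma)
  keep <- w > 1e-4
  if (!any(keep)) return(NULL)
  list(bin = b[keep], w = w[keep] / sum(w[keep]))
}

#' Render mobility-resolved MS1 frames
#'
#' Each ground-truth entry contributes a Gaussian elution profile times a
#' Gaussian mobility profile times its isotope envelope; the per-frame
#' intensity is the abundance times the retention-time weight integrated
#' over one cycle, so the summed signal of a fully eluting species
#' equals its abundance times the envelope sum. Optional noise adds
#' spurious centroids (including isotope-like doublets) on a log-uniform
#' m/z grid.
#'
#' @param lipidome from [generate_lipidome()].
#' @param config a [run_config()].
#' @param cal a `tims_calibration`; defaults to the linear map over the
#'   configured mobility range.
#' @param time_range optional `c(t0, t1)` (s) restricting rendering to a
#'   run-time slice.
#' @param n_isotopes isotope peaks rendered per entry.
#' @return list of class `frame_data`: `peaks` (frame, time_s, bin,
#'   scan_time_ms, mz, intensity + provenance columns entry_id),
#'   `frames` (frame metadata), `cal`, `config`.
#' @export
render_frames <- function(lipidome, config = attr(lipidome, "config"),
                          cal = NULL, time_range = NULL, n_isotopes = 3) {
  stopifnot(is.data.frame(lipidome))
  if (is.null(config)) config <- run_config()
  if (is.null(cal))
    cal <- default_calibration(config$ramp_ms, config$ook0_range)
  set.seed((config$seed + 1013) %% .Machine$integer.max)

  times <- seq(0, config$gradient_s, by = config$cycle_s)
  if (!is.null(time_range))
    times <- times[times >= time_range[1] & times <= time_range[2]]
  frames <- data.frame(frame = seq_along(times), time_s = times,
                       ms_level = 1L)

  if (nrow(lipidome) == 0) {
    peaks <- .render_noise(frames, config)
    return(structure(list(peaks = peaks, frames = frames, cal = cal,
                          config = config), class = "frame_data"))
  }

  lip <- lipidome
  lip$scan_time_ms <- ook0_to_scan_time(cal, lip$ook0)

  # per-entry static profile: isotopes x mobility bins
  iso_cache <- new.env(parent = emptyenv())
  prof <- vector("list", nrow(lip))
  for (k in seq_len(nrow(lip))) {
    f <- lip$formula[k]
    pat <- get0(f, envir = iso_cache)
    if (is.null(pat)) {
      pat <- isotope_pattern(f, n_peaks = n_isotopes)
      assign(f, pat, envir = iso_cache)
    }
    mb <- .mobility_bins(lip$scan_time_ms[k], lip$mob_fwhm_ms[k],
                         config$bin_ms, config$ramp_ms)
    if (is.null(mb)) next
    g <- expand.grid(iso = seq_len(nrow(pat)), bi = seq_along(mb$bin))
    prof[[k]] <- data.frame(
      entry_id = lip$entry_id[k],
      mz = (lip$mz[k] + pat$mass_offset[g$iso] / lip$z[k]),
      w = pat$abundance[g$iso] * mb$w[g$bi],
      bin = mb$bin[g$bi])
  }
  prof <- do.call(rbind, prof)

  # entry x frame elution weights
  sigma_rt <- lip$rt_fwhm_s / (2 * sqrt(2 * log(2)))
  ef <- vector("list", nrow(lip))
  for (k in seq_len(nrow(lip))) {
    sel <- which(abs(times - lip$rt_s[k]) <= 3.5 * sigma_rt[k])
    if (length(sel) == 0) next
    w <- stats::dnorm(times[sel], lip$rt_s[k], sigma_rt[k]) * config$cycle_s
    ef[[k]] <- data.frame(entry_id = lip$entry_id[k], frame = sel,
                          rt_w = w * lip$abundance[k])
  }
  ef <- do.call(rbind, ef)

  if (is.null(prof) || is.null(ef)) {
    peaks <- .render_noise(frames, config)
  } else {
    # join on entry_id (both sorted by entry)
    idx <- split(seq_len(nrow(prof)), prof$entry_id)
    jdx <- split(seq_len(nrow(ef)), ef$entry_id)
    common <- intersect(names(idx), names(jdx))
    pieces <- vector("list", length(common))
    for (ci in seq_along(common)) {
      e <- common[ci]
      a <- prof[idx[[e]], ]; b <- ef[jdx[[e]], ]
      na <- nrow(a); nb <- nrow(b)
      pieces[[ci]] <- data.frame(
        frame = rep(b$frame, each = na),
        bin = rep(a$bin, nb),
        mz = rep(a$mz, nb),
        intensity = rep(a$w, nb) * rep(b$rt_w, each = na),
        entry_id = as.integer(e))
    }
    peaks <- do.call(rbind, pieces)
    peaks <- peaks[peaks$intensity >= 1, , drop = FALSE]
    noise <- .render_noise(frames, config)
    peaks <- rbind(peaks, noise)
  }
  peaks$time_s <- times[peaks$frame]
  peaks$scan_time_ms <- (peaks$bin + 0.5) * config$bin_ms
  peaks <- peaks[order(peaks$frame, peaks$bin, peaks$mz), ]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, frames = frames, cal = cal,
                 config = config), class = "frame_data")
}

.render_noise <- function(frames, config) {
  empty <- data.frame(frame = integer(0), bin = integer(0),
                      mz = numeric(0), intensity = numeric(0),
                      entry_id = integer(0))
  if (!isTRUE(config$noise$enabled) || nrow(frames) == 0) return(empty)
  nper <- stats::rpois(nrow(frames), config$noise$peaks_per_frame)
  ntot <- sum(nper)
  if (ntot == 0) return(empty)
  nbins <- ceiling(config$ramp_ms / config$bin_ms)
  lmz <- log(config$mz_range)
  out <- data.frame(
    frame = rep(frames$frame, nper),
    bin = sample.int(nbins, ntot, replace = TRUE) - 1L,
    mz = exp(stats::runif(ntot, lmz[1], lmz[2])),
    intensity = stats::rexp(ntot, 1 / config$noise$intensity_scale) + 1,
    entry_id = NA_integer_)
  # occasional isotope-like satellites to exercise envelope filters
  dbl <- which(stats::runif(ntot) < config$noise$doublet_prob)
  if (length(dbl) > 0) {
    sat <- out[dbl, ]
    sat$mz <- sat$mz + .ISOTOPE_SPACING
    sat$intensity <- sat$intensity * stats::runif(length(dbl), 0.2, 0.9)
    out <- rbind(out, sat)
  }
  out
}

#' @export
print.frame_data <- function(x, ...) {
  cat("<frame_data> ", nrow(x$frames), " MS1 frames, ",
      nrow(x$peaks), " centroids (", x$config$polarity, ")\n", sep = "")
  invisible(x)
}
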