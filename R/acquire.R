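# Data-dependent acquisition: candidate detection on MS1 frames, PASEF
# and standard scheduling, dynamic exclusion, and the 0.4-s cycle loop.

#' Mobility-dependent collision energy
#'
#' Linear interpolation between the configured endpoints over the
#' scanned mobility range (25-45 eV positive, 35-55 eV negative, rising
#' with 1/K0: larger, slower ions receive more energy). Out-of-range
#' mobilities are clamped with a warning.
#'
#' @param ook0 reduced mobility (1/K0, Vs/cm^2).
#' @param polarity `"positive"` or `"negative"`.
#' @param config a [run_config()].
#' @return collision energy in eV.
#' @export
collision_energy <- function(ook0, polarity = config$polarity,
                             config = run_config()) {
  rng <- config$ook0_range
  if (any(ook0 < rng[1] | ook0 > rng[2])) {
    warning("mobility outside the scanned range; clamping")
    ook0 <- pmin(pmax(ook0, rng[1]), rng[2])
  }
  ce <- if (polarity == "positive") config$ce_pos else config$ce_neg
  ce[1] + (ce[2] - ce[1]) * (ook0 - rng[1]) / (rng[2] - rng[1])
}

# single-frame mobility traces: cluster centroids by m/z, then split by
# scan-time contiguity; returns one row per trace
.frame_traces <- function(pk, bin_ms, mz_tol_da = 0.008,
                          mz_tol_ppm = 15, bin_gap = 3) {
  if (nrow(pk) == 0)
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      apex_bin = integer(0), lo_ms = numeric(0),
                      hi_ms = numeric(0), n_bins = integer(0),
                      entry_id = integer(0)))
  pk <- pk[order(pk$mz), ]
  tol <- pmax(mz_tol_da, pk$mz * mz_tol_ppm * 1e-6)
  g <- cumsum(c(TRUE, diff(pk$mz) > tol[-1]))
  # split m/z clusters into scan-time-contiguous traces
  o <- order(g, pk$bin)
  pk <- pk[o, ]; g <- g[o]
  tid <- cumsum(c(TRUE, diff(g) != 0 | diff(pk$bin) > bin_gap))
  utid <- unique(tid)
  tot <- as.vector(rowsum(pk$intensity, tid))
  wmz <- as.vector(rowsum(pk$mz * pk$intensity, tid)) / tot
  oi <- order(tid, -pk$intensity)
  first <- oi[!duplicated(tid[oi])]
  apex_bin <- pk$bin[first]
  maxint <- pk$intensity[first]
  half <- pk$intensity >= maxint[match(tid, utid)] / 2
  lo <- unname(tapply(pk$bin[half], tid[half], min)[as.character(utid)])
  hi <- unname(tapply(pk$bin[half], tid[half], max)[as.character(utid)])
  nb <- tabulate(match(tid, utid))
  # provenance: entry id of the trace's apex centroid
  eid <- pk$entry_id[first]
  data.frame(mz = wmz, intensity = tot, apex_bin = apex_bin,
             lo_ms = lo * bin_ms, hi_ms = (hi + 1) * bin_ms,
             n_bins = as.integer(nb), entry_id = eid)
}

#' Detect precursor candidates on an MS1 frame
#'
#' Centroids are grouped into mobility traces (m/z clustering followed
#' by scan-time contiguity), traces are assembled into isotope
#' envelopes by the characteristic 1.00336/z spacing with an
#' envelope-shape plausibility check on the M+1/M ratio, and envelopes
#' below the 100-count intensity threshold (or without an isotope
#' partner) are rejected.
#'
#' @param frame_peaks centroid table of one MS1 frame (columns `bin`,
#'   `mz`, `intensity`, optionally `entry_id` provenance).
#' @param config a [run_config()].
#' @param cal calibration used to report the mobility apex.
#' @param max_z maximum charge considered.
#' @return data.frame of candidates: `mono_mz`, `z`, `intensity`,
#'   `scan_time_ms`, `lo_ms`/`hi_ms` (half-height window), `ook0`,
#'   `n_iso`, `entry_id`.
#' @export
detect_candidates <- function(frame_peaks, config = run_config(),
                              cal = NULL, max_z = 2) {
  if (is.null(cal))
    cal <- default_calibration(config$ramp_ms, config$ook0_range)
  tr <- .frame_traces(frame_peaks, config$bin_ms)
  empty <- data.frame(mono_mz = numeric(0), z = integer(0),
                      intensity = numeric(0), scan_time_ms = numeric(0),
                      lo_ms = numeric(0), hi_ms = numeric(0),
                      ook0 = numeric(0), n_iso = integer(0),
                      entry_id = integer(0))
  if (nrow(tr) < 2) return(empty)
  tr <- tr[order(tr$mz), ]
  n <- nrow(tr)
  claimed <- rep(FALSE, n)
  c_idx <- integer(0); c_z <- integer(0); c_int <- numeric(0)
  c_niso <- integer(0)
  for (i in seq_len(n)) {
    if (claimed[i]) next
    for (z in seq_len(max_z)) {
      members <- i
      cur <- i
      repeat {
        want <- tr$mz[cur] + .ISOTOPE_SPACING / z
        tol <- max(0.01, tr$mz[cur] * 2e-5)
        j <- which(!claimed & abs(tr$mz - want) <= tol &
                     abs(tr$apex_bin - tr$apex_bin[i]) <= 4)
        j <- setdiff(j, members)
        if (length(j) == 0) break
        j <- j[which.min(abs(tr$mz[j] - want))]
        members <- c(members, j)
        cur <- j
        if (length(members) >= 4) break
      }
      if (length(members) >= 2) {
        # plausibility of the M+1/M ratio for a CHO-dominated ion of
        # this mass (approximately one carbon per 14 Da)
        r1 <- tr$intensity[members[2]] / tr$intensity[members[1]]
        expected <- (tr$mz[i] * z / 14) * 0.0108
        if (r1 > 0.2 * expected && r1 < 3 * expected && r1 < 1.6) {
          claimed[members] <- TRUE
          c_idx <- c(c_idx, i); c_z <- c(c_z, z)
          c_int <- c(c_int, sum(tr$intensity[members]))
          c_niso <- c(c_niso, length(members))
          break
        }
      }
    }
  }
  if (length(c_idx) == 0) return(empty)
  st <- (tr$apex_bin[c_idx] + 0.5) * config$bin_ms
  out <- data.frame(mono_mz = tr$mz[c_idx], z = c_z, intensity = c_int,
                    scan_time_ms = st, lo_ms = tr$lo_ms[c_idx],
                    hi_ms = tr$hi_ms[c_idx],
                    ook0 = scan_time_to_ook0(cal, st),
                    n_iso = c_niso, entry_id = tr$entry_id[c_idx])
  out <- out[out$intensity >= config$intensity_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact optimal single-ramp selection under the run-to-deadline policy:
# a scheduled target occupies [max(lo, prev_hi + switch), hi]; feasible
# if the dwell is at least min_dwell and hi fits inside the ramp.
# Dynamic programme over candidates sorted by window end, maximising
# target count with summed intensity as tie-break.
.schedule_ramp <- function(cand, config) {
  if (nrow(cand) == 0) return(integer(0))
  keep <- cand$hi_ms <= config$ramp_ms &
    pmax(cand$lo_ms, 0) + config$min_dwell_ms <= cand$hi_ms
  idx <- which(keep)
  if (length(idx) == 0) return(integer(0))
  cc <- cand[idx, ]
  ord <- order(cc$hi_ms)
  cc <- cc[ord, ]; idx <- idx[ord]
  n <- nrow(cc)
  cnt <- integer(n); val <- numeric(n); prev <- integer(n)
  for (i in seq_len(n)) {
    cnt[i] <- 1L; val[i] <- cc$intensity[i]; prev[i] <- 0L
    for (j in seq_len(i - 1)) {
      start <- max(cc$lo_ms[i], cc$hi_ms[j] + config$switch_ms)
      if (start + config$min_dwell_ms <= cc$hi_ms[i]) {
        c2 <- cnt[j] + 1L; v2 <- val[j] + cc$intensity[i]
        if (c2 > cnt[i] || (c2 == cnt[i] && v2 > val[i])) {
          cnt[i] <- c2; val[i] <- v2; prev[i] <- j
        }
      }
    }
  }
  best <- which(cnt == max(cnt))
  best <- best[which.max(val[best])]
  sel <- integer(0)
  while (best > 0) { sel <- c(best, sel); best <- prev[best] }
  idx[sel]
}

#' Schedule precursors for PASEF MS/MS ramps
#'
#' For each of the cycle's MS/MS ramps, selects the largest feasible
#' set of candidates whose mobility scan-time windows can be visited
#' serially with at least the quadrupole switching time between
#' targets (exact interval-scheduling optimum; ties broken by summed
#' intensity). Candidates whose cumulative sampled intensity is below
#' the target value are re-scheduled on later ramps; candidates at or
#' above it are dropped from subsequent ramps (and dynamically excluded
#' by the acquisition loop).
#'
#' @param candidates from [detect_candidates()] (one MS1 frame),
#'   optionally with a `cum_intensity` column from previous cycles.
#' @param config a [run_config()].
#' @param n_ramps number of MS/MS ramps to fill.
#' @return data.frame of scheduled targets with `ramp`, the candidate
#'   columns, and `iso_lo_ms`/`iso_hi_ms` scheduling interval.
#' @export
schedule_pasef <- function(candidates, config = run_config(),
                           n_ramps = config$ramps_per_cycle) {
  if (is.null(candidates$cum_intensity))
    candidates$cum_intensity <- 0
  out <- list()
  cum <- candidates$cum_intensity
  for (r in seq_len(n_ramps)) {
    eligible <- which(cum < config$intensity_target)
    sel <- .schedule_ramp(candidates[eligible, , drop = FALSE], config)
    sel <- eligible[sel]
    if (length(sel) > 0) {
      tg <- candidates[sel, , drop = FALSE]
      tg$ramp <- r
      out[[r]] <- tg
      cum[sel] <- cum[sel] + tg$intensity
    }
  }
  if (length(out) == 0) {
    res <- candidates[0, , drop = FALSE]
    res$ramp <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Schedule standard (non-PASEF) TIMS-MS/MS
#'
#' One precursor per ramp: the quadrupole holds the most intense
#' remaining candidate's mass for the entire ramp. Same repeat and
#' exclusion accounting as PASEF.
#'
#' @inheritParams schedule_pasef
#' @export
schedule_standard <- function(candidates, config = run_config(),
                              n_ramps = config$ramps_per_cycle) {
  if (is.null(candidates$cum_intensity))
    candidates$cum_intensity <- 0
  cum <- candidates$cum_intensity
  out <- list()
  for (r in seq_len(n_ramps)) {
    eligible <- which(cum < config$intensity_target)
    if (length(eligible) == 0) next
    sel <- eligible[which.max(candidates$intensity[eligible])]
    tg <- candidates[sel, , drop = FALSE]
    # the quadrupole holds this mass for the entire ramp
    tg$lo_ms <- 0
    tg$hi_ms <- config$ramp_ms
    tg$ramp <- r
    out[[length(out) + 1]] <- tg
    cum[sel] <- cum[sel] + tg$intensity
  }
  if (length(out) == 0) {
    res <- candidates[0, , drop = FALSE]
    res$ramp <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
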