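# MS/MS frame rendering and the full data-dependent acquisition loop.

# relative fragment yields by rule kind; sterol precursors dominate
# their spectra (precursor-is-base-peak acceptance rule)
.FRAG_YIELD <- c(diagnostic = 1.0, neutral_loss = 0.5, chain_nl = 0.35,
                 chain_carboxylate = 0.8, n_type = 0.5)
.PRECURSOR_YIELD <- c(GL = 0.3, GP = 0.25, SP = 0.3, ST = 2.0)

# lazily built fragment tables per ground-truth entry
.entry_fragments <- function(lipidome, cache) {
  function(entry_row) {
    key <- as.character(lipidome$entry_id[entry_row])
    tab <- get0(key, envir = cache)
    if (!is.null(tab)) return(tab)
    sp <- parse_lipid_name(lipidome$chain_name[entry_row])
    tab <- suppressWarnings(expected_fragments(
      sp, lipidome$adduct[entry_row], lipidome$polarity[entry_row]))
    if (nrow(tab) > 0)
      tab$yield <- unname(.FRAG_YIELD[tab$kind])
    assign(key, tab, envir = cache)
    tab
  }
}

#' Render MS/MS frames for scheduled targets
#'
#' Fragment centroids are placed at the precursor's mobility position;
#' fragment intensities are proportional to the precursor ion count
#' sampled during the target's scan-time window (Gaussian mobility
#' profile overlap), so halving the window halves the spectrum. When the
#' quadrupole window covers several co-eluting species the spectrum is
#' chimeric. A residual precursor peak is always rendered; for sterols
#' it dominates the spectrum.
#'
#' @param targets data.frame of scheduled targets with columns
#'   `event_id`, `time_s`, `mono_mz`, `lo_ms`, `hi_ms`.
#' @param lipidome ground truth from [generate_lipidome()].
#' @param config a [run_config()].
#' @param cal a `tims_calibration`.
#' @return data.frame spectra: `event_id`, `mz`, `intensity`,
#'   `entry_id` provenance.
#' @export
render_msms <- function(targets, lipidome, config = run_config(),
                        cal = NULL) {
  if (is.null(cal))
    cal <- default_calibration(config$ramp_ms, config$ook0_range)
  cache <- new.env(parent = emptyenv())
  getfrag <- .entry_fragments(lipidome, cache)
  lip <- lipidome
  lip$scan_time_ms <- ook0_to_scan_time(cal, lip$ook0)
  lip$sigma_rt <- lip$rt_fwhm_s / (2 * sqrt(2 * log(2)))
  lip$sigma_ms <- lip$mob_fwhm_ms / (2 * sqrt(2 * log(2)))
  ord <- order(lip$mz)
  mz_sorted <- lip$mz[ord]
  a_ev <- list(); a_mz <- list(); a_int <- list(); a_eid <- list()
  p <- 0L
  for (t in seq_len(nrow(targets))) {
    tg_ev <- targets$event_id[t]
    lo <- findInterval(targets$mono_mz[t] - config$isolation_th,
                       mz_sorted) + 1
    hi <- findInterval(targets$mono_mz[t] + config$isolation_th,
                       mz_sorted)
    if (hi < lo) next
    rows <- ord[lo:hi]
    rows <- rows[abs(lip$rt_s[rows] - targets$time_s[t]) <=
                   3.5 * lip$sigma_rt[rows]]
    for (k in rows) {
      frame_int <- lip$abundance[k] *
        stats::dnorm(targets$time_s[t], lip$rt_s[k], lip$sigma_rt[k]) *
        config$cycle_s
      frac <- stats::pnorm(targets$hi_ms[t], lip$scan_time_ms[k],
                           lip$sigma_ms[k]) -
        stats::pnorm(targets$lo_ms[t], lip$scan_time_ms[k],
                     lip$sigma_ms[k])
      sampled <- frame_int * frac
      if (sampled < 1) next
      fr <- getfrag(k)
      pmz <- lip$mz[k]
      pint <- sampled * .PRECURSOR_YIELD[[lip$category[k]]]
      p <- p + 1L
      if (nrow(fr) > 0) {
        a_mz[[p]] <- c(fr$mz, pmz)
        a_int[[p]] <- c(sampled * fr$yield, pint)
      } else {
        a_mz[[p]] <- pmz
        a_int[[p]] <- pint
      }
      a_ev[[p]] <- rep(tg_ev, length(a_mz[[p]]))
      a_eid[[p]] <- rep(lip$entry_id[k], length(a_mz[[p]]))
    }
  }
  if (p == 0L)
    return(data.frame(event_id = integer(0), mz = numeric(0),
                      intensity = numeric(0), entry_id = integer(0)))
  res <- data.frame(event_id = unlist(a_ev), mz = unlist(a_mz),
                    intensity = unlist(a_int), entry_id = unlist(a_eid))
  res <- res[order(res$event_id, res$mz), ]
  rownames(res) <- NULL
  res
}

#' Run a full data-dependent acquisition
#'
#' Replays the acquisition cycle over a rendered MS1 frame stream: per
#' 0.4-s cycle, one MS1 frame is inspected for isotope-pattern
#' candidates, three MS/MS ramps are scheduled (PASEF or standard mode)
#' and their spectra rendered. Precursors are tracked across cycles:
#' low-abundance precursors (above the 100-count threshold but below
#' the 4000-count target) are repeatedly scheduled until the target is
#' reached, after which they are dynamically excluded for 0.2 min.
#'
#' @param frame_data from [render_frames()].
#' @param lipidome the ground truth that produced the frames.
#' @param mode `"pasef"` or `"standard"`.
#' @param config a [run_config()].
#' @return object of class `acquisition`: `events` (one row per MS/MS
#'   event: run time, ramp, isolation m/z and scan-time window,
#'   mobility, collision energy, repeat index, precursor track id),
#'   `spectra`, `tracks`, `frame_stats`, plus mode/config/cal.
#' @export
run_acquisition <- function(frame_data, lipidome,
                            mode = c("pasef", "standard"),
                            config = frame_data$config) {
  mode <- match.arg(mode)
  cal <- frame_data$cal
  peaks <- frame_data$peaks
  frames <- frame_data$frames
  by_frame <- split(seq_len(nrow(peaks)), peaks$frame)

  tracks <- data.frame(track_id = integer(0), mz = numeric(0),
                       ook0 = numeric(0), cum_intensity = numeric(0),
                       n_events = integer(0), last_seen = numeric(0),
                       excluded_until = numeric(0))
  next_track <- 1L
  events <- vector("list", nrow(frames))
  frame_stats <- data.frame(frame = frames$frame,
                            time_s = frames$time_s,
                            n_candidates = 0L, n_targets = 0L)
  scheduler <- if (mode == "pasef") schedule_pasef else schedule_standard
  next_event <- 1L

  for (fi in seq_len(nrow(frames))) {
    tnow <- frames$time_s[fi]
    ii <- by_frame[[as.character(frames$frame[fi])]]
    if (is.null(ii)) next
    cand <- detect_candidates(peaks[ii, , drop = FALSE], config, cal)
    frame_stats$n_candidates[fi] <- nrow(cand)
    if (nrow(cand) == 0) next

    # match candidates to known precursor tracks
    cand$track_id <- NA_integer_
    cand$cum_intensity <- 0
    if (nrow(tracks) > 0) {
      for (ci in seq_len(nrow(cand))) {
        hit <- which(abs(tracks$mz - cand$mono_mz[ci]) <= 0.02 &
                       abs(tracks$ook0 - cand$ook0[ci]) <= 0.05)
        if (length(hit) > 0) {
          hit <- hit[which.min(abs(tracks$mz[hit] - cand$mono_mz[ci]))]
          cand$track_id[ci] <- tracks$track_id[hit]
          cand$cum_intensity[ci] <- tracks$cum_intensity[hit]
        }
      }
    }
    new <- which(is.na(cand$track_id))
    if (length(new) > 0) {
      ids <- next_track + seq_along(new) - 1L
      cand$track_id[new] <- ids
      next_track <- next_track + length(new)
      tracks <- rbind(tracks, data.frame(
        track_id = ids, mz = cand$mono_mz[new], ook0 = cand$ook0[new],
        cum_intensity = 0, n_events = 0L, last_seen = tnow,
        excluded_until = 0))
    }
    ti <- match(cand$track_id, tracks$track_id)
    tracks$last_seen[ti] <- tnow
    tracks$mz[ti] <- cand$mono_mz
    tracks$ook0[ti] <- cand$ook0

    # dynamic exclusion gate
    open <- which(tracks$excluded_until[ti] <= tnow)
    if (length(open) == 0) next
    sched <- scheduler(cand[open, , drop = FALSE], config)
    if (nrow(sched) == 0) next
    frame_stats$n_targets[fi] <- nrow(sched)

    sched$event_id <- next_event + seq_len(nrow(sched)) - 1L
    next_event <- next_event + nrow(sched)
    sched$cycle <- fi
    sched$time_s <- tnow
    sched$ce <- collision_energy(sched$ook0, config$polarity, config)
    # bookkeeping: cumulative sampled intensity and repeat index
    sti <- match(sched$track_id, tracks$track_id)
    reps <- integer(nrow(sched))
    for (si in seq_len(nrow(sched))) {
      tracks$cum_intensity[sti[si]] <-
        tracks$cum_intensity[sti[si]] + sched$intensity[si]
      tracks$n_events[sti[si]] <- tracks$n_events[sti[si]] + 1L
      reps[si] <- tracks$n_events[sti[si]]
      if (tracks$cum_intensity[sti[si]] >= config$intensity_target)
        tracks$excluded_until[sti[si]] <- tnow + config$exclusion_s
    }
    sched$repeat_index <- reps
    events[[fi]] <- sched

    # release cumulative bookkeeping for tracks whose MS1 feature ended
    stale <- tracks$last_seen < tnow - 3 * config$cycle_s &
      tracks$excluded_until <= tnow
    if (any(stale)) tracks$cum_intensity[stale] <- 0
  }

  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(event_id = integer(0), cycle = integer(0),
                         time_s = numeric(0), ramp = integer(0),
                         mono_mz = numeric(0), z = integer(0),
                         intensity = numeric(0), scan_time_ms = numeric(0),
                         lo_ms = numeric(0), hi_ms = numeric(0),
                         ook0 = numeric(0), ce = numeric(0),
                         track_id = integer(0), repeat_index = integer(0),
                         entry_id = integer(0))
    spectra <- data.frame(event_id = integer(0), mz = numeric(0),
                          intensity = numeric(0), entry_id = integer(0))
  } else {
    rownames(events) <- NULL
    spectra <- render_msms(events, lipidome, config, cal)
  }
  structure(list(events = events, spectra = spectra, tracks = tracks,
                 frame_stats = frame_stats, mode = mode, config = config,
                 cal = cal),
            class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  ncyc <- nrow(x$frame_stats)
  cat("<acquisition> ", x$mode, " mode: ", nrow(x$events),
      " MS/MS events over ", ncyc, " cycles (mean ",
      round(mean(x$frame_stats$n_targets / x$config$ramps_per_cycle), 2),
      " targets/ramp)\n", sep = "")
  invisible(x)
}

#' Acquisition summary statistics
#'
#' @param acq an `acquisition`.
#' @return list: `n_msms`, `mean_targets_per_ramp` (over ramps of
#'   cycles with at least one candidate), `msms_rate_hz`, `mean_repeat`
#'   (MS/MS events per distinct fragmented precursor).
#' @export
acquisition_stats <- function(acq) {
  cfg <- acq$config
  active <- acq$frame_stats$n_candidates > 0
  mean_tpr <- if (any(active))
    mean(acq$frame_stats$n_targets[active]) / cfg$ramps_per_cycle else 0
  list(n_msms = nrow(acq$events),
       mean_targets_per_ramp = mean_tpr,
       msms_rate_hz = mean_tpr * cfg$ramps_per_cycle / cfg$cycle_s,
       mean_repeat = if (nrow(acq$events) > 0)
         nrow(acq$events) / length(unique(acq$events$track_id)) else 0)
}
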