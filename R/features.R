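# 4D MS1 feature detection, adduct collapsing, and MS/MS-to-feature
# assignment. This is the package's documented replacement for
# proprietary 4D feature finders: per-frame mobility traces are clustered
# over m/z, split at mobility valleys (resolving co-eluting isomers),
# traced over retention time with a 2-frame gap tolerance, grouped into
# isotope envelopes, and integrated.

# split a mobility intensity profile at valleys between local maxima;
# returns an apex label per input row
.split_mobility <- function(bin, intensity, min_sep_bins = 5,
                            valley_frac = 0.5) {
  ub <- sort(unique(bin))
  prof <- as.vector(rowsum(intensity, bin))
  if (length(ub) < 2 * min_sep_bins) return(rep(1L, length(bin)))
  is_max <- vapply(seq_along(ub), function(i) {
    lo <- max(1, i - 2); hi <- min(length(ub), i + 2)
    prof[i] == max(prof[lo:hi])
  }, logical(1))
  apex <- which(is_max & prof >= 0.25 * max(prof))
  if (length(apex) <= 1) return(rep(1L, length(bin)))
  # merge apexes closer than the minimum separation or without a deep
  # valley between them
  keep <- apex[1]
  for (a in apex[-1]) {
    prevk <- keep[length(keep)]
    valley <- min(prof[prevk:a])
    if (ub[a] - ub[prevk] >= min_sep_bins &&
        valley < valley_frac * min(prof[a], prof[prevk])) {
      keep <- c(keep, a)
    } else if (prof[a] > prof[prevk]) {
      keep[length(keep)] <- a
    }
  }
  if (length(keep) == 1) return(rep(1L, length(bin)))
  # assign each bin to the nearest surviving apex (boundary at the
  # valley minimum between consecutive apexes)
  bounds <- vapply(seq_len(length(keep) - 1), function(i) {
    seg <- keep[i]:keep[i + 1]
    ub[seg[which.min(prof[seg])]]
  }, numeric(1))
  findInterval(bin, c(-Inf, bounds)) |> as.integer()
}

#' Extract 4D features from MS1 frames
#'
#' Clusters centroids by m/z, splits clusters at mobility valleys and
#' retention-time gaps (more than 2 missing frames end a trace), groups
#' co-eluting traces into isotope envelopes by their 1.00336/z spacing,
#' estimates apexes by intensity-weighted centroids, and integrates the
#' feature volume. Features below the intensity threshold (500 counts
#' positive mode, 200 negative) or with fewer than `min_points` 4D data
#' points (frame x mobility-bin x isotope centroids) are dropped.
#'
#' @param frame_data from [render_frames()] (or any object with the same
#'   `peaks`/`cal`/`config` layout).
#' @param config a [run_config()].
#' @param recursive logical; recursive mode lowers the minimum point
#'   count to 50 (second-pass extraction seeded by unexplained MS/MS
#'   precursors).
#' @param max_z maximum charge state.
#' @return data.frame of features: `feature_id`, `mz`, `z`, `rt_s`,
#'   `rt_lo_s`, `rt_hi_s`, `rt_fwhm_s`, `scan_time_ms`, `mob_fwhm_ms`,
#'   `ook0`, `ccs`, `intensity`, `n_points`, `n_iso`, `entry_id`
#'   (ground-truth provenance of the dominant centroids, `NA` for
#'   noise-born features).
#' @export
extract_features <- function(frame_data, config = frame_data$config,
                             recursive = FALSE, max_z = 2) {
  pk <- frame_data$peaks
  cal <- frame_data$cal
  min_pts <- if (recursive) 50 else config$min_points
  thr <- if (config$polarity == "positive")
    config$feature_threshold_pos else config$feature_threshold_neg
  empty <- data.frame(feature_id = integer(0), mz = numeric(0),
                      z = integer(0), rt_s = numeric(0),
                      rt_lo_s = numeric(0), rt_hi_s = numeric(0),
                      rt_fwhm_s = numeric(0), scan_time_ms = numeric(0),
                      mob_fwhm_ms = numeric(0), ook0 = numeric(0),
                      ccs = numeric(0), intensity = numeric(0),
                      n_points = integer(0), n_iso = integer(0),
                      entry_id = integer(0))
  if (nrow(pk) == 0) return(empty)

  # m/z clustering (single linkage on sorted gaps)
  pk <- pk[order(pk$mz), ]
  # flat absolute tolerance: centroid m/z is exact in the simulator, and
  # 0.0022 Da resolves the closest systematic interference (sodium
  # adduct vs +2 C / +3 double bonds, 0.00245 Da) at any lipid m/z
  mzg <- cumsum(c(TRUE, diff(pk$mz) > 0.0022))

  # mobility splitting within each m/z cluster, then RT tracing
  segs <- vector("list", 2048); nseg <- 0L
  for (ii in split(seq_len(nrow(pk)), mzg)) {
    q <- pk[ii, ]
    mob <- .split_mobility(q$bin, q$intensity)
    for (jj in split(seq_len(nrow(q)), mob)) {
      r <- q[jj, ]
      r <- r[order(r$frame, r$bin), ]
      uf <- unique(r$frame)
      fgrp <- cumsum(c(TRUE, diff(uf) > 3))  # gap tolerance 2 frames
      rgrp <- fgrp[match(r$frame, uf)]
      for (kk in split(seq_len(nrow(r)), rgrp)) {
        s0 <- r[kk, ]
        # chromatographic valley split: partially overlapping isobars
        # with distinct elution apexes become separate traces
        rtg <- .split_mobility(s0$frame, s0$intensity, min_sep_bins = 8,
                               valley_frac = 0.7)
        for (ll in split(seq_len(nrow(s0)), rtg)) {
        s <- s0[ll, ]
        nseg <- nseg + 1L
        if (nseg > length(segs)) segs <- c(segs, vector("list", nseg))
        tot <- sum(s$intensity)
        # half-height widths from the marginal profiles
        fprof <- rowsum(s$intensity, s$frame)
        fmax <- max(fprof[, 1])
        fk <- as.numeric(rownames(fprof))[fprof[, 1] >= fmax / 2]
        bprof <- rowsum(s$intensity, s$bin)
        bmax <- max(bprof[, 1])
        bk <- as.numeric(rownames(bprof))[bprof[, 1] >= bmax / 2]
        eid <- s$entry_id[!is.na(s$entry_id)]
        segs[[nseg]] <- c(
          mz = sum(s$mz * s$intensity) / tot,
          intensity = tot,
          rt = sum(s$time_s * s$intensity) / tot,
          rt_lo = min(s$time_s), rt_hi = max(s$time_s),
          rt_fwhm = (max(fk) - min(fk) + 1) *
            diff(s$time_s[!duplicated(s$frame)])[1] %||% config$cycle_s,
          st = sum(s$scan_time_ms * s$intensity) / tot,
          mob_fwhm = (max(bk) - min(bk) + 1) * config$bin_ms,
          npts = nrow(s),
          nframes = length(unique(s$frame)),
          eid = if (length(eid)) as.integer(names(which.max(
            table(eid)))) else NA_integer_)
        }
      }
    }
  }
  if (nseg == 0) return(empty)
  seg <- as.data.frame(do.call(rbind, segs[seq_len(nseg)]))
  # prune single-flash segments (noise): require persistence
  seg <- seg[seg$nframes >= 3, , drop = FALSE]
  if (nrow(seg) == 0) return(empty)

  # isotope grouping over segments
  seg <- seg[order(seg$mz), ]
  n <- nrow(seg)
  claimed <- rep(FALSE, n)
  feats <- vector("list", n); nf <- 0L
  ord_int <- order(-seg$intensity)
  for (i0 in ord_int) {
    if (claimed[i0]) next
    # walk down in m/z: i0 must be monoisotopic, so check that no
    # unclaimed segment sits one spacing below with coherent RT/mobility
    best <- NULL
    for (z in seq_len(max_z)) {
      iso_tol <- 0.0022
      below <- which(!claimed & abs(seg$mz - (seg$mz[i0] -
        .ISOTOPE_SPACING / z)) <= iso_tol &
        abs(seg$rt - seg$rt[i0]) <= 2 &
        abs(seg$st - seg$st[i0]) <= 2 &
        seg$intensity > seg$intensity[i0])
      if (length(below) > 0) { best <- NULL; break }
      members <- i0; cur <- i0
      repeat {
        want <- seg$mz[cur] + .ISOTOPE_SPACING / z
        j <- which(!claimed & abs(seg$mz - want) <= iso_tol &
                     abs(seg$rt - seg$rt[i0]) <= 2 &
                     abs(seg$st - seg$st[i0]) <= 2)
        j <- setdiff(j, members)
        if (length(j) == 0) break
        j <- j[which.min(abs(seg$mz[j] - want))]
        members <- c(members, j); cur <- j
        if (length(members) >= 5) break
      }
      score <- length(members)
      if (is.null(best) || score > best$score)
        best <- list(members = members, z = z, score = score)
      if (score >= 2) break  # prefer low charge when an envelope exists
    }
    if (is.null(best)) next
    members <- best$members
    claimed[members] <- TRUE
    nf <- nf + 1L
    m0 <- members[1]
    ion_mass <- seg$mz[m0] * best$z
    ook0 <- scan_time_to_ook0(cal, seg$st[m0])
    feats[[nf]] <- data.frame(
      mz = seg$mz[m0], z = best$z, rt_s = seg$rt[m0],
      rt_lo_s = min(seg$rt_lo[members]), rt_hi_s = max(seg$rt_hi[members]),
      rt_fwhm_s = seg$rt_fwhm[m0], scan_time_ms = seg$st[m0],
      mob_fwhm_ms = seg$mob_fwhm[m0], ook0 = ook0,
      ccs = mobility_to_ccs(ook0, ion_mass, best$z),
      intensity = sum(seg$intensity[members]),
      n_points = as.integer(sum(seg$npts[members])),
      n_iso = length(members),
      entry_id = seg$eid[m0])
  }
  if (nf == 0) return(empty)
  out <- do.call(rbind, feats[seq_len(nf)])
  # deisotoping cleanup: a single-isotope feature sitting one or two
  # spacings above a co-eluting envelope is an orphaned isotope trace
  # from a chimeric m/z cluster, not a species
  if (nrow(out) > 1) {
    drop <- rep(FALSE, nrow(out))
    for (i in which(out$n_iso == 1)) {
      for (k in 1:3) {
        hit <- which(abs(out$mz + k * .ISOTOPE_SPACING / out$z -
                           out$mz[i]) <= 0.005 &
                       abs(out$rt_s - out$rt_s[i]) <= 4 &
                       out$intensity > out$intensity[i])
        hit <- setdiff(hit, i)
        if (length(hit) > 0) { drop[i] <- TRUE; break }
      }
    }
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[out$intensity >= thr & out$n_points >= min_pts, ,
             drop = FALSE]
  out <- out[order(out$mz), ]
  out$feature_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("feature_id", setdiff(names(out), "feature_id"))]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Collapse adduct series into feature groups
#'
#' Features co-eluting in retention time (apex difference within half the
#' narrower RT FWHM, configurable) whose mass difference matches an
#' inter-adduct delta (e.g. +21.98194 for sodium vs proton) within the
#' ppm tolerance share an adduct group; mobility may differ between
#' adducts.
#'
#' @param features from [extract_features()].
#' @param config a [run_config()] (supplies polarity and ppm tolerance).
#' @param adducts adduct table.
#' @param rt_tol_s co-elution tolerance in seconds; default half the
#'   median feature RT FWHM.
#' @return `features` with an `adduct_group` column.
#' @export
collapse_adducts <- function(features, config = run_config(),
                             adducts = default_adducts(),
                             rt_tol_s = NULL) {
  if (nrow(features) == 0) {
    features$adduct_group <- integer(0)
    return(features)
  }
  if (is.null(rt_tol_s))
    rt_tol_s <- stats::median(features$rt_fwhm_s) / 2
  ad <- adducts[adducts$polarity == config$polarity, ]
  deltas <- unique(round(as.vector(outer(ad$mz_offset, ad$mz_offset, "-")),
                         6))
  deltas <- deltas[deltas > 0.1]
  parent <- seq_len(nrow(features))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  o <- order(features$mz)
  mzs <- features$mz[o]
  for (a in seq_along(o)) {
    for (b in seq_len(a - 1)) {
      dm <- mzs[a] - mzs[b]
      if (dm > max(deltas) + 0.1) next
      ia <- o[a]; ib <- o[b]
      if (abs(features$rt_s[ia] - features$rt_s[ib]) > rt_tol_s) next
      if (features$z[ia] != features$z[ib]) next
      tol <- config$prec_ppm * 1e-6 * mzs[a]
      if (any(abs(dm - deltas) <= tol)) {
        ra <- find(ia); rb <- find(ib)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  grp <- vapply(seq_len(nrow(features)), find, integer(1))
  features$adduct_group <- match(grp, unique(grp))
  features
}

#' Assign MS/MS events to features
#'
#' An event links to a feature when the quadrupole window contains the
#' feature m/z, the event's mobility position lies within the feature's
#' mobility FWHM, and the event time falls within the feature's RT
#' bounds. When several features satisfy all gates the nearest in
#' (m/z, mobility) wins and the link is flagged chimeric. Repeated
#' events of one precursor are merged into a single summed spectrum per
#' feature.
#'
#' @param features from [extract_features()] (or [collapse_adducts()]).
#' @param acq an `acquisition`.
#' @param config a [run_config()].
#' @return `features` with columns `n_msms`, `chimeric`; the summed
#'   spectra are attached as attribute `"spectra"` (a list keyed by
#'   `feature_id` with data.frames `mz`/`intensity`).
#' @export
assign_msms <- function(features, acq, config = acq$config) {
  features$n_msms <- rep(0L, nrow(features))
  features$chimeric <- rep(FALSE, nrow(features))
  spectra <- vector("list", nrow(features))
  names(spectra) <- as.character(features$feature_id)
  ev <- acq$events
  if (nrow(ev) > 0 && nrow(features) > 0) {
    links <- integer(nrow(ev))
    half_mob <- features$mob_fwhm_ms / 2
    for (e in seq_len(nrow(ev))) {
      ok <- which(abs(features$mz - ev$mono_mz[e]) <= config$isolation_th &
                    abs(features$scan_time_ms - ev$scan_time_ms[e]) <=
                      half_mob &
                    ev$time_s[e] >= features$rt_lo_s - 1e-9 &
                    ev$time_s[e] <= features$rt_hi_s + 1e-9)
      if (length(ok) == 0) { links[e] <- NA_integer_; next }
      if (length(ok) > 1) {
        d <- abs(features$mz[ok] - ev$mono_mz[e]) / config$isolation_th +
          abs(features$scan_time_ms[ok] - ev$scan_time_ms[e]) /
            pmax(half_mob[ok], 0.5)
        ok <- ok[which.min(d)]
        features$chimeric[ok] <- TRUE
      }
      links[e] <- ok
    }
    sp <- acq$spectra
    for (fi in unique(links[!is.na(links)])) {
      lk <- which(links == fi)
      features$n_msms[fi] <- length(lk)
      # sum only events of the feature's own precursor when any exist;
      # events merely co-isolating the feature stay out of the summed
      # spectrum
      own <- lk[abs(ev$mono_mz[lk] - features$mz[fi]) <= 0.015]
      if (length(own) > 0) lk <- own
      eids <- ev$event_id[lk]
      ss <- sp[sp$event_id %in% eids, , drop = FALSE]
      if (nrow(ss) == 0) next
      # sum repeated events: merge centroids within 0.005 Da
      ss <- ss[order(ss$mz), ]
      g <- cumsum(c(TRUE, diff(ss$mz) > 0.005))
      merged <- data.frame(
        mz = as.vector(rowsum(ss$mz * ss$intensity, g)) /
          as.vector(rowsum(ss$intensity, g)),
        intensity = as.vector(rowsum(ss$intensity, g)))
      spectra[[as.character(features$feature_id[fi])]] <- merged
    }
  }
  attr(features, "spectra") <- spectra
  features
}
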