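# constructed candidate tables for scheduler tests
make_cands <- function(lo, hi, intensity = 1000) {
  data.frame(mono_mz = 500 + seq_along(lo), z = 1L,
             intensity = rep_len(intensity, length(lo)),
             scan_time_ms = (lo + hi) / 2, lo_ms = lo, hi_ms = hi,
             ook0 = 1, n_iso = 3L, entry_id = NA_integer_)
}

test_that("collision energy interpolates linearly over the mobility range", {
  cfg <- run_config()
  expect_equal(collision_energy(0.6, "positive", cfg), 25)
  expect_equal(collision_energy(1.95, "positive", cfg), 45)
  expect_equal(collision_energy(1.275, "positive", cfg), 35)
  expect_equal(collision_energy(0.6, "negative", cfg), 35)
  expect_equal(collision_energy(1.95, "negative", cfg), 55)
  expect_warning(ce <- collision_energy(2.2, "positive", cfg), "clamp")
  expect_equal(ce, 45)
})

test_that("candidate detection finds clean envelopes and applies the threshold", {
  cfg <- run_config()
  mkframe <- function(mz0, bins, base) {
    do.call(rbind, lapply(seq_along(bins), function(i)
      data.frame(bin = bins[i],
                 mz = mz0 + c(0, 1, 2) * 1.00336,
                 intensity = base[i] * c(1, 0.45, 0.12),
                 entry_id = 1L)))
  }
  fp <- mkframe(760.5851, 58:64, c(40, 150, 400, 600, 380, 160, 45))
  cand <- detect_candidates(fp, cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$mono_mz, 760.5851, tolerance = 1e-6)
  expect_equal(cand$z, 1L)
  expect_equal(cand$n_iso, 3L)
  # apex bin 61 at 0.5 ms bins
  expect_equal(cand$scan_time_ms, 30.75)
  # envelope summing to less than 100 counts is rejected
  weak <- mkframe(760.5851, 60:62, c(10, 25, 12))
  expect_equal(nrow(detect_candidates(weak, cfg)), 0)
  # two species separated by 10 ms in mobility give two candidates
  two <- rbind(mkframe(760.5851, 58:62, c(100, 300, 500, 280, 90)),
               mkframe(760.6951, 78:82, c(120, 350, 520, 300, 100)))
  expect_equal(nrow(detect_candidates(two, cfg)), 2)
  # a lone peak without isotope partner is not a candidate
  lone <- data.frame(bin = 60:62, mz = 500.5,
                     intensity = c(200, 500, 250), entry_id = NA)
  expect_equal(nrow(detect_candidates(lone, cfg)), 0)
})

test_that("contiguously tiled 6-ms windows yield 16 targets in one ramp", {
  lo <- 6 * (0:17); hi <- lo + 6
  cand <- make_cands(lo, hi)
  sched <- schedule_pasef(cand, run_config(), n_ramps = 1)
  expect_equal(nrow(sched), 16)  # windows ending beyond 100 ms drop out
  expect_equal(sort(sched$lo_ms), lo[1:16])
})

test_that("a weak candidate is rescheduled on every ramp of the cycle", {
  cand <- make_cands(40, 46, intensity = 500)
  sched <- schedule_pasef(cand, run_config())
  expect_equal(nrow(sched), 3)
  expect_equal(sched$ramp, 1:3)
  # a strong candidate is scheduled once
  strong <- make_cands(40, 46, intensity = 10000)
  expect_equal(nrow(schedule_pasef(strong, run_config())), 1)
})

test_that("ramp schedules are disjoint with switching gaps", {
  cfg <- run_config()
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    lo <- stats::runif(n, 0, 95)
    hi <- pmin(lo + stats::runif(n, 2, 12), 100)
    sched <- schedule_pasef(make_cands(lo, hi), cfg, n_ramps = 1)
    if (nrow(sched) < 2) next
    s <- sched[order(sched$hi_ms), ]
    gaps <- s$hi_ms[-1] - s$hi_ms[-nrow(s)]
    expect_true(all(gaps >= cfg$switch_ms - 1e-9))
    # each target retains at least the minimum dwell
    start <- pmax(s$lo_ms, c(0, s$hi_ms[-nrow(s)] + cfg$switch_ms))
    expect_true(all(s$hi_ms - start >= cfg$min_dwell_ms - 1e-9))
  }
})

test_that("the scheduler matches the brute-force optimum for small fixtures", {
  cfg <- run_config()
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(3:11, 1)
    lo <- stats::runif(n, 0, 96)
    hi <- pmin(lo + stats::runif(n, 2, 15), 102)
    sched <- schedule_pasef(make_cands(lo, hi), cfg, n_ramps = 1)
    opt <- oracle_schedule_count(data.frame(start = lo, end = hi),
                                 ramp_ms = cfg$ramp_ms,
                                 switch_ms = cfg$switch_ms,
                                 min_dwell_ms = cfg$min_dwell_ms)
    expect_equal(nrow(sched), opt, label = paste("fixture", rep))
  }
})

test_that("adding a candidate never decreases the scheduled count", {
  cfg <- run_config()
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    lo <- stats::runif(n, 0, 90)
    hi <- pmin(lo + stats::runif(n, 3, 10), 100)
    base <- nrow(schedule_pasef(make_cands(lo, hi), cfg, n_ramps = 1))
    lo2 <- c(lo, stats::runif(1, 0, 90))
    hi2 <- c(hi, min(lo2[n + 1] + 5, 100))
    more <- nrow(schedule_pasef(make_cands(lo2, hi2), cfg, n_ramps = 1))
    expect_gte(more, base)
  }
})

test_that("standard mode takes one precursor per ramp, PASEF at least as many", {
  cfg <- run_config()
  set.seed(41)
  lo <- stats::runif(20, 0, 90); hi <- pmin(lo + 5, 100)
  cand <- make_cands(lo, hi, intensity = stats::runif(20, 200, 3000))
  std <- schedule_standard(cand, cfg)
  expect_equal(nrow(std), 3)
  expect_equal(as.integer(table(std$ramp)), rep(1L, 3))
  # standard occupies the full ramp per target
  expect_true(all(std$lo_ms == 0 & std$hi_ms == cfg$ramp_ms))
  pasef <- schedule_pasef(cand, cfg)
  expect_gte(nrow(pasef), nrow(std))
  # the standard pick is the most intense eligible candidate
  expect_equal(std$intensity[1], max(cand$intensity))
})

test_that("acquisition honours dynamic exclusion and threshold rules", {
  cfg <- run_config(gradient_s = 40, seed = 19,
                    noise = list(enabled = FALSE))
  gt <- generate_lipidome(15, config = cfg)
  fd <- render_frames(gt, cfg)
  acq <- run_acquisition(fd, gt, "pasef", cfg)
  expect_gt(nrow(acq$events), 0)
  # every event's mobility position lies inside its scan-time window
  expect_true(all(acq$events$scan_time_ms >= acq$events$lo_ms - 1e-9 &
                    acq$events$scan_time_ms <= acq$events$hi_ms + 1e-9))
  # per track: once the cumulative target is reached, no further event
  # occurs within the exclusion time
  for (tid in unique(acq$events$track_id)) {
    ev <- acq$events[acq$events$track_id == tid, ]
    ev <- ev[order(ev$time_s, ev$ramp), ]
    cum <- cumsum(ev$intensity)
    k <- which(cum >= cfg$intensity_target)[1]
    if (!is.na(k) && k < nrow(ev)) {
      expect_gte(ev$time_s[k + 1], ev$time_s[k] + cfg$exclusion_s - 1e-9)
    }
  }
  # all scheduled candidates were above the intensity threshold
  expect_true(all(acq$events$intensity >= cfg$intensity_threshold))
})

test_that("an empty landscape yields MS1 frames only", {
  cfg <- run_config(gradient_s = 10, seed = 4,
                    noise = list(enabled = FALSE))
  gt <- generate_lipidome(3, config = cfg)[0, ]
  fd <- render_frames(gt, cfg)
  acq <- run_acquisition(fd, gt, "pasef", cfg)
  expect_equal(nrow(acq$events), 0)
  expect_equal(nrow(acq$spectra), 0)
})

test_that("low-abundance precursors are fragmented repeatedly on the benchmark", {
  pre <- benchmark_preset("plasma-scaled")
  gt <- generate_lipidome(pre$n_species, config = pre$config)
  fd <- render_frames(gt, pre$config)
  acq <- run_acquisition(fd, gt, "pasef", pre$config)
  st <- acquisition_stats(acq)
  # precursors are fragmented more than once on average (summed-spectrum
  # strategy); under the cumulative-target accounting the desk-scale
  # mean sits in the low single digits
  expect_gt(st$mean_repeat, 1.5)
  expect_lt(st$mean_repeat, 8)
})
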