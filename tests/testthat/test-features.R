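feat_cfg <- function(...) {
  run_config(gradient_s = 90, seed = 5,
             noise = list(enabled = FALSE), ...)
}

test_that("isolated species are recovered as single accurate features", {
  cfg <- feat_cfg()
  gt <- generate_lipidome(25, config = cfg)
  fd <- render_frames(gt, cfg)
  ft <- extract_features(fd)
  vol <- tapply(fd$peaks$intensity, fd$peaks$entry_id, sum)
  above <- as.integer(names(vol))[vol >= cfg$feature_threshold_pos]
  rec <- ft$entry_id[!is.na(ft$entry_id)]
  expect_true(all(above %in% rec))
  expect_lte(mean(table(rec)), 1.05)  # about one feature per entry
  m <- merge(ft, gt, by = "entry_id")
  expect_true(all(abs(1e6 * (m$mz.x - m$mz.y) / m$mz.y) < 1))
  expect_true(all(abs(m$ook0.x - m$ook0.y) / m$ook0.y < 0.002))
  expect_true(all(abs(m$rt_s.x - m$rt_s.y) < 0.5))
  # CCS recomputed from the feature mobility agrees with ground truth
  expect_lt(sqrt(mean(((m$ccs.x - m$ccs.y) / m$ccs.y * 100)^2)), 0.5)
  # intensity conservation for isolated, well-sampled peaks (species
  # near the rendering floor lose their sub-count tails)
  mm <- m[m$abundance >= 2e4, ]
  envs <- vapply(mm$formula, function(f)
    sum(isotope_pattern(f, 3)$abundance), numeric(1))
  expect_true(all(abs(mm$intensity / (mm$abundance * envs) - 1) < 0.05))
})

test_that("features below threshold or point minimum are dropped", {
  cfg <- feat_cfg()
  gt <- generate_lipidome(6, config = cfg, seed = 8)
  gt$abundance <- 180  # renders below the 500-count positive threshold
  fd <- render_frames(gt, cfg)
  expect_equal(nrow(extract_features(fd)), 0)
})

test_that("co-eluting mobility-separated isomers give two features", {
  cfg <- feat_cfg()
  gt <- generate_lipidome(4, config = cfg, seed = 12)[1:2, ]
  # same m/z and RT, mobility apexes more than 2x FWHM apart
  gt$mz <- 760.5851; gt$rt_s <- 45; gt$rt_fwhm_s <- 4
  gt$mob_fwhm_ms <- 2.5
  gt$formula <- "C42H82NO8P"
  gt$abundance <- c(5e4, 4e4)
  cal <- default_calibration()
  st <- c(50, 58)  # 8 ms apart
  gt$ook0 <- scan_time_to_ook0(cal, st)
  gt$ccs <- mobility_to_ccs(gt$ook0, gt$mz)
  gt$entry_id <- 1:2
  fd <- render_frames(gt, cfg)
  ft <- extract_features(fd)
  expect_equal(nrow(ft), 2)
  expect_equal(sort(ft$scan_time_ms), st, tolerance = 0.02)
})

test_that("extraction is idempotent on identical frames", {
  cfg <- feat_cfg()
  gt <- generate_lipidome(10, config = cfg, seed = 3)
  fd <- render_frames(gt, cfg)
  expect_identical(extract_features(fd), extract_features(fd))
})

test_that("adduct collapsing groups co-eluting adduct pairs only", {
  cfg <- feat_cfg()
  base <- data.frame(
    feature_id = 1:4, z = 1L,
    mz = c(760.5851, 782.5670, 760.5851 + 21.98194 / 2, 500.2),
    rt_s = c(45, 45, 200, 45), rt_fwhm_s = 4,
    rt_lo_s = 0, rt_hi_s = 0, scan_time_ms = 50, mob_fwhm_ms = 2.5,
    ook0 = 1.3, ccs = 280, intensity = 1e4, n_points = 200L,
    n_iso = 3L, entry_id = NA_integer_)
  base$mz[3] <- 782.5670   # same delta but 155 s later
  got <- collapse_adducts(base, cfg)
  expect_equal(got$adduct_group[1], got$adduct_group[2])
  expect_false(got$adduct_group[3] == got$adduct_group[1])
  expect_false(got$adduct_group[4] == got$adduct_group[1])
  # grouped count below raw count on a simulated run with multi-adduct
  gt <- generate_lipidome(40, config = cfg, seed = 6)
  fd <- render_frames(gt, cfg)
  ft <- collapse_adducts(extract_features(fd), cfg)
  expect_lt(length(unique(ft$adduct_group)), nrow(ft))
  # groups should not mix species
  m <- merge(ft, gt[, c("entry_id", "species_id")], by = "entry_id")
  mix <- tapply(m$species_id, m$adduct_group,
                function(x) length(unique(x)))
  # rare co-elution coincidences may bridge two species; the vast
  # majority of groups must be pure
  expect_gte(mean(mix == 1), 0.9)
})

test_that("MS/MS events link by window, mobility and retention gates", {
  cfg <- feat_cfg()
  gt <- generate_lipidome(20, config = cfg, seed = 14)
  fd <- render_frames(gt, cfg)
  ft <- collapse_adducts(extract_features(fd), cfg)
  acq <- run_acquisition(fd, gt, "pasef", cfg)
  fa <- assign_msms(ft, acq, cfg)
  expect_gt(sum(fa$n_msms > 0), 0)
  sp <- attr(fa, "spectra")
  expect_equal(sum(!vapply(sp, is.null, logical(1))),
               sum(fa$n_msms > 0))
  # an event far from every feature m/z stays unlinked
  fake <- acq
  fake$events <- acq$events[1, ]
  fake$events$mono_mz <- 1490
  fake$spectra <- acq$spectra[acq$spectra$event_id ==
                                fake$events$event_id, ]
  fb <- assign_msms(ft, fake, cfg)
  expect_equal(sum(fb$n_msms), 0)
})

test_that("PASEF links far more features to spectra than standard mode", {
  cfg <- run_config(gradient_s = 80, seed = 9)
  gt <- generate_lipidome(250, config = cfg)
  fd <- render_frames(gt, cfg)
  ft <- collapse_adducts(extract_features(fd), cfg)
  fp <- assign_msms(ft, run_acquisition(fd, gt, "pasef", cfg), cfg)
  fs <- assign_msms(ft, run_acquisition(fd, gt, "standard", cfg), cfg)
  expect_gt(mean(fp$n_msms > 0), mean(fs$n_msms > 0))
})
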