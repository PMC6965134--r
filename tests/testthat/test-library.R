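make_run <- function(run, jitter_sd = 0, seed = 1) {
  set.seed(seed)
  base <- data.frame(
    name = c("PC 34:1", "PE 36:2", "TAG 52:2", "SM 34:1"),
    adduct = c("[M+H]+", "[M+H]+", "[M+NH4]+", "[M+H]+"),
    mz = c(760.5851, 744.5538, 876.8015, 703.5749),
    ccs = c(281.2, 268.4, 309.8, 269.1),
    rt_s = c(500, 520, 900, 480))
  base$ccs <- base$ccs * exp(stats::rnorm(nrow(base), 0, jitter_sd))
  base$run <- run
  base
}

test_that("library compilation is permutation-invariant with median consensus", {
  runs <- lapply(1:5, function(i) make_run(paste0("r", i),
                                           jitter_sd = 0.001, seed = i))
  lib <- compile_library(runs)
  expect_equal(nrow(lib), 4)
  expect_true(all(lib$n_obs == 5))
  lib2 <- compile_library(rev(runs))
  expect_equal(lib, lib2)
  # consensus is the median of per-run values
  vals <- sapply(runs, function(r) r$ccs[r$name == "PC 34:1"])
  expect_equal(lib$ccs[lib$name == "PC 34:1"], stats::median(vals))
})

test_that("replicate mobility jitter of 0.1% appears as about 0.1% CV", {
  set.seed(42)
  cvs <- replicate(30, {
    runs <- lapply(1:5, function(i)
      make_run(paste0("r", i), jitter_sd = 0.001,
               seed = sample.int(1e6, 1)))
    stats::median(compile_library(runs)$cv_pct)
  })
  expect_equal(mean(cvs), 0.1, tolerance = 0.25)
})

test_that("single-run libraries are flagged and m/z conflicts are errors", {
  lib <- compile_library(list(make_run("only")))
  expect_true(all(is.na(lib$cv_pct)))
  expect_true(all(lib$flagged))
  bad <- make_run("r2"); bad$mz[1] <- bad$mz[1] * (1 + 8e-6)
  expect_error(compile_library(list(make_run("r1"), bad)),
               "integrity")
})

test_that("inter-group CV is computed over group medians", {
  runs <- lapply(1:6, function(i) {
    r <- make_run(paste0("r", i), jitter_sd = 0.0005, seed = i)
    r$group <- if (i <= 3) "labA" else "labB"
    r
  })
  lib <- compile_library(runs)
  expect_true(all(is.finite(lib$inter_group_cv_pct)))
  expect_lt(stats::median(lib$inter_group_cv_pct), 0.3)
})

test_that("quantification statistics follow their definitions", {
  m <- matrix(100, nrow = 4, ncol = 5,
              dimnames = list(paste0("L", 1:4), NULL))
  qs <- quant_stats(m)
  expect_true(all(qs$cv_pct == 0))
  expect_equal(qs$completeness_pct, 100)
  expect_equal(qs$complete_in_all, 4)
  # one lipid missing in 2 of 5 replicates contributes 3/5
  m2 <- m; m2[1, 1:2] <- NA
  qs2 <- quant_stats(m2)
  expect_equal(unname(qs2$n_detected[1]), 3)
  expect_equal(qs2$completeness_pct, (18 / 20) * 100)
  expect_equal(unname(qs2$quantified_in_n["3"]), 1L)
  expect_error(quant_stats(matrix(-1, 2, 2)), ">= 0")
})

test_that("log-normal noise of sigma 0.12 yields a median CV near 12%", {
  set.seed(7)
  n <- 400
  m <- matrix(exp(log(1e5) + stats::rnorm(n * 5, 0, 0.12)),
              nrow = n, ncol = 5)
  qs <- quant_stats(m)
  # expected CV of a log-normal: sqrt(exp(sigma^2) - 1) = 12.04%
  expect_equal(qs$median_cv_pct, 12.0, tolerance = 0.1)
  expect_gt(qs$frac_cv_below_20, 0.9)
})

test_that("library comparison reports deviations, overlap and correlation", {
  a <- compile_library(list(make_run("a1", 0.0005, 1),
                            make_run("a2", 0.0005, 2)))
  self <- compare_libraries(a, a)
  expect_true(all(self$per_lipid$dev_pct == 0))
  expect_equal(self$median_abs_dev_pct, 0)
  expect_equal(self$pearson_r, 1)
  b <- a; b$ccs <- a$ccs * 1.005
  cmp <- compare_libraries(a, b)
  expect_equal(cmp$per_lipid$dev_pct,
               rep((1 / 1.005 - 1) * 100, 4), tolerance = 1e-9)
  # disjoint libraries: empty report
  c2 <- a; c2$name <- paste0("X", a$name)
  empty <- compare_libraries(a, c2)
  expect_equal(empty$n_shared, 0L)
})

test_that("normal jitter of 0.2% leaves about 95% of deviations within 0.4%", {
  set.seed(11)
  n <- 500
  base <- data.frame(name = paste0("TAG 50:", seq_len(n) %% 9),
                     adduct = paste0("[M+X", seq_len(n), "]+"),
                     mz = 800 + seq_len(n) * 0.01,
                     ccs = 300 + seq_len(n) * 0.01, run = "a")
  jit <- base; jit$ccs <- base$ccs * (1 + stats::rnorm(n, 0, 0.002))
  cmp <- compare_libraries(jit, base)
  frac <- mean(abs(cmp$per_lipid$dev_pct) <= 0.4)
  expect_equal(frac, 0.954, tolerance = 0.035)
})

test_that("leave-one-out putative assignment recovers TAG grid members", {
  cfg <- run_config(gradient_s = 1800, seed = 29,
                    noise = list(enabled = FALSE))
  gt <- generate_lipidome(900, config = cfg)
  tg <- gt[gt$class == "TAG" & gt$adduct == "[M+NH4]+", ]
  db <- build_database("TAG", "positive")
  id_all <- data.frame(species_name = tg$name, adduct = tg$adduct,
                       ccs = tg$ccs)
  # clusters with at least 3 members support leave-one-out
  counts <- table(tg$carbons)
  eligible <- which(tg$carbons %in% as.numeric(names(counts))[counts >= 3])
  hits <- 0; wrong <- 0; tried <- 0
  for (i in eligible) {
    tried <- tried + 1
    feat <- data.frame(mz = tg$mz[i], ccs = tg$ccs[i])
    got <- putative_assignment(feat, id_all[-i, , drop = FALSE], db,
                               config = cfg)
    if (!is.na(got$putative_name)) {
      if (got$putative_name == tg$name[i]) hits <- hits + 1
      else if (sub(" .*", "", got$putative_name) != "TAG")
        wrong <- wrong + 1
    }
  }
  expect_gte(hits / tried, 0.95)
  expect_equal(wrong, 0)
})

test_that("features off the cluster trend stay unassigned", {
  cfg <- run_config(seed = 2, noise = list(enabled = FALSE))
  id <- data.frame(species_name = c("TAG 50:1", "TAG 50:2", "TAG 50:3"),
                   adduct = "[M+NH4]+",
                   ccs = c(309, 306.5, 304))
  db <- build_database("TAG", "positive")
  mz_502 <- db$mz[db$name == "TAG 50:2" & db$adduct == "[M+NH4]+"]
  ok <- putative_assignment(data.frame(mz = mz_502, ccs = 306.4),
                            id[-2, ], db, config = cfg)
  expect_equal(ok$putative_name, "TAG 50:2")
  off <- putative_assignment(data.frame(mz = mz_502, ccs = 306.5 * 1.03),
                             id[-2, ], db, config = cfg)
  expect_true(is.na(off$putative_name))
  # an external predicted CCS deviating more than 1% vetoes assignment
  pred <- data.frame(name = "TAG 50:2", adduct = "[M+NH4]+",
                     ccs_pred = 306.5 * 1.02)
  veto <- putative_assignment(data.frame(mz = mz_502, ccs = 306.4),
                              id[-2, ], db, predicted = pred,
                              config = cfg)
  expect_true(is.na(veto$putative_name))
})
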