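#' Acquisition/run configuration
#'
#' Bundles every tunable of the simulated LC-TIMS-MS run and the
#' downstream engines, with the instrument defaults used throughout:
#' 100 ms accumulation and ramp, 1 MS1 + 3 PASEF MS/MS frames per 0.4 s
#' cycle, m/z 50-1550, mobility range 0.6-1.95 Vs/cm^2, chromatographic
#' peaks of 3-6 s FWHM and mobility peaks of 2-3 ms FWHM.
#'
#' @param gradient_s LC gradient length in seconds (default 30 min).
#' @param cycle_s acquisition cycle (s): one MS1 frame plus
#'   `ramps_per_cycle` MS/MS ramps.
#' @param ramps_per_cycle PASEF MS/MS ramps per cycle.
#' @param ramp_ms TIMS accumulation/ramp time (ms).
#' @param bin_ms width of a mobility scan-time bin (ms).
#' @param mz_range recorded m/z range.
#' @param ook0_range scanned mobility range (1/K0, Vs/cm^2).
#' @param rt_fwhm_s range of chromatographic peak FWHM (s).
#' @param mob_fwhm_ms range of mobility peak FWHM (ms).
#' @param switch_ms quadrupole switching time between PASEF targets (ms).
#' @param min_dwell_ms minimum usable isolation dwell per target (ms).
#' @param intensity_threshold candidate intensity threshold (counts).
#' @param intensity_target cumulative intensity target; precursors below
#'   it are rescheduled, above it dynamically excluded.
#' @param exclusion_s dynamic exclusion time (s, default 0.2 min).
#' @param isolation_th quadrupole isolation half-width (Th).
#' @param ce_pos,ce_neg collision energy ramp endpoints (eV) mapped
#'   linearly over `ook0_range`.
#' @param feature_threshold_pos,feature_threshold_neg feature intensity
#'   thresholds (counts).
#' @param min_points minimum number of 4D data points per feature (100;
#'   50 in recursive mode).
#' @param prec_ppm,frag_ppm precursor and fragment mass tolerances (ppm).
#' @param noise list: `enabled`, `peaks_per_frame` (Poisson rate of
#'   spurious centroids per MS1 frame), `intensity_scale` (exponential
#'   mean of noise counts), `doublet_prob` (chance a noise peak carries
#'   an isotope-like satellite).
#' @param seed integer seed fixing the full run.
#' @param polarity `"positive"` or `"negative"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(gradient_s = 1800, cycle_s = 0.4,
                       ramps_per_cycle = 3, ramp_ms = 100, bin_ms = 0.5,
                       mz_range = c(50, 1550), ook0_range = c(0.6, 1.95),
                       rt_fwhm_s = c(3, 6), mob_fwhm_ms = c(2, 3),
                       switch_ms = 1, min_dwell_ms = 2,
                       intensity_threshold = 100, intensity_target = 4000,
                       exclusion_s = 12, isolation_th = 1,
                       ce_pos = c(25, 45), ce_neg = c(35, 55),
                       feature_threshold_pos = 500,
                       feature_threshold_neg = 200,
                       min_points = 100, prec_ppm = 5, frag_ppm = 10,
                       noise = list(enabled = TRUE, peaks_per_frame = 30,
                                    intensity_scale = 30,
                                    doublet_prob = 0.05),
                       seed = 1, polarity = "positive") {
  stopifnot(gradient_s > 0, cycle_s > 0, ramp_ms > 0, bin_ms > 0,
            diff(mz_range) > 0, diff(ook0_range) > 0,
            intensity_threshold < intensity_target)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> ", x$polarity, " mode; gradient ", x$gradient_s,
      " s; cycle ", x$cycle_s, " s (1 MS1 + ", x$ramps_per_cycle,
      " MS/MS ramps of ", x$ramp_ms, " ms); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read / write a workflow configuration
#'
#' Configurations serialise losslessly to YAML so that a simulated run's
#' "methods section" is reconstructable from its config file.
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Packaged benchmark presets
#'
#' `"plasma"` is the full plasma-like landscape: 3000 species over a
#' 30-min gradient with a class mix weighted toward TAG and PC, dense
#' enough that mid-gradient MS1 frames carry 20+ schedulable isotope
#' patterns. `"plasma-scaled"` keeps the same per-frame candidate
#' density (species per second of gradient) but shrinks the run to a
#' 2-min gradient with 200 species so that end-to-end analyses run in
#' seconds; it is the default problem size for examples and validation.
#'
#' `"plasma-dense"` packs the full species request into the 2-min
#' gradient so that live precursor candidates exceed the standard-mode
#' MS/MS capacity severalfold, reproducing the acquisition regime of a
#' real plasma run, where parallelised fragmentation pays off most; it
#' is the testbed for PASEF-versus-standard comparisons.
#'
#' @param name preset name.
#' @param seed seed stored in the config.
#' @param polarity ionisation mode.
#' @return list with `config` (a `run_config`) and `n_species`.
#' @export
benchmark_preset <- function(name = c("plasma-scaled", "plasma-dense",
                                      "plasma"),
                             seed = 1, polarity = "positive") {
  name <- match.arg(name)
  if (name == "plasma") {
    list(config = run_config(gradient_s = 1800, seed = seed,
                             polarity = polarity),
         n_species = 3000)
  } else if (name == "plasma-dense") {
    list(config = run_config(gradient_s = 120, seed = seed,
                             polarity = polarity),
         n_species = 3000)
  } else {
    list(config = run_config(gradient_s = 120, seed = seed,
                             polarity = polarity),
         n_species = 200)
  }
}
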