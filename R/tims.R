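#' TIMS scan calibration
#'
#' The TIMS separation coordinate is linearly mapped between scan time
#' within the mobility ramp (ms) and reduced mobility 1/K0 (Vs/cm^2).
#' `fit_calibration()` fits the line by least squares from calibrant
#' points; with collinear points the fit is exact.
#'
#' @param points data.frame or matrix with columns `scan_time` (ms) and
#'   `ook0` (1/K0, Vs/cm^2); at least two rows with distinct scan times.
#' @param ramp_ms ramp (scan) time in ms.
#' @param ook0_range mobility range spanned by the ramp.
#' @return object of class `tims_calibration` with `slope`
#'   (Vs/cm^2 per ms), `intercept`, `ramp_ms`, `ook0_range`.
#' @examples
#' cal <- fit_calibration(data.frame(scan_time = c(0, 100),
#'                                   ook0 = c(0.6, 1.95)))
#' cal$slope  # 0.0135
#' @export
fit_calibration <- function(points, ramp_ms = 100,
                            ook0_range = c(0.6, 1.95)) {
  points <- as.data.frame(points)
  if (nrow(points) < 2) stop("calibration requires at least 2 points")
  t <- points$scan_time; y <- points$ook0
  if (length(unique(t)) < 2)
    stop("degenerate calibration: scan times are not distinct")
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope == 0)
    stop("degenerate calibration: zero slope")
  structure(list(slope = slope,
                 intercept = unname(fit$coefficients[1]),
                 ramp_ms = ramp_ms, ook0_range = ook0_range,
                 residuals = unname(fit$residuals)),
            class = "tims_calibration")
}

#' Default linear calibration over the full ramp
#'
#' Maps scan time 0 ms to the lower and `ramp_ms` to the upper end of the
#' mobility range (0.6-1.95 Vs/cm^2 by default), i.e. low-mobility ions
#' are released first in real TIMS scans but the package adopts the
#' convention that 1/K0 increases with scan time.
#'
#' @inheritParams fit_calibration
#' @export
default_calibration <- function(ramp_ms = 100, ook0_range = c(0.6, 1.95)) {
  fit_calibration(data.frame(scan_time = c(0, ramp_ms), ook0 = ook0_range),
                  ramp_ms = ramp_ms, ook0_range = ook0_range)
}

#' Convert between scan time and reduced mobility
#' @param cal a `tims_calibration`.
#' @param scan_time_ms scan time within the ramp (ms).
#' @param ook0 reduced mobility 1/K0 (Vs/cm^2).
#' @return the mapped coordinate.
#' @export
scan_time_to_ook0 <- function(cal, scan_time_ms) {
  cal$intercept + cal$slope * scan_time_ms
}

#' @rdname scan_time_to_ook0
#' @export
ook0_to_scan_time <- function(cal, ook0) {
  (ook0 - cal$intercept) / cal$slope
}

#' @export
print.tims_calibration <- function(x, ...) {
  cat("<tims_calibration> 1/K0 =", signif(x$intercept, 6), "+",
      signif(x$slope, 6), "* t[ms];  ramp", x$ramp_ms, "ms\n")
  invisible(x)
}

#' Physical parameters for the Mason-Schamp conversion
#'
#' @param gas_mass drift gas molecular mass in Da (N2 by default).
#' @param temperature_k gas temperature in K.
#' @return list used by [mobility_to_ccs()] / [ccs_to_mobility()].
#' @export
ccs_params <- function(gas_mass = 28.0134, temperature_k = 305) {
  if (gas_mass <= 0 || temperature_k <= 0)
    stop("gas mass and temperature must be positive")
  list(gas_mass = gas_mass, temperature_k = temperature_k)
}

#' Mobility to collisional cross section (Mason-Schamp)
#'
#' Omega = (3 z e) / (16 N0) * sqrt(2 pi / (mu kB T)) * (1/K0), with
#' reduced mass mu = m_ion * m_gas / (m_ion + m_gas) and N0 the gas
#' number density at 273.15 K and 1 atm. 1/K0 is taken in Vs/cm^2 and
#' the result returned in Angstrom^2.
#'
#' @param ook0 reduced mobility 1/K0 (Vs/cm^2), > 0.
#' @param ion_mass ion mass in Da (m/z times charge for singly charged).
#' @param charge charge number z (>= 1).
#' @param params from [ccs_params()].
#' @return CCS in Angstrom^2.
#' @export
mobility_to_ccs <- function(ook0, ion_mass, charge = 1,
                            params = ccs_params()) {
  if (any(ook0 <= 0)) stop("1/K0 must be > 0")
  if (any(ion_mass <= 0) || any(charge < 1))
    stop("non-physical ion mass or charge")
  mu <- ion_mass * params$gas_mass / (ion_mass + params$gas_mass) * .AMU_KG
  pref <- 3 * charge * .E_CHARGE / (16 * .N0_LOSCHMIDT) *
    sqrt(2 * pi / (mu * .K_BOLTZMANN * params$temperature_k))
  # 1/K0 [Vs/cm^2] -> [Vs/m^2]; m^2 -> Angstrom^2
  pref * (ook0 * 1e4) * 1e20
}

#' Collisional cross section to mobility (inverse Mason-Schamp)
#' @param ccs CCS in Angstrom^2, > 0.
#' @inheritParams mobility_to_ccs
#' @return 1/K0 in Vs/cm^2.
#' @export
ccs_to_mobility <- function(ccs, ion_mass, charge = 1,
                            params = ccs_params()) {
  if (any(ccs <= 0)) stop("CCS must be > 0")
  ccs / mobility_to_ccs(1, ion_mass, charge, params)
}

#' Duty-cycle concentration gain of trapped accumulation
#'
#' Ions accumulated over the full ramp are released within a narrow
#' mobility peak; the fold concentration equals accumulation time over
#' peak width (100 ms accumulation and 2 ms peaks give a 50-fold gain in
#' signal-to-noise over continuous acquisition).
#'
#' @param accumulation_ms accumulation time (ms), > 0.
#' @param peak_fwhm_ms mobility peak FWHM (ms), > 0.
#' @return fold concentration (dimensionless).
#' @export
duty_cycle_gain <- function(accumulation_ms, peak_fwhm_ms) {
  if (any(accumulation_ms <= 0) || any(peak_fwhm_ms <= 0))
    stop("times must be positive")
  accumulation_ms / peak_fwhm_ms
}

#' Ion mobility resolving power
#'
#' R = (1/K0) / Delta(1/K0) where the peak width Delta(1/K0) is the FWHM
#' expressed in mobility units; with a linear scan calibration a peak of
#' `fwhm_ms` translates to `fwhm_ms * slope`.
#'
#' @param ook0 peak position (1/K0, Vs/cm^2), > 0.
#' @param delta_ook0 peak FWHM in 1/K0 units, > 0.
#' @return dimensionless resolving power CCS/DeltaCCS.
#' @export
ims_resolution <- function(ook0, delta_ook0) {
  if (any(ook0 <= 0) || any(delta_ook0 <= 0))
    stop("inputs must be positive")
  ook0 / delta_ook0
}

#' Packaged TIMS calibrant ions
#'
#' The positive- and negative-mode tuning-mix ions (m/z, 1/K0) shipped
#' as the default calibration fixture.
#'
#' @param polarity `"positive"`, `"negative"` or `"both"`.
#' @param path TSV path; defaults to the packaged table.
#' @return data.frame with columns `mz`, `ook0`, `polarity`.
#' @export
load_calibrants <- function(polarity = c("both", "positive", "negative"),
                            path = system.file("extdata", "calibrants.tsv",
                                               package = "timspasef")) {
  polarity <- match.arg(polarity)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (polarity != "both") tab <- tab[tab$polarity == polarity, ]
  tab
}
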