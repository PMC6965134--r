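# Independent oracles used across the test suite. Constants here are
# typed separately from the package sources (CIAAW/CODATA values) so that
# mass and physics checks do not share code with the implementation.

ORACLE_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, P = 30.97376163, S = 31.97207100,
                 Na = 22.9897692809, Cl = 34.96885268)
ORACLE_ELECTRON <- 0.00054857990907

# sum of element masses from a named count vector
oracle_mass <- function(counts) {
  sum(ORACLE_MASS[names(counts)] * counts)
}

# Brute-force isotope distribution: convolve per-atom distributions one
# atom at a time over nominal shifts. Only C, H, O supported (enough for
# lipid formulas at test scale).
oracle_isotope_dist <- function(counts, nmax = 6) {
  iso <- list(
    C = list(shift = c(0, 1), ab = c(0.9893, 0.0107)),
    H = list(shift = c(0, 1), ab = c(0.999885, 0.000115)),
    O = list(shift = c(0, 1, 2), ab = c(0.99757, 0.00038, 0.00205)),
    N = list(shift = c(0, 1), ab = c(0.99636, 0.00364)),
    P = list(shift = 0, ab = 1)
  )
  p <- c(1, rep(0, nmax))
  for (el in names(counts)) {
    for (k in seq_len(counts[[el]])) {
      q <- rep(0, nmax + 1)
      for (i in seq_along(iso[[el]]$shift)) {
        s <- iso[[el]]$shift[i]
        idx <- seq_len(nmax + 1 - s)
        q[idx + s] <- q[idx + s] + p[idx] * iso[[el]]$ab[i]
      }
      p <- q
    }
  }
  p
}

# Closed-form least squares for a straight line
oracle_lsq_line <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Independent Mason-Schamp evaluation (CODATA 2018 constants)
oracle_mason_schamp <- function(ook0, mz, z = 1, gas = 28.0134, T = 305) {
  kB <- 1.380649e-23; e <- 1.602176634e-19
  N0 <- 101325 / (kB * 273.15)
  mu <- mz * z * gas / (mz * z + gas) * 1.66053906660e-27
  (3 * z * e) / (16 * N0) * sqrt(2 * pi / (mu * kB * T)) * ook0 * 1e4 * 1e20
}

# Brute-force optimal PASEF ramp scheduling: enumerate all candidate
# subsets and orderings under the run-to-deadline occupancy model (each
# selected target occupies [max(window start, previous end + switch),
# window end); feasible if the dwell is at least min_dwell and the full
# window lies inside the ramp).
oracle_schedule_count <- function(windows, ramp_ms = 100, switch_ms = 1,
                                  min_dwell_ms = 2) {
  n <- nrow(windows)
  ord <- order(windows$end)
  windows <- windows[ord, ]
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    t <- -Inf; ok <- TRUE
    for (i in sel) {
      if (windows$end[i] > ramp_ms) { ok <- FALSE; break }
      start <- max(windows$start[i], t + switch_ms)
      if (start + min_dwell_ms > windows$end[i]) { ok <- FALSE; break }
      t <- windows$end[i]
    }
    if (ok) best <- length(sel)
  }
  best
}
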