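# Physical and atomic constants used throughout the package.
# Monoisotopic atomic masses: IUPAC/CIAAW values, >= 6 decimals.

.ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Na", "Cl", "K")

.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.9737615120,
  S  = 31.9720706912,
  Na = 22.9897692820,
  Cl = 34.9688526800,
  K  = 38.9637064864
)

# Heavy-isotope table for envelope calculations: per element, the nominal
# mass shift, exact mass, and natural abundance of each isotope.
.ISOTOPES <- list(
  C  = data.frame(shift = c(0L, 1L),
                  mass = c(12.0, 13.0033548378),
                  ab = c(0.9893, 0.0107)),
  H  = data.frame(shift = c(0L, 1L),
                  mass = c(1.0078250319, 2.0141017781),
                  ab = c(0.999885, 0.000115)),
  N  = data.frame(shift = c(0L, 1L),
                  mass = c(14.0030740052, 15.0001088989),
                  ab = c(0.99636, 0.00364)),
  O  = data.frame(shift = c(0L, 1L, 2L),
                  mass = c(15.9949146221, 16.9991315650, 17.9991596129),
                  ab = c(0.99757, 0.00038, 0.00205)),
  P  = data.frame(shift = 0L, mass = 30.9737615120, ab = 1),
  S  = data.frame(shift = c(0L, 1L, 2L),
                  mass = c(31.9720706912, 32.9714587098, 33.9678669012),
                  ab = c(0.9499, 0.0075, 0.0425)),
  Na = data.frame(shift = 0L, mass = 22.9897692820, ab = 1),
  Cl = data.frame(shift = c(0L, 2L),
                  mass = c(34.9688526800, 36.9659025900),
                  ab = c(0.7576, 0.2424)),
  K  = data.frame(shift = c(0L, 2L),
                  mass = c(38.9637064864, 40.9618252579),
                  ab = c(0.932581, 0.067302 / (0.932581 + 0.067302 + 0.000117) *
                           (0.932581 + 0.000117 + 0.067302)))
)
# 40K (0.0117%) is ignored; renormalise K abundances to sum to 1.
.ISOTOPES$K$ab <- c(0.932581, 0.067302) / (0.932581 + 0.067302)

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS

# Average spacing between adjacent isotope peaks of C/H/N/O-dominated ions,
# used for envelope recognition in MS1 frames (Da per nominal shift).
.ISOTOPE_SPACING <- 1.00336

# Mason-Schamp ingredients (SI)
.K_BOLTZMANN <- 1.380649e-23      # J/K
.E_CHARGE <- 1.602176634e-19      # C
.N0_LOSCHMIDT <- 101325 / (.K_BOLTZMANN * 273.15)  # molecules / m^3
.AMU_KG <- 1.66053906660e-27

# timsTOF lock masses, recorded as constants (the simulator is already
# calibrated; no recalibration is performed).
.LOCK_MASS_POS <- 622.028960
.LOCK_MASS_NEG <- 666.019887
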