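Package: timspasef
Title: Simulation and Analysis of PASEF Lipidomics on TIMS Mass Spectrometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for lipidomics on trapped ion mobility
    (TIMS) quadrupole time-of-flight instruments operated in parallel
    accumulation-serial fragmentation (PASEF) mode. Simulates LC-TIMS-MS
    runs of a known lipidome (chromatographic and mobility peak shapes,
    isotope envelopes, class-structured collisional cross section trends,
    class-diagnostic MS/MS fragmentation), schedules data-dependent MS/MS
    with a PASEF precursor scheduler, extracts four-dimensional features
    (m/z, retention time, ion mobility, intensity), annotates lipids with
    a rule-based MS/MS filter set and three-level shorthand nomenclature,
    and compiles high-precision collisional cross section libraries with
    reproducibility statistics. Includes linear TIMS scan calibration and
    Mason-Schamp mobility/CCS conversion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
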