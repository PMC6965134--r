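---
title: "Models and methods behind the PASEF lipidomics toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the PASEF lipidomics toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(timspasef)
```

This vignette is the package's own account of its science: the models
it implements, the assumptions and defaults behind them, what the
simulator does and does not emulate, and the design choices made where
the design was genuinely open. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## The measurement being modelled

A trapped ion mobility (TIMS) quadrupole time-of-flight instrument
separates ions three times before detection: by reversed-phase
chromatography (minutes), by ion mobility inside a 100-ms TIMS ramp,
and by m/z in the TOF analyzer. A dual TIMS design accumulates the
incoming beam in a first analyzer while a second releases the previous
batch in order of mobility, so up to the full ion current is used when
accumulation and ramp times are equal (100 ms each here). Because ions
of one mobility elute from the ramp within a few milliseconds, the
quadrupole can visit many precursors serially within a single ramp —
the PASEF principle. The package models the whole chain at centroid
level and replaces the two proprietary software steps of such
workflows (4D feature finding and lipid annotation) with documented
algorithms.

## Lipid chemistry

Species are described at shorthand level: class, total acyl carbons
`n`, total double bonds `d`, optional per-chain composition. Formula
templates per class (e.g. TAG `n:d` → C(n+3)H(2n+2−2d)O6,
PC `n:d` → C(n+8)H(2n+16−2d)NO8P) are verified in the tests against
reference compositions such as tripalmitin and DPPC. Ether/plasmalogen
PC and PE substitute one ester oxygen (−O +2H); oxidised
glycerophospholipids add +O/+2O to the base template. sn-positions,
double-bond positions and geometry are deliberately not encoded — they
are not evident from mobility-resolved MS/MS at this level.

Atomic masses are IUPAC monoisotopic values hard-coded to at least six
decimals; the electron mass (0.000549 Da) is applied per charge.
Isotope envelopes are computed by exact polynomial convolution of the
per-element heavy-isotope distributions, aggregated by nominal shift.
The `[M−CH3]−` adduct is defined as loss of a methyl radical with one
extra electron; the full adduct table ships as an editable TSV, as do
the fragmentation rules. Chain fragments follow fixed conventions:
carboxylate anions RCOO− per chain in negative mode (supporting for
sphingolipids, required for glycerophospholipids), fatty-acid neutral
losses for glycerolipids in positive mode (plus NH3 for ammoniated
precursors), and the long-chain-base ion [LCB+H−2H2O]+ as the
N″-type evidence for ceramides and glycosphingolipids. The N″-type
entries are flagged `configurable` in the rule table because the exact
fragment set such software requires is not standardised.

## TIMS physics

The scan is calibrated linearly between scan time within the ramp and
reduced mobility 1/K0, by least squares over calibrant ions (the
packaged table holds the four positive-mode and three negative-mode
tuning-mix points). The calibration is fit in scan-time space against
1/K0, not against CCS. Mobility and collisional cross section are
interconverted with the Mason–Schamp equation

Ω = (3 z e)/(16 N0) · sqrt(2π/(μ k_B T)) · (1/K0),

with μ the ion–gas reduced mass and N0 the gas number density at
273.15 K and 1 atm. The paper-style defaults leave drift gas and
temperature unstated, so the package defaults to N2 (28.0134 Da) and
305 K, both configurable; published CCS values from other instruments
therefore validate relative, not absolute, conventions. Duty-cycle
arithmetic (accumulation/FWHM, e.g. 100 ms/2 ms = 50-fold
concentration) and mobility resolving power (1/K0 divided by the peak
FWHM in mobility units) are provided as first-class functions.

## The run simulator

`generate_lipidome()` draws species from a plasma-like class mix
(TAG- and PC-weighted in positive mode; TAG and sterols are not
ionised in negative mode), with chains from a pool of physiological
fatty acids in which odd-chain acyls carry about 1% weight. One entry
is kept per species-level name, because chain isomers of the same
`n:d` share formula, retention trend and CCS trend and would be
inseparable by construction. Retention follows the
equivalent-carbon-number convention (`rt` rises with carbons, falls
with double bonds, class-specific offsets; cholesteryl esters elute
late). CCS follows class-specific affine trends in m/z with a
2.5-Å² per-double-bond decrement and 0.2% lognormal jitter, anchored
to published class positions (PC 34:1 [M+H]+ near 281 Å², SM 34:1
near 269 Å², TAG 48:1 [M+NH4]+ near 311 Å²) and a TAG-versus-DAG
offset of 54.7 Å² at equal m/z. Mobilities derive from CCS by the
inverse Mason–Schamp conversion, which also reproduces the
higher-mass/lower-mobility diagonal of real frames.

Abundances are log-normal (median 2×10⁴ counts, σ_log = 1.8). Counts
are arbitrary units, but the scale is deliberately consistent with
the instrument-style thresholds the engines use (candidate threshold
100 counts, scheduling target 4000, feature thresholds 500/200): a
median species near its apex samples a few thousand counts per frame,
so the 100/4000 bracket is exercised across the distribution.

Frames are rendered as centroids: Gaussian elution profile × Gaussian
mobility profile (2–3 ms FWHM on a 0.5-ms scan-time grid) × isotope
envelope, with per-frame intensity equal to abundance times the
elution weight integrated over one 0.4-s cycle — so a fully eluting
species conserves its abundance times envelope sum, which the tests
assert to 1%. Contributions below one count are dropped. Noise adds
Poisson-distributed spurious centroids per frame on a log-uniform m/z
grid, 5% of which carry an isotope-like satellite to exercise the
envelope filters. MS/MS spectra are rendered on demand for a
scheduled target: every species inside the ±1 Th quadrupole window
and the sampled scan-time interval contributes its rule-table
fragments at the precursor's mobility position, scaled by the window
overlap (so halving the window halves the spectrum, and co-isolation
produces genuinely chimeric spectra). Sterol spectra are dominated by
the precursor ion. Ion-charge control, multiple charging of lipids
and TOF transient effects are not modelled; provenance (which
ground-truth entry produced each centroid) is retained for scoring
only and never used by the analysis algorithms.

What passing tests therefore show about real data: the algorithms are
correct under clean centroid statistics, exact masses and Gaussian
peak shapes. They do not demonstrate robustness to mass-calibration
drift, detector saturation, peak tailing or real chemical noise; the
flat 0.0022-Da clustering tolerance in the feature finder, in
particular, is matched to the simulator's exact centroid masses and
would be widened to a ppm-scaled tolerance on real spectra.

## The acquisition engine

Candidates on an MS1 frame are mobility traces (m/z clusters split by
scan-time contiguity) assembled into isotope envelopes by the
1.00336/z spacing, with an M+1/M plausibility check against the
carbon count expected for a lipid of that mass (≈ one carbon per
14 Da); envelopes below 100 counts, or without an isotope partner,
are not candidates.

Scheduling within a ramp follows a run-to-deadline policy: the
quadrupole stays on a precursor until its elution window ends, then
needs 1 ms to switch; a target must retain at least 2 ms of dwell.
Under this occupancy model the selection is solved exactly by dynamic
programming over candidates sorted by window end, maximising target
count with summed intensity as tie-break; the tests verify equality
with exhaustive subset search on every fixture up to 12 candidates.
Candidates whose cumulative sampled intensity is below the 4000-count
target are re-scheduled on the later ramps of the cycle and on
subsequent cycles; on reaching the target they enter dynamic
exclusion for 0.2 min. Cumulative bookkeeping is released once the
MS1 feature disappears. Collision energy interpolates linearly over
the mobility range (25→45 eV positive, 35→55 eV negative), rising
with 1/K0 — larger, slower ions receive more energy. Standard mode
differs in exactly one respect: one precursor per ramp (the most
intense eligible candidate), with the quadrupole fixed for the whole
100 ms.

Under this repeat policy and the benchmark's count scale, the mean
number of fragmentation events per precursor lands between four and
six rather than near two: a precursor first seen on its rising edge
needs several events before its cumulative signal crosses the 4000
target. Real acquisition engines report lower repeat counts, which
suggests additional accounting (for example per-cycle caps) that is
not publicly specified; the package keeps the documented
cumulative-target policy.

## 4D feature extraction

The feature finder replaces the proprietary step with a documented
algorithm: (1) single-linkage m/z clustering of all MS1 centroids;
(2) valley splitting of each cluster's mobility profile (resolving
co-eluting isomers separated by at least about twice the mobility
FWHM); (3) retention tracing with a 2-frame gap tolerance plus valley
splitting of the elution profile (resolving partially co-eluting
isobars); (4) isotope grouping of the resulting traces by 1.00336/z
with retention and mobility coherence, seeded at the most intense
trace, rejecting seeds that have a heavier unclaimed partner one
spacing below; (5) apexes by intensity-weighted centroids, volume by
summation, CCS from the mobility apex via the calibration and
Mason–Schamp. "4D points" are counted as contributing
frame × mobility-bin × isotope centroids, the unit being otherwise
unstated. A final cleanup removes single-isotope features sitting one
or two spacings above a stronger co-eluting envelope (orphaned
isotope traces of chimeric clusters). Features need 100 points (50 in
recursive mode) and 500/200 counts (positive/negative) to survive.

Adducts are collapsed into groups when co-eluting features differ by
an inter-adduct mass delta within 5 ppm. MS/MS events link to a
feature when the quadrupole window contains the feature m/z, the
event's mobility position lies within the feature's mobility FWHM and
the event time falls inside the feature's retention bounds; ties go
to the nearest feature in (m/z, mobility) and are flagged chimeric.
Repeated events of the feature's own precursor are summed into one
spectrum; co-isolation-only events are linked but kept out of the
summed spectrum.

## Annotation

The in-silico database enumerates species-level entries per class
(including ether PC/PE and +O/+2O oxidised GP variants) crossed with
the polarity's adducts; TAG and sterols are excluded in negative
mode. Search considers every entry within 5 ppm of the precursor,
matches rule-table fragments at 10 ppm, and infers chain composition
fragment-first: observed chain fragments (from a plausibility-capped
grid, at most (c−8)/2 double bonds per chain) are combined to
decompositions of (n, d), with the even-carbon requirement enforced
for glycerophospholipid chain pairs. The curation filters are hard
predicates: sodiated/ammoniated PC needs the protonated feature or
both sodium-specific neutral losses; classes with a defined
head-group diagnostic or loss require it; ceramides and neutral
glycosphingolipids require the long-chain-base fragment; sterols pass
on precursor dominance; TAG (DAG) needs two (one) distinct chain
fragments; negative mode always needs a chain carboxylate. Every
rejection is recorded with the rule that fired.

Candidate ranking goes beyond the simple most-matches rule because
near-isobars can match the same fragment peaks: candidates are ordered
by matched-fragment count, then by precursor-anchored evidence
(neutral losses computed from this precursor discriminate the true
owner of a chimeric spectrum, whereas a shared diagnostic ion like
m/z 184.0733 does not), then by precursor mass error, then by
parsimony (unmodified species before ether/oxidised variants), then
by mean fragment error. Two different species tied on all of these
are genuinely indistinguishable and the feature is left unannotated
rather than guessed — the automated counterpart of manual
false-positive removal.

Names follow the three-level convention: species-level short names
("PC 32:1"), partially resolved long names with `@` marking a chain
not evidenced by fragments ("Cer d18:1_26:0@"), and fully resolved
long names ("PG 16:1_16:1"). Deduplication merges same-name features
(adducts, mobility-separated but MS/MS-indistinguishable peaks)
co-eluting within a tolerance (default 3 s), while same-name features
at clearly distinct retention times are kept separate as potential
isomers; because the two behaviours pull in opposite directions, the
`split_isomers` switch exposes both.

## CCS libraries and the conformational landscape

Library entries are keyed by (name, adduct) with the median as
consensus (robust to one bad run) and sd/mean × 100 as CV;
inter-group CVs are computed over group medians. Compilation is
permutation-invariant, and mixed m/z under one key beyond 5 ppm is an
integrity error, not a warning. Quantification statistics operate on
a lipids × replicates matrix with explicit missingness: CVs for
lipids present in at least three replicates, the fraction of CVs
below 20%, counts of lipids quantified in N of the replicates, and
completeness defined as the filled fraction of the matrix over
lipids detected at least once (the alternative "quantified in all
replicates" count is reported alongside, as the two statistics answer
different questions). Putative assignment fits CCS against
double-bond count within each (class, carbon-number, adduct) cluster
of identified lipids — at least two members required — and assigns an
unidentified feature only when its m/z matches a database species
within 5 ppm, its CCS lies within 1% of the cluster trend, and any
externally supplied predicted CCS agrees within 1%; the gates follow
the worked TG 48:1 example (measured 311.2 Å², predicted 308.4 Å²).
CCS prediction itself is out of scope; predictions are consumed from
a user-supplied table.

## Benchmarks and problem sizes

Three packaged presets define the study conditions. `plasma` is the
full-scale landscape (3000 species, 30-min gradient). `plasma-scaled`
keeps the same species-per-second density in a 2-min, 200-species run
and is the default for examples, recovery and CCS validation — small
enough that the complete noiseless round trip runs in about a minute.
`plasma-dense` packs the full 3000-species request (about 2000
realisable unique names) into the 2-min gradient so that live
precursor candidates exceed the standard-mode MS/MS capacity
severalfold; this is the regime in which a real complex-sample run
operates, where feature numbers dwarf what one-precursor-per-ramp
acquisition can fragment, and it is the testbed for the
PASEF-versus-standard identification comparison. At the sparser
preset densities, standard mode has enough cycles to visit most
precursors and the contrast between modes understates what dense
samples show.

## Numerical choices and degenerate inputs

Calibration requires two distinct scan times and errors otherwise;
zero or negative mobilities, CCS values, masses and temperatures are
rejected at the physics layer. Formula arithmetic refuses negative
element counts, so impossible adduct subtractions fail loudly.
Envelope convolution is exact (binary exponentiation of per-element
polynomials) rather than approximated. The m/z clustering tolerance
(0.0022 Da) resolves the closest systematic lipid interference — a
sodium adduct versus two extra carbons and three double bonds,
0.00245 Da — at any lipid mass. Scheduling ties are broken by summed
intensity; empty candidate sets, empty lipidomes and empty spectra
all propagate as empty, schema-valid results. All randomness flows
from the single configured seed; reruns are identical.

## Known limitations

Centroid-level simulation cannot expose profile-domain failure modes;
the simulator's exact masses make the analysis tolerances tighter
than real data would allow; z > 2 and in-source fragmentation are not
modelled; negative-mode defaults are less exercised than
positive-mode ones; the repeat-count behaviour of the acquisition
engine is a documented approximation of unpublished firmware
accounting; and the putative-assignment trend model assumes at least
two identified members per cluster, so sparse classes cannot receive
putative names.
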