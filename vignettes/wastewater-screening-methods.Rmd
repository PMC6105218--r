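---
title: "Methods: non-target and suspect screening of wastewater LC-HRMS data"
author: "wwscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-target and suspect screening of wastewater LC-HRMS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wwscreen)
```

## The problem

Municipal wastewater carries hundreds of *emerging contaminants* —
artificial sweeteners, pharmaceutical residues, preservatives such as
parabens — that conventional treatment removes only partially. Profiling a
treatment plant by reversed-phase LC coupled to high-resolution mass
spectrometry (Q-TOF) yields, per sample, thousands of centroided
m/z–intensity pairs across a chromatographic run in both electrospray
polarities. The analytical questions this package operationalizes are:

1. Which *chemical species* (features) are present in a sample, and with
   what monoisotopic mass, retention time and abundance?
2. Which *molecular formulas* are compatible with each feature, after
   chemically informed filtering?
3. Which of a curated list of suspect contaminants are present in which
   treatment stage, under which extraction protocol?
4. How much of the feature load does each treatment stage remove, how
   strongly does the sample matrix suppress or enhance ionization, and
   which compounds persist into the effluent and therefore qualify as
   *pollution markers*?

## Chemistry primitives

Element masses and isotope abundances are the IUPAC 2013 standard values,
embedded as data (`element_table()`). Formulas are named count vectors
serialized in Hill order. Ionization is restricted to singly charged
±H adducts: `[M+H]+` in positive mode, `[M−H]−` in negative mode.

Two ion-mass conventions coexist in monitoring practice: the physically
correct *proton* convention (±1.00727646 Da, accounting for the electron)
and the *hydrogen-atom* approximation (±1.00782503 Da). They differ by one
electron mass, ≈3.4 ppm at m/z 162, which is resolvable at the 2 ppm
accuracy this workflow enforces — so `ion_mz()` takes an explicit
`convention` argument, defaulting to `proton`. The packaged suspect list
records, per row, which convention reproduces its printed precursor m/z
(the source mixes the two), while `suspect_list()$theor_mz` always carries
the proton-convention value: the simulator plants ions there and screening
matches against the same quantity, so the synthetic data are internally
consistent physics rather than a re-encoding of a typographically mixed
table.

Mass errors are reported as
$\mathrm{ppm} = (m_\text{theor} - m_\text{exp}) / m_\text{theor} \times 10^6$ —
the sign convention under which the packaged suspect list's reported
errors are reproduced.

Isotope patterns (`isotope_pattern()`) are aggregated per nominal-mass bin
(M, M+1, M+2, …): per element, the single-atom isotope distribution is
convolved `count` times (binary exponentiation, memoized); element
distributions are then convolved across the formula. Each bin keeps the
probability-weighted mean exact-mass shift, so a chlorine-dominated M+2
bin (+1.997 Da) is distinguishable from a ¹³C₂ bin (+2.007 Da). Fine
structure within a bin is deliberately not resolved: the downstream gate
compares relative abundances at 5 percentage-point resolution, for which
nominal binning is sufficient, and it keeps the validation oracle (an
exhaustive isotopologue enumeration) tractable. Abundances are expressed
relative to the monoisotopic peak (= 100); for extreme polyhalogenated
species a later bin can exceed 100, which downstream code tolerates.

## Feature extraction

The vendor "molecular feature extraction" step is proprietary; this
package defines a transparent deterministic variant and does **not** aim
to match vendor output:

1. **Noise threshold.** Every centroid below `noise_threshold` (default
   1300 counts, interpreted as an absolute per-centroid floor) is
   discarded first.
2. **Trace linking.** Surviving centroids are sorted by m/z and split
   where the gap between neighbours exceeds `mz_tol_ppm` (default 10 ppm);
   each m/z group is split again at scan discontinuities. Traces spanning
   fewer than `min_scans` (default 3) consecutive scans are dropped. The
   trace m/z is the intensity-weighted mean; the apex defines retention
   time and apex intensity; abundance is the intensity sum.
3. **Deisotoping.** Traces separated by ≈ k·1.00336/z Da whose apexes
   co-elute (`apex_rt_tol`, default 0.1 min) and whose apex intensity does
   not exceed 1.2× the putative monoisotopic trace are merged. The
   spacing tolerance scales with k (`k × iso_spacing_tol`, default
   0.01 Da) so that ³⁴S- and ³⁷Cl-dominated M+2 bins, which sit ~10 mDa
   light of 2×1.00336, still match. Charge 1 is tried before charge 2;
   isolated traces become charge-1 singletons.
4. **Neutral mass** under the polarity's ±H hypothesis.

Observed isotope-cluster abundances are taken from *apex intensities*, not
integrated areas: the noise threshold truncates weak satellite traces
earlier than their parent, which would bias integrated ratios low, whereas
apex ratios are unaffected.

Tie-breaking is deterministic throughout (closest m/z wins; earlier trace
on exact ties), and extraction output is invariant to input-row
permutation.

## Formula identification

`identify_feature()` runs the gate cascade in cost order — the gates are
conjunctive, so ordering cannot change the accepted set:

1. **Enumeration** of all formulas within the ppm window over bounded
   element counts (depth-first, heaviest element outermost, running-mass
   pruning; hydrogen solved in closed form). Completeness is tested
   against a naive grid-search oracle.
2. **Golden-rules filter** (the non-spectral rules): element-count bounds
   widening with mass (rule 1), non-negative integral RDBE for
   even-electron neutrals (rule 2), H/C within 0.2–3.1 (rule 4),
   heteroatom/C caps N ≤ 1.3, O ≤ 1.2, P ≤ 0.3, S ≤ 0.8, Cl ≤ 0.8
   (rule 5), and joint NOPS caps (rule 6). The isotope rule (3) is the
   separate gate below; the trimethylsilyl rule (7) is GC-specific and
   excluded. All suspects are even-electron neutral molecules, hence the
   RDBE integrality assumption. Every rejection is labelled with the
   failing rule(s).
3. **Mass-accuracy gate**: |ppm| ≤ 2 by default.
4. **Isotope gate**: the maximum absolute deviation between observed and
   simulated relative abundances over the M+1, M+2 bins must be ≤ 5
   percentage points. A bin missing from the observed cluster counts as 0
   only when the simulation predicts > 1% — below that, absence is noise,
   not evidence.
5. **Score gate**: the composite score
   `100·(0.4·exp(−(ppm/2)²) + 0.4·exp(−(dev/5)²) + 0.2·exp(−(Δspacing/0.005)²))`
   must exceed 98. No public definition of the instrument software's score
   exists, so this exponential form is the package's own: it is 100 at a
   perfect tri-criteria match, strictly decreasing in each error, and
   weighted toward the two criteria the workflow gates on. It is isolated
   in `identification_score()` so it can be swapped without touching the
   cascade. The "> 98%" gate keeps its operational meaning: near-perfect
   agreement on all three criteria simultaneously.

Survivors are ranked by score, ties broken by |ppm|.

## Suspect screening

Screening is MS1-level: a suspect is detected in a sample when a feature
matches its polarity, theoretical ion m/z within 2 ppm, and retention time
within 0.5 min. The RT tolerance is not specified by monitoring practice
we could cite; 0.5 min is a declared, configurable default. MS/MS
confirmation is recorded separately, mirroring the SCAN vs targeted-MS/MS
acquisition split: `confirm_msms()` requires the monitored product ion
within 0.01 Da (absolute, because transition masses are conventionally
printed at two decimals) above a 5% relative-intensity floor. Detection
matrices collapse duplicate detections idempotently and serialize to a
`+`/`−` CSV grid. Markers are the compounds detected in the effluent stage
under at least one protocol.

## The synthetic campaign generator

No instrument data accompany the workflow this package systematizes, so
the generator *is* the study-conditions definition, not a tuning knob:

* **Samples**: 3 treatment stages (hall of separators → secondary
  settlement tank → effluent quality control station) × 3 SPE protocols
  (A: pH ≈ 2, B: pH ≈ 6, C: pH ≈ 8) × 2 ESI polarities.
* **Suspects**: the 12 packaged contaminants, planted exactly where the
  packaged reference detection matrix says they occur, at their listed
  retention times (methanol mobile phase) and proton-convention ion m/z,
  apex intensity 2×10⁵ counts.
* **Background**: anonymous random CHNOS(Cl) formulas constrained to pass
  the golden rules (so formula identification can be exercised on them),
  ion m/z inside the 100–1700 Da acquisition range, retention uniform in
  1–24 min, apex intensities log-uniform in 5×10³–5×10⁵ counts.
  Stage attrition is Bernoulli per feature, independent across features —
  the simplest model consistent with aggregate removal percentages — with
  survival 0.2 (positive) / 0.1 (negative) across raw → secondary, and
  0.825 across secondary → effluent (encoding "15–20% further removal";
  midpoint). A feature lost at one stage never reappears later.
* **Peak model**: Gaussian chromatographic profiles, sd 0.15 min on a
  0.05-min scan grid (≥ 5 scans per peak; no peak-shape information was
  available, these are declared defaults), carrying the simulated
  3-bin isotope cluster; optional Gaussian per-centroid m/z jitter (ppm)
  and per-compound RT jitter. Sub-noise-floor peaks (≈ 20 per scan) force
  the extractor to do real filtering.
* **Matrix-effect sets**: triplicate area pairs per suspect with
  `A_matrix = factor × A_solvent`; the packaged factors encode the
  reference values (saccharin 0.8073 → −19.27%, paracetamol 1.1247 →
  +12.47%, caffeine 1.32 → +32%) and place the parabens and remaining
  sweeteners in the −90…−70% suppression band; factors for the two
  compounds without a reference value (carbamazepine 0.65, ibuprofen
  0.55) are moderate-suppression choices typical for wastewater extracts.
  Replicate noise is off by default (`me_noise_cv = 0`).

All randomness flows from the mandatory seed; sub-seeds are derived
deterministically per (stage, protocol, polarity), so single runs are
reproducible independent of generation order.

**What the generator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: SPE recovery chemistry, co-elution and
chimeric spectra, retention drift between runs, electrospray saturation,
profile-mode peak shapes, in-source fragmentation, and the real >4000-
compound inventory of an actual plant (undeposited and irreproducible by
construction). The end-to-end tests demonstrate *software* correctness of
the chain under controlled conditions, not method performance on sewage.

## Numerical and design choices

* Mass-class histogram bins are half-open ([100, 500), [500, 1000),
  [1000, ∞)) because prose descriptions of such classes are ambiguous at
  the boundaries.
* Replicate matrix-effect areas are averaged *before* the ME formula;
  the per-replicate ME standard deviation is reported alongside.
* Removal percentages are computed both stage-to-stage and cumulatively
  against the raw stage, because "removed as a result of purification" can
  be read either way; the removal table labels both.
* `run_pipeline()` applies formula identification to suspect-matched
  features (confirmatory role); exhaustive identification of every
  background feature is available through `identify_features()` but kept
  out of `run-all`, since enumeration above ~1000 Da over full element
  bounds is combinatorially expensive and adds nothing to the campaign
  summaries.
* Problem sizes in the shipped tests: campaign recovery runs use 150
  background features per polarity (the default), jittered-recovery
  checks 40, and removal-rate estimation 2000 features per polarity
  averaged over several seeds — large enough that the binomial standard
  error of a removal estimate is ≈ 0.9 percentage points per run.

## Known limitations

* Only ±H singly charged adducts; Na⁺/K⁺ adducts and multiple charging
  are out of scope (charge-2 isotope spacing is recognized during
  deisotoping, but no charge-2 neutral masses are assigned).
* The identification score is package-defined; absolute score values are
  not comparable with vendor scores, only the gate semantics are.
* mzML input requires the Bioconductor `mzR` package and centroided
  spectra; profile data are rejected, not centroided.
* The extractor links traces greedily in m/z order; pathological designed
  inputs with interleaved near-isobaric traces can split differently than
  a global-optimum assignment would.
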