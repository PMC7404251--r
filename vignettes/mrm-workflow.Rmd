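---
title: "Designing and quantifying label-free MRM assays with mrmassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying label-free MRM assays with mrmassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmassay)
```

## The problem

Multiple reaction monitoring (MRM) on a triple-quadrupole mass
spectrometer quantifies a protein through surrogate tryptic peptides: the
first quadrupole isolates a peptide precursor ion, the collision cell
fragments it, and the third quadrupole isolates one backbone fragment.
Each (precursor m/z, product m/z) pair is a *transition*, and the area of
its chromatographic peak is the quantitative signal. Because no isotopic
internal standard is used in the label-free variant, absolute
concentrations come from an external calibration curve, and identity is
secured by requiring several transitions of the same peptide to co-elute.

`mrmassay` implements this workflow for bacterial secreted proteins — the
motivating application is the two *Bacillus pumilus* serine proteases
AprBp (a subtilisin-like protease) and GseBp (a glutamyl endopeptidase),
secreted by wild-type *B. pumilus* and by recombinant *B. subtilis*
strains carrying the bacitracin-inducible LIKE expression system. The
package covers assay design (digestion, peptide selection, m/z and
instrument-parameter computation, transition-list export), a synthetic
chromatogram generator standing in for the instrument, peak integration
and detection, calibration with linear range and lower limit of
quantification (LLOQ), and strain-comparison reporting.

## From protein sequence to transition list

Secreted proteases are synthesised as pre-pro-proteins. Only the mature
chain reaches the culture supernatant (AprBp: residues 108–381 of the
381-residue precursor; GseBp: 89–303 of 303), so design starts from the
mature chain, extracted with `extract_chain()` from chain annotations
supplied in configuration — there is no standard FASTA header dialect for
chain ranges, so they are never parsed from headers. Coordinates are
1-based and inclusive on both ends. For GseBp the published propeptide
and mature ranges share residue 89; the bundled configuration assigns the
propeptide 27–88 so the three chains tile the precursor exactly, and any
other boundary can be configured.

`tryptic_digest()` cleaves after K/R, by default suppressed before
proline (the Keil rule, matching common transition-design software); a
"strict" switch cleaves regardless, since published digestion settings
often leave the proline exception implicit. The assay default is zero
missed cleavages.

`filter_candidates()` applies the standard proteotypic-candidate rules:
length 8–25 (shorter peptides are unselective; longer ones are recovered
poorly from gels), no cysteine or methionine (modification-prone during
sample processing), and — when a background digest is supplied — exact
sequence uniqueness across background proteins. Isoleucine and leucine
are *not* collapsed by default although they are mass-identical; a
`collapse_il` switch enables the stricter check.

Masses use the monoisotopic residue table plus water 18.010565 Da and
proton 1.007276 Da; precursors are doubly protonated
(`(M + 2 m_H)/2`) and products are singly charged b/y ions. The identity
`b_i + y_{n-i} = M + 2 m_H` holds at machine precision and is enforced
property-style in the tests.

Product ions are picked two ways. The default automatic policy ranks
y-ions with index ≥ 3 by descending m/z, skipping candidates within 3 Th
of the precursor (precursor leakage at unit resolution), and keeps the
top three. This is a reasonable prior, but real assays are refined on the
instrument, where relative fragment intensity — which the package does not
predict — decides. The `"explicit"` policy therefore accepts the ion list
of a validated assay verbatim; the bundled reference assay
(`reference_assay()`, 6 peptides × 3 y-ions) is reproduced this way, and
under the explicit policy only listed peptides are retained, because an
explicit ion list *defines* an assay.

Collision energy and declustering potential follow vendor practice as
linear functions of precursor m/z per charge state. The shipped
coefficients are ordinary least-squares fits to the six reference
precursors (CE ≈ 0.0360·mz + 8.82 V, DP ≈ 0.0728·mz + 31.13 V for 2+)
and are refittable from any (m/z, value) pairs with
`fit_instrument_model()`. Export rounds m/z to 2 decimals and volts to 1
decimal; all internal computation and testing is at full precision with
absolute tolerances, never string equality, because printed tables mix
rounding and truncation.

## The synthetic chromatogram generator

`simulate_trace()` generates the statistical structure the downstream
analysis assumes, so the whole pipeline is testable without instrument
data: a single Gaussian elution peak on a uniform grid, with

* area = `response_factor · concentration` (default 10^5 area units per
  µg mL⁻¹ for a quantifier; confirmatory ions scale by 0.6 and 0.35),
* apex drawn once per trace from N(`rt_mean`, `rt_jitter_sd` = 0.01 min),
* peak sigma 0.02 min (≈2.8 s FWHM, typical sharp UHPLC peaks),
* additive Gaussian baseline noise (level 50, SD 10 counts), floored at 0,
* grid step 0.005 min over a 15-min run — the sampling rate implied by a
  20-ms dwell duty cycle.

Optional behaviours: detector saturation (incremental response compressed
by a factor, default 0.3, above a configurable level — used to emulate a
calibration series that loses linearity at its top), and a contaminant
peak appearing with configurable probability at a fixed offset.

The generator is seeded end to end; per-trace seeds are derived
deterministically from the run seed, so identical configuration and seed
give byte-identical artifacts.

What the simulator deliberately does **not** emulate: peak tailing and
asymmetry (symmetric shape is itself a criterion for *selecting*
transitions, so the default models the selected, well-behaved case),
isotope patterns, ion suppression and matrix effects beyond the single
interference peak, retention-time drift across a batch, and
heteroscedastic detector noise. Passing tests therefore demonstrate that
the analysis code recovers what this model generates — linearity, noise
floors, co-elution logic — not that it would survive every pathology of
real chromatography.

### The strain-panel fixture

`example_sample_sheet()` encodes the study the package targets: 10
samples — wild-type *B. pumilus* 3-19 (positive control) and
protease-deficient *B. subtilis* AT1 (negative control), both uninduced,
plus four recombinant strains (MRB044/MRB046 secreting AprBp,
MRB047/MRB049 secreting GseBp) with and without bacitracin induction.

Ground truth is defined on the supernatant scale, where all published
strain comparisons are stated; in-vial truths are derived through the
vial-total constant described below. The published vial and supernatant
values are mutually inconsistent for one sample (MRB046 uninduced); the
sheet takes the supernatant value as truth there, because every
fold-change claim is stated on supernatant concentrations — with the
printed vial value the strain's own induction ratio could not hold.

## Peak integration and detection

`integrate_peak()` smooths with a Savitzky–Golay (moving-polynomial)
filter, window 7 points and order 2 — mild enough to leave a ~17-point
FWHM peak unbiased. The apex is the smoothed maximum in the retention
window (default ±0.15 min around the expected time); the baseline is the
median of the signal *outside* the window, robust to one interference
peak elsewhere; boundaries walk outward from the apex to the first return
to baseline; the area is the trapezoidal integral of the *raw* signal
above baseline between the boundaries. Signal-to-noise is smoothed peak
height over the MAD of off-window smoothing residuals; a flat noiseless
trace yields S/N 0 by convention (height is zero), and an apex on the
window edge is flagged rather than trusted.

A peptide counts as detected (`detect_peptide()`) when every transition
reaches S/N ≥ 3 and all apexes agree within 0.1 min. The S/N threshold is
a package convention — detection thresholds are rarely printed — and both
parameters are configurable. Protein-level quantification uses the
designated quantifier peptide's quantifier transition only (NAVDTANNR
y8 for AprBp, TDTNIGNTVGYR y9 for GseBp); the others confirm identity.

## Calibration, linear range, LLOQ

The calibration series is the serial dilution 0.0033–3.3 µg mL⁻¹ (the
decade series 3.3·10⁻ᵏ plus midpoints, 7 levels × 3 replicates).
`linear_range()` drops the highest level while the straight-line r² over
level means is below 0.99 — the conventional way saturation truncates a
series. `lloq()` is the standard bioanalytical rule: the lowest level
back-calculating within ±20% of nominal with replicate CV ≤ 20%.
`fit_calibration()` chains range determination, the (optionally
1/x-weighted) fit, and LLOQ; the default is unweighted, matching
straight-line calibration plots, with 1/x offered because low-end-heavy
series are standard practice. `quantify_area()` inverts the line, clamps
negative back-calculations to zero, and flags results below the LLOQ or
above the linear range.

Supernatant concentrations come from the mass-fraction identity

> sn = vial · total_protein(SN) / total_protein(vial).

The per-vial total-protein concentration behind the published panel is
not reported. Solving the identity across the panel's mutually consistent
rows gives a constant of ≈16.5 µg mL⁻¹ (the geometric mean of the
per-row implied constants, excluding the one inconsistent row); 16.5
ships as the configuration default, always overridable, and reproduces
the consistent published supernatant values within printing round-off.
The least-squares solution in the literal sum-of-squares sense (≈16.8) is
dominated by the two largest rows and fits the printed column worse,
which is why the geometric mean was preferred. Two published rows besides
the inconsistent one (the induced top producer and the wild-type GseBp
row) deviate from any single constant by more than printing precision;
they are carried as printed, not corrected.

`fold_change()` and `strain_report()` close the loop: induction ratios
per strain and target, cross-strain ratios against a reference strain,
with zero denominators reported as "not computable" (the negative
control) and sheet samples missing from results listed, never dropped.

## Numerical choices and problem sizes

* Tolerances: m/z comparisons ±0.01 Th absolute; volts ±0.1 V; areas
  within 0.5% of the closed-form Gaussian integral in noiseless checks.
* The simulated study (10 samples × 18 transitions plus 2 × 21
  calibration traces at 3001 points each) runs in a few seconds; tests
  that only exercise orchestration use a shortened 8-min run with a
  0.01-min grid. These sizes were chosen as the smallest that leave every
  peak fully resolved (grid ≥ 8 points across ±2σ is enforced).
* End-to-end recovery is asserted within 3 propagated noise SDs, where
  the propagation combines single-trace area noise
  (`noise_sd · step · sqrt(window points)`) with the calibration line's
  inverse-prediction variance.
* Seeds: every stochastic test and pipeline run fixes one; per-trace
  seeds are derived with a large-prime stride modulo 2³¹−1.

## Limitations

Beyond the simulator simplifications above: no spectral-library intensity
prediction, no retention-time prediction (RT is measured metadata), no
modified or semi-tryptic peptides, no multi-peak deconvolution or
cross-sample RT alignment, no uncertainty propagation beyond replicate
CV, and no label-based (isotope-dilution) quantification — the workflow
is deliberately label-free.

## A worked design example

```{r}
records <- synthetic_protease_records()
mature <- lapply(records, extract_chain, kind = "mature")
cfg <- fixture_config()
assay <- build_transition_table(
  mature,
  design_settings(policy = "explicit",
                  explicit_ions = cfg$design$explicit_ions,
                  quantifier_ions = cfg$design$quantifier_ions,
                  rt = cfg$design$rt))
assay[assay$quantifier, c("protein_id", "peptide", "precursor_mz",
                          "product_ion", "product_mz", "ce_volts")]
```

And the full simulated study:

```{r}
res <- run_pipeline(fixture_config(seed = 7), stage = "all",
                    out_dir = tempfile())
res$report$induction[, c("strain", "target", "fold")]
```
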