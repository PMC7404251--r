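# mrmassay

Design and label-free quantification of multiple-reaction-monitoring
(MRM) assays for bacterial secreted proteins, in R.

Targeted proteomics on a triple quadrupole watches *transitions* — pairs
of a peptide precursor m/z (Q1) and one of its b/y fragment m/z values
(Q3) — and quantifies a protein through the chromatographic peak area of
one quantifier transition of a proteotypic peptide, calibrated against an
external dilution series. `mrmassay` implements the whole desk side of
that workflow for the two *Bacillus pumilus* serine proteases AprBp
(subtilisin-like protease) and GseBp (glutamyl endopeptidase), and for
any other target you feed it:

* **Assay design** — in-silico tryptic digestion (Keil rule, configurable),
  proteotypic-candidate filtering (length 8–25, no C/M, background
  uniqueness), doubly protonated precursor and singly charged y/b ion
  m/z from monoisotopic residue masses, per-precursor collision energy
  and declustering potential from linear models
  (CE = 0.0360·mz + 8.82 V, DP = 0.0728·mz + 31.13 V for 2+ precursors,
  refittable), and vendor-style transition-list CSV export.
* **Synthetic chromatograms** — a seeded generator producing Gaussian
  elution peaks whose areas are linear in concentration on a noisy
  baseline, with optional saturation and interference, plus a bundled
  strain-panel sample sheet (wild type, negative control, four inducible
  recombinant strains).
* **Quantification** — Savitzky–Golay smoothing, robust baseline and
  boundary detection, trapezoidal integration, S/N + co-elution peptide
  detection, calibration curves with iterative linear-range trimming and
  bioanalytical LLOQ (±20% accuracy, ≤20% CV), back-calculation to
  supernatant concentrations, and strain-comparison fold-changes.

## Worked example

Design the six-peptide protease assay from the bundled synthetic
full-length sequences (the real precursors are not deposited; the
bundled 381/303-residue constructs carry the six published proteotypic
peptides at their published positions):

```r
library(mrmassay)
cfg <- fixture_config()
mature <- lapply(synthetic_protease_records(), extract_chain, "mature")
assay <- build_transition_table(mature,
  design_settings(policy = "explicit",
                  explicit_ions = cfg$design$explicit_ions,
                  quantifier_ions = cfg$design$quantifier_ions,
                  rt = cfg$design$rt))
assay[assay$quantifier, ]
#>    protein_id          peptide precursor_mz product_ion product_mz dp_volts ce_volts
#>  AprBp_mature        NAVDTANNR      487.736          y8    860.422  66.6610  26.4029
#>  AprBp_mature       APAVHAQGYK      521.277          y7    802.421  69.1041  27.6120
#>  AprBp_mature LENTATPLGNSFYYGK      887.936         y10   1145.563  95.8112  40.8298
#>  GseBp_mature     TDTNIGNTVGYR      655.820          y9    993.511  78.9041  32.4622
#>  GseBp_mature         ISGYPGDK      418.711          y7    723.331  61.6332  23.9146
#>  GseBp_mature    ATAAFVEFINYAK      722.877          y9   1130.588  83.7885  34.8795
```

The quantifier transitions are NAVDTANNR 487.74 → 860.42 (AprBp) and
TDTNIGNTVGYR 655.82 → 993.51 (GseBp); the remaining transitions confirm
identity by co-elution.

Run the full simulated study — calibration series (0.0033–3.3 µg/mL),
strain panel, integration, calibration, quantification, report:

```r
res <- run_pipeline(fixture_config(seed = 7), stage = "all",
                    out_dir = "mrmassay_out")
res$curves$AprBp
#> calibration_curve [AprBp]
#>   area = 1e+05 * conc + 0.050922   (r^2 = 1.00000, weighting none)
#>   linear range 0.0033 - 3.3 ug/mL, LLOQ 0.0033 ug/mL

res$report$induction[res$report$induction$computable, ]
#>  strain target   fold
#>  MRB044  AprBp 62.499
#>  MRB046  AprBp  6.001
#>  MRB047  GseBp 13.895
#>  MRB049  GseBp 10.000
```

The slope recovers the simulator's configured response factor (10^5 area
units per µg/mL), and the induction fold-changes recover the panel's
ground truth: bacitracin induction raises AprBp secretion ≈62-fold in
MRB044 and 6-fold in MRB046; induced MRB044 out-secretes induced MRB046
50-fold, and induced MRB049 out-secretes induced MRB047 12-fold. The
negative-control strain AT1 is reported "not detected" with ratios "not
computable".

A thin CLI wrapper with the same stages lives at
`inst/cli/mrmassay.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mrmassay.R", package="mrmassay"))')" all --out-dir out --seed 7
```

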