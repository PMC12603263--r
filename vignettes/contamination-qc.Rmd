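---
title: "Contamination-aware quality control for plasma proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contamination-aware quality control for plasma proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaQC)
```

## The problem

Blood plasma is the most accessible window into human physiology, but it is a
brutally skewed analyte: roughly twenty proteins carry about 99% of the
protein mass, and the dynamic range spans more than ten orders of magnitude.
Modern sample-preparation workflows — bead-based corona enrichment, perchloric
acid precipitation (PCA-N) — compress this range and open up the low-abundance
proteome, but they also amplify a classic pre-analytical failure mode:
residual blood cells. Platelets, erythrocytes and peripheral blood mononuclear
cells (PBMCs) that survive plasma preparation contribute their own proteomes
to the measurement, and workflows that enrich low-abundance proteins enrich
cellular contamination with them. A contaminated cohort can yield thousands of
"plasma" proteins that are really platelet proteins, and — worse — apparent
biomarkers whose group differences are artifacts of differential
contamination.

`plasmaQC` implements a complete, testable pipeline around this problem:

1. **Marker derivation** — identify cell-type-specific contamination markers
   from spike-in experiments by a four-criterion filter cascade.
2. **Contamination metrics** — per-sample contamination index (CI), cellular
   enrichment score (ES), contaminant enrichment factor, and Z-scored panel
   summaries.
3. **Dose–response modelling** — linear versus power-law behaviour of CI
   against spiked cell count, including saturation detection.
4. **A three-step QC strategy** for biomarker studies: outlier flagging,
   group-bias testing, and candidate–marker correlation screening.
5. **Workflow profiling** — rank-abundance reshaping, physicochemical
   enrichment-bias tests, replicate CVs, and PCA with KNN imputation.
6. **A synthetic-data generator** that emulates plasma plus cellular spike-in
   experiments with full ground truth, so that every stage above is testable
   without access to raw MS data.

## The statistics

**Contamination index.** For a sample with linear-scale intensities $x_i$ and
a marker panel $M$,

$$\mathrm{CI} = \frac{\sum_{i \in M,\ \mathrm{detected}} x_i}
                     {\sum_{i \notin M,\ \mathrm{detected}} x_i}.$$

Missing values contribute zero to both sums (an undetected marker contributes
nothing, matching how summed intensities behave in DIA reports). The CI is
scale-invariant — multiplying a sample by any constant leaves it unchanged —
which is what makes it comparable across instruments and loading amounts.
A sample containing only marker proteins has an undefined CI and is flagged
as such, never returned as infinity.

**Cellular enrichment score.** The ratio of the summed intensity of the top
30 cell-specific markers to the summed intensity of the 30 most abundant
plasma proteins (ranked in a designated reference sample set with markers
excluded). Where the CI asks "how much of this sample is cellular", the ES
asks "how large is the cellular signal relative to the plasma core", which is
the quantity that exposes the disproportionate amplification of contamination
by bead workflows.

**Marker filter cascade.** A protein enters a cell-type panel when, comparing
pure-contaminant replicates against pure-plasma replicates, it satisfies all
of: fold change above 1000 (platelets, erythrocytes) or 100 (PBMCs); at least
2 precursors; mean contaminant log10 intensity above 7.5 / 8.2 / 7.1
(platelet / erythrocyte / PBMC); and replicate CV below 20% / 20% / 35%.
Proteins detected in the contaminant but never in plasma are *exclusive*: they
have no finite fold change and are aligned at 1.1 times the largest finite
fold change in the table, so they outrank every shared protein while keeping
a finite, plottable value. The panel is the top 30 survivors by fold change
(ties broken by protein id). The filter is a pure conjunction, so the order
of filter application is irrelevant, and raising any threshold can only
shrink the panel — both properties are tested.

**Dose–response models.** CI versus spiked cell count $c$ is fitted two ways:
ordinary least squares $\mathrm{CI} = mc + k$ on the raw scale, and
$\log_{10}\mathrm{CI} = \log_{10} a + b\,\log_{10} c$ for the power law
$\mathrm{CI} = a c^b$. Bead workflows with finite binding capacity produce
concave dose–response ($b < 1$); direct workflows are linear through the
origin.

## Model comparison: why the criterion is log-scale

The two fits must be compared on identical points (only strictly positive
pairs can enter a power law). Replicate noise in MS intensities is
multiplicative — a constant *coefficient of variation*, not a constant
absolute error — so residuals are compared as
$\log_{10}(\mathrm{observed}) - \log_{10}(\mathrm{predicted})$, with
small-sample AIC (AICc) as the reported criterion. A raw-scale residual
comparison was implemented first and rejected: with counts log-spaced over six
decades, raw residual sums are dominated entirely by the top one or two
counts, which both models fit, and the comparison degenerates to a coin flip
driven by noise at the highest count. Under the log-scale criterion, the
regime-recovery experiment (100 seeds per regime at CV 0.15, the generating
models being an affine line and a $b = 0.5$ power law) selects the generating
model in effectively every run; the tests require at least 95 of 100 per
regime. A linear fit that predicts a nonpositive CI at an observed positive
point cannot generate the data under multiplicative error and loses the
comparison outright.

## The three-step QC strategy

1. **Per-sample assessment.** The study baseline is the median of
   $\log_{10}(\mathrm{CI} + \varepsilon)$ per cell type
   ($\varepsilon = 10^{-6}$ guards the zero-CI case). A sample is flagged
   when it exceeds the median by more than $k \cdot \mathrm{MAD}$ (default
   $k = 3$; MAD with the usual 1.4826 normal-consistency factor). The rule is
   one-sided — only *high* contamination is pathological — and robust: a few
   gross outliers barely move a median/MAD baseline. Fewer than 5 samples
   leave all flags undefined, since a "study-specific baseline" is then
   meaningless. Flags are tri-state (`pass` / `flag` / `undefined`); no NaN
   or infinity ever reaches a report.
2. **Group-bias testing.** Contamination indices are heavy-tailed by nature,
   so group comparisons use rank tests: two-sided Mann–Whitney U for two
   groups, Kruskal–Wallis for more. A group below 3 samples makes the test
   undefined; exactly constant data yield $p = 1$ by convention.
3. **Candidate validation.** Each candidate biomarker is Spearman-correlated
   (pairwise-complete, at least 6 paired detections) against every panel
   marker and against the per-sample CI; a maximum absolute correlation at or
   above 0.7 flags the candidate as a potential contamination artifact. This
   is a screening flag, not an inference, so no multiplicity correction is
   applied to it by default. Spearman is the default because any monotone
   coupling to contamination is disqualifying; Pearson is available.

The headline guarantee, exercised as an acceptance test over 100 simulated
two-group studies (20 vs 20 samples, five-fold contamination bias, CV 0.2):
the contamination-driven false biomarker is flagged in at least 95% of
studies, a genuine biomarker is falsely flagged in at most 5%, and the group
bias itself is detected at $p < 0.01$ in at least 95%.

## The synthetic world

The generator states one world, calibrated to facts about blood rather than
to any test outcome:

* **Plasma**: 1000 protein groups by default; per-protein relative mass
  log-normal in log10 space (sd 1.5), sorted descending, with the 20-protein
  head block rescaled deterministically to carry exactly 99% of the mass
  (the defining dynamic-range feature). Total protein 70 µg/µL (7e7 pg), the
  physiological plasma protein concentration.
* **Cells**: platelet / erythrocyte / PBMC proteomes of 6000 / 3000 / 8000
  proteins. Per-cell protein mass is proportional to cell volume
  (10 / 90 / 250 fL at 0.25 pg protein per fL, i.e. 2.5 / 22.5 / 62.5 pg per
  cell), which is why a few thousand PBMCs per µL can rival a hundred
  thousand platelets. Each proteome has three compartments: 50 designated
  *exclusive marker* proteins — the most abundant cellular proteins, carrying
  half the cell's protein mass (90% for erythrocytes, whose five
  hemoglobin-like head proteins alone carry 80% of total mass) and separated
  from everything else by a ten-fold abundance gap, the way ACTB or HBB
  dominate their cells; non-marker exclusive proteins; and a *shared*
  compartment of low-abundance plasma proteins the cell also expresses. The
  shared compartment is what gives marker derivation realistic finite fold
  changes (trace cellular leakage detected near the noise floor of plasma),
  without which every cellular protein would be "exclusive" and fold-change
  alignment would be degenerate.
* **Spike-in mixing** is exact mass bookkeeping: per-protein true mass =
  plasma mass + Σ count × per-cell mass × cell abundance. The study's series
  are 1 to 2×10⁶ cells/µL (platelets, erythrocytes) and 1 to 1.4×10⁴
  (PBMCs), in quadruplicate.
* **Workflows** transform true mass by
  `captured = affinity · mass^exponent`, followed by global proportional
  rescaling of a sample at the binding capacity. The compression exponent
  (< 1 for beads) is what reshapes the rank-abundance curve and makes the CI
  concave in cell count; capacity caps the *total* captured signal
  (saturation of identifications and intensities) but cancels in the CI
  ratio, so in this model the power-law dose–response of bead workflows is
  carried by compression, with capacity saturating totals. No quantitative
  capture model is published for these beads; this two-parameter
  parameterization is a modelling choice, chosen as the simplest mechanism
  reproducing the observed saturation and enrichment behaviour. Preset
  capacities and intensity scales are calibrated once against the canonical
  70 µg/µL plasma input so that pure plasma sits just below bead saturation
  and every preset reports ~7e11 total intensity for pure plasma (the
  instrument-loading normalization all workflows share in practice).
* **Measurement** applies mean-preserving multiplicative log-normal noise
  with exact target CV (σ² = ln(1 + CV²)), a hard detection limit, and
  sigmoidal abundance-dependent dropout centred at the LOD (steepness 3 per
  log10 unit) — the standard DIA missingness pattern, needed for the KNN
  imputation stage to have something to do. Preset LOD is 10³ intensity
  units, the noise floor consistent with a 7e11 total: it leaves the dim tail
  of plasma partially missing and lets trace-level shared proteins be
  detected, which in turn lets finite fold changes span into the 10⁴ range
  observed in real marker derivations. Simulated precursor counts are
  `max(1, round(2·(log10 I − log10 LOD)))` — a monotone proxy that gives the
  minimum-precursor filter something real to cut.
* **Randomness**: every generator takes one explicit integer seed and
  restores the caller's RNG state; identical inputs and seed give
  bit-identical output.

What the generator does *not* emulate: peptide-level signals, retention time,
interferences, batch effects, shared peptides between proteins, or
platelet-activation biology (activation markers are ordinary marker proteins
here). A green test on this world therefore establishes the *logic* of the
pipeline — filters, indices, fits and flags do what they claim on data whose
truth is known — not instrument-level realism.

## Numerical and design choices

* **Sorted-abundance edge case.** The plasma head-block rescaling guarantees
  the exact top-20 mass fraction for any target in (0, 1); global descending
  order is additionally guaranteed in the head-dominant regime (targets near
  the default 0.99). For small targets with few proteins a descending vector
  mathematically cannot carry less than 20/n of its mass in the top 20, so
  only the block masses, not global order, are guaranteed there.
* **Missing vs zero.** DIA outputs conflate them; `read_quant_matrix()` maps
  both empty cells and zeros to missing by default (`zeros_as_missing =
  FALSE` to override). Summed-intensity metrics then skip missing values,
  which is numerically identical to treating undetected proteins as
  contributing zero.
* **Scale safety.** Matrices carry an explicit log-scale tag;
  every sum-based metric refuses a log10 view loudly, and the z-score / PCA
  functions refuse linear input. This is tested, not advisory.
* **CV and z conventions.** Population (÷n) standard deviation everywhere a
  CV or z-score is computed, declared once and tested (two replicates 90 and
  110 have CV 0.1; two log10 values 1 and 3 have z ∓1).
* **Abundance threshold side.** The marker intensity filter applies to the
  *contaminant* mean intensity — the only side where markers are reliably
  detected.
* **Enrichment factor.** No formula is published for the contaminant
  ("platelet") enrichment factor; it is implemented as the CI ratio against
  a matched pure-plasma reference measured under the same workflow, with an
  ES-ratio alternative behind the `method` argument.
* **"Differed by ≥ 80%".** Read literally on the linear ratio: enriched at
  ratio ≥ 1.8, depleted at ≤ 0.2 (with a 1e-9 tolerance so boundary ratios
  classify inclusively); an |log2 FC| reading is available via
  `mode = "log2"`.
* **Outlier-rule world.** The outlier acceptance scenario uses studies of
  n = 40 with a *bounded* baseline contamination band (uniform ±0.15 log10
  around 2×10⁴ platelets/µL) plus discrete ten-fold handling failures in 5%
  of samples — the picture the rescue experiments paint: a well-handled
  baseline with discrete compromised samples. Under an unbounded log-normal
  baseline no scale-free median+MAD rule can achieve a literally zero
  false-flag rate at this study size, since the false-flag probability of
  such a rule is scale-invariant.
* **Physicochemical constants.** Kyte–Doolittle hydropathies, Guruprasad
  DIWV dipeptide weights, average residue masses and an EMBOSS-style pKa set
  are vendored as published constants; the isoelectric point is found by
  bisection of the Henderson–Hasselbalch net charge to |charge| < 10⁻⁴.
  Ambiguous residues (B, Z, X, U, O) count toward sequence length but are
  excluded from scale averages, the mass sum, and the dipeptide walk.
  The Welch two-sided t-test is used for enriched-vs-depleted property
  comparisons; sidedness and variance treatment are unstated upstream, so
  this is declared as an interpretation.
* **KNN imputation** operates in sample space (a sample's missing protein is
  the mean of that protein in its 3 nearest samples by Euclidean distance
  over mutually detected proteins), matching its purpose of completing
  samples for PCA; proteins detected in fewer than two samples are dropped
  first, and a protein with no detected donor falls back to its own mean.
* **Interfaces.** All functionality is exposed as plain R functions; the
  worked example in the README is the canonical entry point, and
  `scripts/acceptance.R` drives the full pipeline from the command line.

## Known limitations

* The capture model has no per-protein competition: saturation rescales a
  sample globally, so capacity alone cannot change *relative* abundances.
  Competition kinetics (protein corona exchange) are out of scope.
* Absolute cell counts cannot be calibrated from a CI; only the monotone
  association is established.
* Workflow-specific marker panels are supported simply by deriving from
  workflow-restricted matrices; there is no cross-workflow harmonization.
* Protein identifiers are opaque strings; no isoform or ortholog handling.
* The candidate screen is a correlation flag. A candidate genuinely
  co-regulated with platelet biology will be flagged even if it is a real
  biomarker — that is the intended, conservative behaviour.
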