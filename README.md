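# plasmaQC

Contamination-aware quality control for mass-spectrometry-based plasma
proteomics.

Plasma is dominated by ~20 proteins carrying ~99% of its protein mass.
Modern workflows — bead-corona enrichment, perchloric-acid precipitation —
compress this dynamic range to reach the low-abundance proteome, but they
also amplify the signal of residual blood cells (platelets, erythrocytes,
PBMCs). In a biomarker cohort, differential cellular contamination can
masquerade as biology. `plasmaQC` is for proteomics core facilities and
biomarker-study analysts who need to quantify, flag and control that failure
mode.

The package implements:

* **Marker derivation** — cell-type contamination marker panels from
  pure-contaminant vs. pure-plasma measurements, by a four-criterion filter
  cascade: fold change > 1000 (platelets/erythrocytes) or > 100 (PBMCs),
  ≥ 2 precursors, mean contaminant log10 intensity > 7.5/8.2/7.1, replicate
  CV < 20%/20%/35%; contaminant-exclusive proteins are aligned at 1.1× the
  largest finite fold change. Ships the published top-5 marker gene symbols
  per cell type (`reference_marker_panels()`).
* **Contamination metrics** — per sample, with marker panel *M*:
  contamination index `CI = Σ_{i∈M} x_i / Σ_{i∉M} x_i` (detected, linear
  intensities), cellular enrichment score `ES = Σ top-30 markers / Σ top-30
  plasma proteins`, contaminant enrichment factor (CI ratio vs. a matched
  pure-plasma reference), and Z-scored marker-panel summaries.
* **Dose–response models** — OLS `CI = m·c + k` and power law
  `CI = a·c^b` (log-log fit) against spiked cell count `c`, with model
  comparison under the multiplicative-error model; bead saturation shows up
  as `b < 1`.
* **Three-step QC for biomarker studies** — (1) outlier flagging against a
  study baseline (median + 3·MAD on log10 CI, one-sided), (2) group-bias
  rank tests (Mann–Whitney / Kruskal–Wallis), (3) candidate screening by
  Spearman correlation against marker panels and the CI (|rho| ≥ 0.7 flags).
* **Workflow profiling** — rank-abundance shift profiles vs. a neat
  baseline, ≥80% enrichment/depletion calls, sequence-derived
  physicochemical bias tests (MW, length, pI, GRAVY, aromaticity,
  instability index; Welch t), replicate CV distributions, PCA with
  3-nearest-neighbour imputation.
* **A synthetic-data generator** — plasma + cellular spike-in experiments
  with full ground truth (dilution series, combined contamination,
  centrifugation rescue, two-group artifact studies), so the entire pipeline
  is testable without raw data.

## Worked example

Derive a platelet marker panel from a simulated spike-in experiment, follow
the contamination index across a dilution series on a bead workflow, and run
the three-step QC on a two-group study containing a contamination-driven
false biomarker:

```r
library(plasmaQC)

plasma   <- generate_plasma_proteome(1000, seed = 7)
platelet <- generate_cell_proteome("platelet", n_proteins = 6000, seed = 8,
                                   plasma = plasma)

# marker derivation from pure-contaminant vs pure-plasma quadruplicates
ex    <- simulate_contaminant_experiment(platelet, plasma, workflow = "neat",
                                         seed = 9)
fc    <- compute_fold_changes(ex$contaminant, ex$plasma)
panel <- select_markers(fc, "platelet")
panel
#> marker_panel: 30 platelet markers (source: select_markers)
#>    protein_id cell_type fold_change rank mean_log10_intensity         cv exclusive_flag
#> 1    PLT.M001  platelet    5619.015    1             9.129204 0.03443532           TRUE
#> 2    PLT.M002  platelet    5619.015    2             9.052724 0.08423717           TRUE
#> ...
```

All 30 selected proteins are designed ground-truth markers, aligned at
1.1 × the largest finite fold change (5619) because they are never detected
in plasma.

```r
sim    <- simulate_dilution_series("platelet", "nonmagnetic", seed = 10,
                                   plasma = plasma, cell = platelet)
scores <- contamination_index(sim$matrix, panel)
cmp    <- fit_dose_response(scores, sim$samples)
cmp$preferred
#> [1] "power"
cmp$power
#> dose_response_fit [power]: a = 6.502e-05, b = 0.4828; r2 = 0.9910 (n = 32)
```

On the non-magnetic bead workflow the index grows as `count^0.48` — the
concave, saturating dose–response characteristic of finite bead capacity —
whereas the same series under the neat workflow is linear in count.

```r
study <- simulate_two_group_study(seed = 11)   # cases carry 5x platelet load
qc <- run_qc(study$matrix, study$samples, list(platelet = panel),
             candidates = c(study$true_biomarker, study$false_biomarker))
qc
#> qc_report: 40 samples, panels: platelet
#>   group bias [platelet]: mann-whitney p = 0.000921 (flag)
#>   candidates flagged: 1 / 2
qc$candidate_validation$per_candidate
#>   candidate max_abs_r top_marker   r_vs_ci artifact_flag
#> 1  PLS00100 0.3217636   PLT.M018 0.2720450          pass
#> 2  PLT.M040 0.9906191   PLT.M003 0.9855535          flag
```

The contamination-driven candidate (`PLT.M040`, a platelet protein outside
the QC panel) is flagged through its 0.99 correlation with panel markers;
the genuine biomarker (`PLS00100`, a plasma protein with a real 2× group
effect) passes. The group-level contamination bias is itself detected at
p < 0.001 — the signal that this cohort's "biomarkers" need scrutiny.

`write_qc_report(qc, "qc_out/")` emits a versioned JSON + TSV report.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline end to end on freshly simulated
data — marker derivation, dilution-series dose–response on a direct and a
bead workflow, and the three-step QC on a two-group artifact study — and
writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/contamination-qc.Rmd`) documents the
models, the synthetic world and its calibration, numerical conventions
(population-sd CV/z, missing-vs-zero handling, scale-safety guards), and
known limitations.
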