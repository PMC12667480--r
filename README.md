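# tlscape

Detection, scoring and survival analysis of **tertiary lymphoid
structures (TLS)** in imaging-based spatial transcriptomics of tumor
tissue, with a ground-truthed synthetic-tissue simulator.

TLSs are organized aggregates of B cells, NK/T cells and dendritic cells
that assemble inside tumors; their burden and maturity carry prognostic
information. Given per-cell counts with µm coordinates (CosMx-style),
`tlscape` localizes the constituent immune populations by marker-panel
scoring, delineates TLSs as spatial density clusters, and connects TLS
burden to expression programs and overall survival. It is written for
computational biologists who want each step of that pipeline as a plain,
deterministic, individually testable function with tabular (tibble)
inputs and outputs.

## The method at its core

* **Annotation.** Cells pass QC (detected genes in [500, 5000],
  mitochondrial fraction ≤ 20% by default), are log-normalized
  (`ln(1 + 10⁴·x/total)`), and typed by the argmax over per-type mean
  z-scores of a marker panel (B: *CD79A*, *MS4A1*; DC: *ITGAX*, *CD40*;
  NK/T: *CD3D*, *CD3E*, *GNLY*; plus myeloid, cancer, endothelial,
  fibroblast panels).
* **Detection.** Per sample, DBSCAN (ε = 0.08 in min-max-normalized
  coordinates, minPts = 100, Euclidean) clusters the B/NK-T/DC cells;
  clusters with **> 100** cells are TLS regions. Each region is
  summarized by its convex hull (monotone chain), shoelace area in mm²,
  and per-type composition; every cell inside a hull joins that region's
  compartment, the rest is nTLS. Called regions are validated by
  one-sided Wilcoxon tests of *MKI67*, *CXCR5*, *CCL2* (TLS > nTLS, BH
  adjusted).
* **Scoring.** Per-sample TLS burden — total TLS cell count or cumulative
  TLS area Σᵣ areaᵣ — splits the cohort at the median (high ⇔ statistic
  strictly > median). Region maturity is classified by a single-sample
  weighted-KS enrichment score (α = 0.25) of the germinal-center set
  {*BCL6*, *AICDA*, *CD38*, *ICOS*, *CXCR5*, *CXCL13*} on the region's
  mean expression; score ≥ cohort median ⇒ mature. AUCell-style
  recovery-curve scores (top 5% of ranks) are available per cell.
* **Inference.** Wilcoxon rank-sum (exact by enumeration for n ≤ 20,
  tie-corrected normal approximation otherwise), BH FDR, preset DE
  filters, hypergeometric over-representation over GMT collections,
  Kaplan-Meier product-limit curves S(t) = Π(1 − dᵢ/nᵢ), and the
  two-group log-rank test χ² = (O − E)²/V.
* **Simulation.** `simulate_sample()`/`simulate_cohort()` plant immune
  discs (150 µm radius, 90%/10% immune fractions in/out, negative
  binomial counts, marker-fold elevation, mito block) and draw survival
  from exponential proportional hazards on standardized TLS burden —
  providing exact ground truth (`truth_recovery()`: region
  precision/recall, cell-level adjusted Rand index) for every claim the
  tests make.

## Worked example

```r
library(tlscape)

out <- run_pipeline(file.path(tempdir(), "tls_run"), n_samples = 6, seed = 2024)
out$score_report
#> # A tibble: 6 × 6
#>   sample_id n_tls total_tls_cells cumulative_area_mm2 statistic group
#>   <chr>     <int>           <int>               <dbl>     <dbl> <chr>
#> 1 S01           4             804               0.467       804 high
#> 2 S02           2             486               0.291       486 low
#> 3 S03           4             846               0.514       846 high
#> 4 S04           4             803               0.497       803 high
#> 5 S05           3             739               0.452       739 low
#> 6 S06           4             799               0.476       799 low
```

Six simulated samples carried 2–4 planted TLSs each; the cohort median of
the TLS cell count (801) splits them into three high samples (804, 846,
803) and three low (486, 739, 799) — a sample is high only when its
statistic is strictly greater than the median. The called regions carry
geometry and maturity:

```r
out$regions[, c("region_id", "n_cells", "area_mm2", "maturity_label")]
#> # A tibble: 21 × 4
#>    region_id n_cells area_mm2 maturity_label
#>  1 S01_TLS1      209   0.133  mature
#>  2 S01_TLS2      202   0.106  mature
#>  3 S01_TLS3      199   0.128  immature
#>  4 S01_TLS4      194   0.0990 immature
#>  ...
```

TLS-associated genes are strongly elevated inside the called regions
(difference of compartment means on the log scale; one-sided Wilcoxon,
BH-adjusted p-values floored at the smallest positive double):

```r
out$validation
#> # A tibble: 3 × 4
#>   gene  effect         p     p_adj
#> 1 MKI67   3.80 2.23e-308 2.23e-308
#> 2 CXCR5   3.61 2.23e-308 2.23e-308
#> 3 CCL2    3.80 2.23e-308 2.23e-308

glance(out$logrank)
#> # A tibble: 1 × 3
#>    chi2    df p_value
#> 1 0.559     1   0.455
```

A six-sample demo cohort has essentially no power for survival — the
log-rank p of 0.455 is the honest result at this size. The calibration
and power of the same median-split log-rank analysis are established on
80-sample cohorts by the test suite and the acceptance script (null
rejection rate ≈ 0.04 at α = 0.05; power 1.0 at hazard coefficient 1).

`plot_spatial(out$cells, out$regions)` draws the tissue maps with dashed
region hulls, `autoplot(out$km$high)` / `plot_km_groups()` the survival
curves, and `autoplot(out$de)` a volcano of the TLS-vs-nTLS contrast.
`inst/cli/tlscape.R` exposes the same steps as shell subcommands
(`simulate`, `qc`, `annotate`, `detect-tls`, `score`, `diffexp`,
`survival`, `run-all`).

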