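# histoclock

Histone-modification epigenetic clocks from ChIP-seq peak signal.

DNA-methylation clocks dominate biological-age estimation, but histone
marks (H3K27ac, H3K4me1/3, H3K36me3, H3K27me3, H3K9me3) carry
complementary, mechanistically rich information about chromatin aging —
including nonlinear trajectories and the fragmentation of
super-enhancers that linear methylation models miss. `histoclock` is an
R package for analysts who have replicated peak calls and per-peak read
counts for age-annotated samples and want to build, evaluate, and
stress-test a tissue- and mark-specific age predictor from them.

## What it computes

Starting from per-sample peak calls (BED/narrowPeak/broadPeak), a raw
count matrix (peaks × samples), and a sample sheet (age, sex, batch,
tissue, mark):

1. **Consensus peaks** — per age group, base pairs covered by ≥ *k*
   replicate peak calls are kept and merged; subconsensus sets are
   merged across groups (`build_consensus`).
2. **Signal quantification** — read densities
   *d = c / (L/10³) / (R/10⁶)* (count over peak length in kb over
   reads-in-peaks in millions), then log₂ transform and background
   subtraction (matched input, or per-sample median centering)
   (`quantify_density`, `log2_background_subtract`).
3. **Batch correction** — parametric empirical-Bayes location/scale
   adjustment that preserves age and sex covariates, with before/after
   F-statistic and PCA diagnostics (`fit_adjust`, `batch_diagnostics`).
4. **Screening** — per-peak Spearman ρ with age, BH-adjusted p-values,
   and the joint candidate filter |ρ| ≥ 0.5 & p ≤ 0.05; PC1–age
   correlation and Fisher-exact annotation enrichment
   (`spearman_screen`, `candidate_filter`, `fisher_enrichment`).
5. **The clock** — an elastic net
   min (1/2n)·Σ(y − ŷ)² + λ(α‖w‖₁ + (1−α)/2‖w‖₂²)
   over standardized peak features, with (α, λ) chosen by
   age-stratified leave-one-group-out cross-validation (11 groups by
   default, standardization re-estimated per fold), reporting RMSE,
   MAE and Pearson r (`histone_clock` and its S3 methods).
6. **Evaluation protocols** — Gaussian-noise robustness over
   σ ∈ {0, 0.3, …, 1.5}; Mann–Whitney curve comparison; quantile-rank
   benchmarking against a reference RMSE distribution; two-model
   saturation analysis with an "artificially doubled" estimated mode
   (`noise_robustness`, `compare_curves`, `quantile_rank`,
   `saturation_analysis`).
7. **Chromatin structure** — enhancer stitching (12.5 kb), ROSE-style
   rank–signal super-enhancer cutoff, per-age-group fragmentation
   trends, and LOESS age-trajectory inflection detection
   (`stitch_enhancers`, `classify_super`, `fragmentation_stats`,
   `loess_trajectory`).
8. **Synthetic data** — `simulate_chipseq` generates peaks, counts,
   replicate calls, sample sheets and ground truth with planted linear
   and breakpoint age effects, batch effects and Poisson sequencing
   noise; `simulate_paired_treatment` plants rejuvenation in pre/post
   pairs; `simulate_enhancer_landscape` plants super-enhancer
   fragmentation.

`run_pipeline()` chains the stages with a YAML config and writes a JSON
provenance manifest; `inst/cli/histoclock.R` exposes the same stages as
shell subcommands.

## Worked example

```r
library(histoclock)

sim <- simulate_chipseq(n_peaks = 2000, n_samples = 100,
                        fraction_linear = 0.05, fraction_nonlinear = 0,
                        age_range = c(5, 75), exact = TRUE, seed = 2)
x   <- log2(sim$signal$values)
fit <- histone_clock(x, sim$samples$age, n_groups = 11)
fit
#> Histone-modification epigenetic clock (elastic net)
#>   features: 95 nonzero of model; alpha = 0.10, lambda = 2.843
#>   LOGO-CV: RMSE 2.50 y, MAE 2.00 y, Pearson r 0.994
```

The fit reports the cross-validated accuracy (every sample predicted
while its whole age stratum was held out): a mean absolute error of
about 2 years and Pearson r ≈ 0.99 on this synthetic regime, with ~95
of 2,000 peaks retained in the sparse model. `plot(fit)` draws
predicted versus chronological age; `predict(fit, newdata)` applies the
clock (with its stored training standardization) to new samples, and
`age_gap(fit, x, meta)` turns predictions into age-acceleration and
paired scaled-gap statistics.

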