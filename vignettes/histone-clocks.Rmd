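---
title: "Building and stress-testing histone-modification age clocks"
author: "histoclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and stress-testing histone-modification age clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoclock)
```

## The model

A histone-modification clock is a sparse linear predictor of
chronological age from per-peak ChIP-seq signal. For a sample with
standardized peak features $z_f$ the predicted age is
$\hat y = b + \sum_f w_f z_f$, with $(w, b)$ minimizing

$$\frac{1}{2n}\sum_i (y_i-\hat y_i)^2 \;+\;
  \lambda\left(\alpha\lVert w\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert w\rVert_2^2\right),$$

the elastic net: the L1 term selects a small peak panel, the L2 term
stabilizes selection among correlated peaks. The solver is glmnet.
One solver detail matters for reproducibility: for Gaussian responses
glmnet internally rescales the quadratic penalty by the standard
deviation of $y$. `fit_elastic_net()` reparameterizes $(\alpha,
\lambda)$ so that it solves exactly the objective above (we verify this
against the closed-form ridge solution in the tests), while
`histone_clock()` keeps its selected $\lambda$ on the solver's own path
scale, which is what it stores, serializes and reuses for prediction.

### Hyperparameter selection without leakage

Samples are split into age strata (default 11 equal-width bins over the
observed age range; empty bins are dropped, and a quantile mode is
available). For every $(\alpha, \lambda)$ on a grid
($\alpha \in \{0, 0.1, \dots, 1\}$, 100 log-spaced $\lambda$ per
$\alpha$), each stratum is held out in turn; feature means and SDs are
re-estimated **on the training folds only**, and the held-out stratum
is predicted. The pair minimizing pooled cross-validated RMSE wins,
with ties broken toward the larger penalty (the sparser model), and the
final model is refit on all samples. The $\lambda$ candidate paths are
derived from the full matrix — this is the standard convention of
`cv.glmnet` and fixes only the *grid*, never the per-fold fit or
scaling.

Age-stratified leave-one-group-out CV is deliberately harsh: each fold
extrapolates beyond the training age range of its stratum. A useful
consequence we document (and test) is that with uninformative features
the pooled CV correlation is *negative*, not zero — each fold predicts
near its training-mean age, which anti-correlates with the held-out
stratum. LOGO-CV therefore cannot flatter a useless clock; our null
test asserts the absence of optimistic bias rather than an exactly
centered null.

## From counts to features

* **Consensus peaks.** Replicate consistency is defined at base-pair
  resolution: positions covered by at least `min_replicates` replicate
  calls (default 2) survive within an age group; subconsensus sets are
  merged across groups. This rule is order-invariant and testable
  against a position-wise coverage oracle. Coordinates are BED-style
  0-based half-open throughout; abutting intervals merge at
  `max_gap = 0`; chromosome names are opaque strings (no `chr1` vs `1`
  aliasing), keeping the code genome-build-agnostic.
* **Density.** $d = c/(L/10^3)/(R/10^6)$ with $R$ the sample's
  reads-in-peaks; densities are invariant to rescaling a sample's
  counts.
* **Background.** $\log_2(d + 1)$ (pseudocount configurable), minus the
  matched input control when provided, minus the per-sample median
  otherwise. We apply the subtraction on the log scale; the choice
  matters (linear-scale subtraction differs) and median centering is
  the download-free default when no input track exists.
* **Standardization** uses the unbiased ($n-1$) SD, is always estimated
  on training folds only, and maps constant features to zero with a
  flag.

## Batch correction

`fit_adjust()` implements the parametric empirical-Bayes
location/scale model: per-feature regression on batch indicators plus
biological covariates (age, sex), standardization by feature grand mean
and pooled variance, per-(batch, feature) additive effects shrunk
toward a per-batch normal prior and variance factors toward an
inverse-gamma prior (method-of-moments hyperparameters, iterated until
the relative change drops below 1e-4 or 100 iterations), then back
transformation restoring covariates and grand mean. Because age and sex
sit in the design, their signal is preserved by construction; the tests
verify that on simulations with batches *correlated* with age, the
post-correction slope estimates beat the uncorrected ones in ≥ 90% of
replicates, and that the output matches the reference ComBat
implementation to within 0.02 on planted-effect data. Batches with
fewer than two samples are folded into a `"small"` pseudo-batch with a
warning rather than failing; a reference-batch mode is intentionally
not provided.

## Screening and enrichment

Spearman ρ is computed on mid-ranks (vectorized over all peaks);
p-values use the t-approximation on $n-2$ df, the standard choice at
dozens-to-hundreds of samples, with an exhaustive-permutation mode for
$n \le 8$ used in testing. BH adjustment is the step-up rule.
Genome-wide FDR control frequently leaves no survivors at moderate
sample sizes, so candidate nomination uses the joint nominal filter
|ρ| ≥ 0.5 and p ≤ 0.05 (both inclusive); the adjusted p-values stay in
the table for honest reporting. Fisher enrichment uses the classical
two-sided convention (summing hypergeometric probabilities ≤ the
observed table's); the doubling convention differs and is not used.
PC1 sign is fixed by making the largest-magnitude loading positive, so
the reported PC1–age correlation is deterministic.

## Evaluation protocols

* **Noise robustness.** Gaussian noise is injected into the
  *standardized* feature space of the evaluation samples — the σ grid
  0–1.5 in steps of 0.3 only makes sense in SD units — with the trained
  model held fixed; σ = 0 skips the noise draw entirely so the baseline
  is bit-identical. Curves are compared per-σ with two-sided
  Mann–Whitney tests (exact for small untied samples).
* **Benchmark rank.** The clock's RMSE is placed in a reference RMSE
  distribution by midrank quantile, which is tie-safe.
* **Saturation.** Per repetition a fixed test set (20%) is held out,
  the rest is split into disjoint halves, and one clock per half is
  trained at each size $n$; Pearson r between the two prediction
  vectors on the shared test set measures stability. The "estimated"
  mode duplicates every sample exactly (no jitter) before the same
  procedure, approximating larger effective sample sizes. Duplicated
  copies may land in different halves; that is the intended estimation
  convention.

## Chromatin structure

Enhancer peaks within 12.5 kb stitch into domains (the widely used
convention; configurable). Super-enhancers are classified by the
rank–signal elbow: with rank and signal scaled to $[0,1]$, the cutoff
sits where the discrete slope first reaches 1; a perfectly linear curve
ties everywhere and resolves to the highest-ranked point (exactly one
super-enhancer), a documented degenerate-case convention.
Fragmentation statistics report, per age group, super/typical counts
and mean lengths with Spearman trends against group age; constant
metrics get a trend of 0 rather than NA so that identical landscapes
read as "no trend".

Trajectories are LOESS fits (local linear, tricube kernel, span 0.5,
1-year grid by default). Inflections are grid ages where the second
finite difference changes sign with magnitude above a noise floor (10%
of the maximum |curvature|); curvature below a scale-aware numerical
threshold is treated as zero so constant and linear signals never
report inflections. The detector is one defensible formalization of
"inflection around an age"; span, grid step and floor are all
parameters.

## The generator and what passing tests mean

`simulate_chipseq()` emulates: a latent log2 density per peak
(baseline ~ N(3, 1)); linear age effects $\beta\,(a-\bar a)/\text{range}$
with $\beta = \pm$`effect_size` on a planted fraction; logistic
breakpoint effects centered at 40 or 60 years (scale 3 y) on another
fraction; per-feature additive batch shifts ~ N(`batch_shift`, 0.1) and
a multiplicative noise-SD factor for non-reference batches; i.i.d.
Gaussian noise (`noise_sd`, default 0.5 log2 units); Poisson counts
with expectation proportional to density × peak length at a given
reads-in-peaks depth (2e6 default), so the density normalization
inverts the model; and per-age-group replicate peak calls with boundary
jitter (SD 50 bp) and 97% detection. Ages are uniform over 5–75 years
by default (an explicit age list is accepted for irregular
distributions); sex is balanced and shuffled so it is never aliased
with batch. The default `effect_size = 1.7` places planted Spearman
correlations near 0.7 via
$r = \beta\,\mathrm{sd}(u)/\sqrt{\beta^2\mathrm{var}(u)+\sigma^2}$ with
$u$ uniform on $[-0.5, 0.5]$ — the screening regime the candidate
filter is designed for. `exact = TRUE` returns the latent densities
(the infinite-depth limit) for oracle-sharp tests. Counts are Poisson,
not negative binomial, to keep the generative model invertible in
tests.

The generator does **not** emulate: irregular real age distributions,
mark-specific signal-to-noise, correlated peaks (LD-like blocks),
copy-number artifacts, or peak-calling errors beyond boundary jitter
and dropout. Passing recovery tests therefore shows the machinery is
correct under its stated model, not that any particular tissue will
yield a clock of a particular accuracy.

`simulate_enhancer_landscape()` plants fragmentation mechanistically:
cluster constituents lose signal with age in proportion to their
centrality (per-cluster rates jittered ×0.5–1.5 so clusters split at
staggered ages); constituents falling below the detection threshold
open gaps larger than the stitch distance, so domains split — more,
shorter super-enhancers with age, the signature the fragmentation
statistics are designed to detect.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the screening regime at
2,000 peaks × 60 samples, the clock regime at 2,000 × 100 with the full
α grid, batch correction at 200 × 60 with 20 slope-recovery replicates,
saturation at sizes 6–26 from an 80-sample pool (8 repetitions, single
α), and 100-instance oracle sweeps for the exact statistics — sizes
chosen so the whole suite completes in a few minutes while every
planted effect is comfortably detectable. Coordinate-descent tolerance
is 1e-12 with exact refits at selected penalties; CV ties break toward
larger λ; all randomness flows through explicit seeds, and identical
configs reproduce byte-identical pipeline outputs (hashed in the
provenance manifest).

## Known limitations

* Published-scale accuracy figures for clocks of this kind (blood
  H3K27ac models with MAE near 5 years) come from large
  controlled-access consortium datasets; nothing here claims to
  reproduce them at desk scale.
* The scaled age gap is defined as
  $(\hat y_{\text{post}}-\hat y_{\text{pre}})/\hat y_{\text{pre}}$; an
  absolute-difference mode exists because the relative form is
  unstable when predicted pre-treatment ages approach zero.
* Cross-mark clocks are plain feature concatenation with mark-prefixed
  peak ids; no cross-mark coupling is modeled.
* Super-enhancer classification is geometry on the rank–signal curve;
  it has no notion of constituent identity across age groups.
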