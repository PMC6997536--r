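---
title: "Consensus ranking of miRNA target predictions: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking of miRNA target predictions: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(miragg)
```

## The problem and the model

miRNA target predictors disagree because they exploit different signals —
seed complementarity, interspecies conservation, hybridization free
energy, site accessibility. Each tool's list is best read as a noisy
ranking of the same underlying universe of miRNA::mRNA interactions.
`miragg` treats consensus building as an order-statistics problem on
normalized ranks.

**Normalization.** Within source *j* (list length *m_j*), an interaction
at rank *k* gets relative rank *k/m_j*, so every source's worst listed
interaction sits at exactly 1. Normalizing by each list's own length —
rather than by a shared universe size — is deliberate: sources differ
enormously in coverage, and per-list normalization makes "bottom of the
list" mean the same thing everywhere. Tied raw scores receive midranks
(the average of the tied positions), which is deterministic and
order-independent.

**Imputation.** An interaction a source does not list is imputed at the
maximum relative rank 1. This is the most pessimistic assignment
consistent with the normalization: absence is treated as "ranked worst",
never as missing-at-random. The synthetic generator's `coverage_bias`
option exists precisely to probe this choice (see below).

**Scoring.** Under the null hypothesis that an interaction's normalized
ranks are independent uniforms, the k-th smallest of *n* ranks follows
Beta(k, n−k+1). `beta_scores()` returns the CDF of that law at each
order statistic; `rra_rho()` takes the minimum over k and applies a
Bonferroni factor *n*, capped at 1, giving a conservative consensus
p-value. `stuart_q()` computes the exact joint probability that all *n*
order statistics are at most their observed values via the alternating
recursion; with *n* the number of sources (≤ ~10) the recursion is exact
in double precision and needs no factorial rescaling. The simpler row
summaries (mean, median, min, geometric mean) are also available; the
replicated benchmark is how one decides which to deploy, and on
equally-informative synthetic sources the mean is consistently the
strongest, matching its standing as the production choice for this kind
of ensemble.

The mean score is reported as the raw arithmetic mean of the normalized
ranks. `bates_p()` maps it to a p-value under the Irwin–Hall/Bates null;
the transform is strictly monotone, so the reranking is identical and
the transform is offered only for presentation on a significance-like
scale. Near a mean of 1 the Bates CDF saturates to 1.0 in double
precision, so the p-value can tie where the raw means still differ —
another reason the raw mean is the canonical score.

**Tie-breaking.** Equal aggregated scores are ordered by more sources
present first, then miRNA and gene identifier, so output is fully
deterministic.

**Threshold.** `filter_by_threshold()` defaults to 0.05, the recommended
working cutoff for the significance-like scores; for the plain mean score
the cutoff is a list-fraction, not a significance level, and should be
chosen from the F-score curve instead.

## Evaluation conventions

All metrics take scores with lower = better and 0/1 validation labels.

- **ROC.** Thresholds sweep distinct score values; tied scores form a
  single step, which makes the trapezoidal AUC equal the Mann–Whitney
  probability with half credit for ties (asserted to 1e-9 in the tests).
- **Partial AUC.** The area of sensitivity over specificity ∈ [0.9, 1]
  is reported raw (maximum 0.1), with linear interpolation where a
  segment crosses the band boundary. A McClish-standardized variant is
  available via `partial_auc(standardize = TRUE)`; raw is the default
  because its magnitudes are directly comparable across curves of the
  same band.
- **PR.** The PR area is the average-precision summation
  Σ precision·Δrecall over threshold steps. Linear interpolation between
  PR points is deliberately avoided: it is optimistically biased, and
  the step summation makes results reproducible bit for bit. One
  consequence worth knowing: for a *random* ranking the average
  precision is a slightly optimistic estimator of the prevalence — each
  positive counts itself in its own precision, an O(1/#positives) bias —
  so the random-baseline calibration test asserts agreement with the
  prevalence at the Monte-Carlo resolution of a single replicate rather
  than at the (ever-shrinking) standard error of the replicate mean.
- **F-scores.** F(i) = 2PR/(P+R) is computed at every rank cutoff i,
  with F = 0 where no positive has been retrieved. `f_at_fraction`
  reports F at cutoff round(x·N) (minimum 1) for a fraction grid
  defaulting to {0.05, 0.1, 0.2, 1}; `mean_f` is the mean of the
  cumulative F-curve over all cutoffs. The single-number "F over all
  interactions" is reported as `mean_f` by design: at the 100% cutoff
  every method on the same data shares one F value (recall 1, precision
  = prevalence), so a per-method summary must integrate the curve.

## The benchmark harness

`intersect_common()` restricts to interactions every compared method
scores — metrics are only comparable on a shared universe.
`subsample_replicates()` draws subsets without replacement, stratified on
the label so each replicate's positive count equals
round(size · parent prevalence) exactly; replicate *i* uses seed
`seed + i`, making the whole protocol reproducible from one integer.
`rm_anova()` is the one-way within-subject decomposition
(F = MS_method / MS_method×replicate); no sphericity correction is
applied. `dunnett_posthoc()` adjusts the paired-t contrasts against the
control by the null distribution of the maximum |t|, estimated from
seeded multivariate-normal draws with the *estimated* within-subject
covariance of the difference vectors — closed-form Dunnett tables assume
an equicorrelation that repeated measures violates, while the simulation
is assumption-light and testable (its familywise error is checked by
simulation in the suite). With a single contrast the exact paired-t
p-value is returned. Adjusted p-values are never allowed below their
unadjusted counterparts.

## The synthetic generator

`simulate_sources()` emulates the statistical structure of a multi-source
benchmark: a universe of interactions, an exact count of validated ones
(default prevalence 5%, matching the composition of curated testing
sets), and per-source latent scores `signal_j · label + N(0, 1)` so a
source's individual AUC is a monotone function of `signal_j` (signal 1 ≈
AUC 0.76). Coverage below 1 drops a label-independent random subset of
each source's list, emulating the heavy divergence of real predictors'
coverage (commonly <10% of the pooled universe is shared by all tools);
`coverage_bias` makes positives more likely to be listed, for probing the
max-rank imputation under informative missingness. The default noise is
additive Gaussian on the latent score; `noise_model = "rank_jitter"`
perturbs the normalized true rank directly, a heavier-tailed rank-space
alternative. The generator does *not* emulate correlated errors between
sources (real predictors share sequence features, so their mistakes
correlate), sequence-level covariates, or non-stationary prevalence
along the list — passing benchmarks on synthetic data therefore
demonstrates correctness of the machinery and the expected ensemble
gain under independence, not field performance on any real database.

Profiles: `tiny` (n = 100, coverage 0.8, signal 1.5 — examples and the
golden regression files), `bench` (n = 50,000, full coverage, signal 1,
prevalence 5% — the replicated comparisons), `paper_scale` (n = 10⁶,
same structure at full published scale, for timing studies).

## Problem sizes and numerical choices

The shipped test suite runs the replicated comparison on a 50,000-
interaction universe with 10 stratified replicates of 10,000 — large
enough that the aggregate-vs-single-source gap (≈ 0.15 AUC at equal
signal 1) dwarfs replicate noise, and small enough to rerun the whole
protocol twenty times while checking the detection rate. Subsampling
replicates at the full universe size would make them identical and the
within-subject error term degenerate, which is why replicates are drawn
at a fifth of the universe. Monte-Carlo sizes: 10⁶ draws for the
order-statistic oracles, 10⁵ for the Dunnett max-|t| null, 5,000 items
for the null-calibration check (one-sided Kolmogorov–Smirnov at
α = 0.01). Degenerate inputs are handled explicitly: zero within-subject
error variance reports F = 0/p = 1 when methods agree and a flagged
p = 0 otherwise; zero-variance paired differences are flagged rather
than silently propagated; empty intersections warn and return an empty
set.

## Known limitations

- Imputation at rank 1 penalizes low-coverage sources' unique findings;
  under strongly informative missingness (positives preferentially
  listed) the penalty is conservative for the consensus.
- The rho score's Bonferroni correction is conservative (super-uniform
  null), so its absolute values understate significance; use it for
  ranking and thresholding, not as a calibrated p-value.
- The Dunnett adjustment is Monte-Carlo: adjusted p-values have
  resolution 1/(draws+1) and are reproducible only with the seed.
- Pathway ranking divides by all member genes by default; restricting
  the denominator to genes present in the prediction universe
  (`denominator = "universe"`) can flip the order of sparsely-predicted
  pathways — the choice is exposed because either convention is
  defensible.
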