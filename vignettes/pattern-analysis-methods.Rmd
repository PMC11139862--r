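---
title: "Methods: latent-pattern phenotyping of longitudinal sepsis transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-pattern phenotyping of longitudinal sepsis transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

Whole-blood RNA sequencing of a sepsis cohort sampled longitudinally — at
enrolment (0 h), 6 h, 24 h, 48 h, 72 h, 28 days, 6 months and 12 months —
captures both the acute host response and, in survivors, the recovery of the
transcriptome toward the healthy-donor state. `sepsisPatterns` packages the
analysis chain for such cohorts:

1. **Factorization.** The log2 TPM matrix `D` (genes x samples) is
   decomposed into non-negative matrices, `D ~ A %*% P`: an amplitude matrix
   `A` (genes x K) describing each gene's weight in each latent pattern, and
   a pattern matrix `P` (K x samples) giving each sample's value for each
   pattern.
2. **Projection.** External bulk samples or single cells are mapped into the
   learned latent space by solving, per target column over the shared genes,
   `min_w ||d - A w||^2` (optionally with `w >= 0`), so pattern biology can
   be interrogated in independent datasets without joint normalization.
3. **Outcome modeling.** Pattern values are related to 28-day mortality with
   per-timepoint logistic regression adjusted for age and sex (in-sample
   AUROC by the rank formulation), patterns are labelled *prognostic*
   (discriminative at enrolment) or *dynamic* (discriminative only from 48 h
   on), and multivariable structure is probed with repeated stratified
   cross-validated random forests (Gini importance), additive AUROC over the
   importance ordering, and per-pattern odds ratios per 1 SD.
4. **Enrichment.** Cell-type significance of projected pattern values uses
   group-size-preserving label permutations of group means; signature gene
   sets are scored by cumulative and mean amplitude ranks against an
   explicit Monte-Carlo background (random rank draws), with the exact
   two-sample Kolmogorov-Smirnov test comparing set ranks with background
   ranks.
5. **Trajectories.** Subject and group movement through pattern space:
   per-timepoint group means, net displacement (first to last observed
   timepoint), per-subject paths, and a recovery index — the slope of the
   standardized distance to the healthy centroid against `log(hours + 1)`.

Because the cohort data that motivated this design are access-restricted,
the package ships a synthetic-cohort generator with known ground truth; all
tests and the acceptance script run against it.

## The factorization model and its numerical choices

The factorization minimizes

```
||D - A P||_F^2 + lambda_A * sum(A) + lambda_P * sum(P),   A, P >= 0
```

by L1-penalized multiplicative updates with random restarts, returning the
restart with the lowest final objective. This is a deterministic,
desk-scale counterpart of the sparse Bayesian NMF samplers used for this
kind of analysis: the `D ~ A P` contract and the sparsity intent are the
same, while posterior uncertainty over factors is deliberately out of
scope. Choices that matter:

- **Sparsity weights** default to `0.01 * mean(D)` for both factors: strong
  enough to suppress spurious dense loadings, weak enough not to bias the
  reconstruction visibly (relative reconstruction error on the default
  synthetic cohort is ~0.11 at K = 30).
- **Initialization** is uniform(0,1] scaled by `mean(D)/K`, restart `r`
  seeded with `seed + r`; multiplicative updates then rescale quickly, so
  the initial scale only needs to be order-of-magnitude right.
- **Convergence**: relative objective change below `tol` (default 1e-5) or
  `max_iter` iterations (default 2000 for direct calls; the pipeline driver
  uses 250, which the loss traces show is past the knee at the shipped
  problem sizes). The trace is checked non-increasing to 1e-9 relative — a
  property of the multiplicative updates that doubles as a regression test.
- **Scale identifiability**: after fitting, each row of `P` is rescaled to
  unit maximum and the inverse scale folded into `A`, leaving `A %*% P`
  unchanged; pattern values are then comparable across patterns.
- **Gene filtering** (`filter_genes`): genes with zero variance or detected
  in under 5% of samples are dropped before factorization to avoid
  degenerate updates.
- **K is a configuration input** (default 30, the configuration of the
  study design this mirrors); the package does not select K automatically.

PCA (`run_pca`) is gene-centered SVD without variance scaling; each
component's sign is fixed so the largest-magnitude gene loading is
positive, and gene means are stored so external data can be projected onto
the same axes.

## Projection conventions

The projection regression uses no intercept and no target re-centering by
default: amplitudes and log2 expression are both non-negative scales, and
the self-projection identity (projecting the source data recovers `P`
exactly) only holds without centering. A per-gene centering flag exists for
targets on incommensurable scales. The default solver is unconstrained
least squares (SVD-based, minimum-norm under rank deficiency, with a
warning); non-negative least squares is available where strictly
non-negative pattern weights are needed. A guard requires at least 50% of
source genes to be found in the target (override with
`allow_low_overlap = TRUE`), which catches silent identifier mismatches
across platforms.

## Outcome modeling choices

- **The 117-subject convention.** Mortality models keep only sepsis
  subjects with a known 28-day outcome; with the default cohort composition
  (63 survived / 54 died / 3 unknown among 120 subjects) this retains 117.
- **Which samples feed the random forest**: one row per subject at the
  enrolment (0 h) sample by default, configurable to any timepoint. (The
  alternative — a subject-level mean — mixes acute and recovered states and
  is harder to interpret prognostically.)
- **Resampling**: stratified 70/30 train/test resplits (10 by default);
  within each training portion, stratified 10-fold cross-validation
  repeated 10 times; Gini importances averaged over all fold models and
  resplits; held-out AUROC computed on each 30% test portion from a forest
  refit on the full training portion. Forests use 500 trees.
- **In-sample vs held-out AUROC**: the per-timepoint logistic AUROC table
  is in-sample (it describes association, pattern by pattern), while all
  random-forest AUROCs are held-out (they describe prediction). The two are
  intentionally not comparable.
- **Prognostic/dynamic threshold** defaults to AUROC 0.70 — comfortably
  above chance yet attainable by single patterns; the dichotomy is
  qualitative and the threshold is an explicit parameter.
- **Odds ratios** are univariate logistic coefficients on scaled pattern
  values, exponentiated, with Wald 95% intervals; scaling makes them "per
  1 SD" and comparable across patterns.
- **Differential expression** is the Welch unequal-variance t-test with
  Benjamini-Hochberg adjustment, applied per timepoint-vs-healthy family.
  Zero-variance genes with unequal means are flagged degenerate (`p = 0`)
  rather than silently dropped.

## Permutation and rank enrichment

All permutation p-values use the add-one estimator `(r + 1) / (n + 1)`, so
the smallest attainable p is `1/(n_perm + 1)` and zero is impossible;
resolving significance near 1e-5 therefore needs at least 99,999
permutations. Cell-type tests permute labels preserving group sizes (the
natural null for "is this group's mean projected value high"). Gene-set
rank draws are without replacement within a draw — a draw models a gene
set, and a set cannot contain a gene twice. Ties in gene statistics get
average ranks; top-N set construction breaks ties lexicographically. The
background model draws `set_size` distinct ranks per iteration
(defaults: 20 ranks, 10,000 iterations, per pattern), and its grand mean
rank estimates `(G + 1)/2`. The exact KS p-value is computed exactly for
`n * m <= 10000` and asymptotically (tagged) beyond.

## What the synthetic generator emulates — and what it does not

The generator draws a sparse exponential amplitude matrix (a configurable
fraction, default 0.7, of genes zeroed per pattern — mimicking the sparse
structure the factorization assumes) and builds pattern weights from an
explicit temporal model: survivors follow
`w(t) = w_healthy + (w_acute - w_healthy) * exp(-t / tau)` (default
`tau = 72 h`), non-survivors stay at their enrolment level and contribute
no samples after 72 h, and subjects carry Gaussian between-subject jitter
(SD 0.15 weight units). Prognostic patterns separate outcomes at enrolment
(default effect 1.5 SD); dynamic patterns start equal in both groups at a
2 SD acute elevation and separate as survivors decay. Unknown-outcome
subjects follow survivor dynamics but carry the label `unknown`, so the
117-subject filter is exercised without inventing biology. Noise is
mean-preserving multiplicative log-normal on TPM (default sigma 0.2;
Poisson counts optional) — standard surrogates for RNA-seq variability.
Default sizes mirror the motivating cohort: 120 sepsis subjects
(63/54/3 survived/died/unknown), 42 healthy donors, retention
probabilities that yield roughly 570–620 samples, 2,000 genes, 6 true
patterns.

What it does **not** model: library-size and batch effects, within-subject
autocorrelated noise beyond the shared subject-level acute weight,
gene-gene correlation beyond the factor structure, census-matched
demographics, or read-level sampling. Passing tests on these cohorts
therefore demonstrate that the estimators recover a known generative truth
under realistic noise — not that real cohorts satisfy the generative
assumptions.

Problem sizes in the test-suite and acceptance runs are chosen at desk
scale: factorization recovery uses 500 genes x 100 samples with K_true = 4
at noise sigma 0.1 across three seeds; the end-to-end run uses the full
default cohort (2,000 genes, ~620 samples, K = 30) with 2 restarts and 250
iterations, which the loss trace shows is converged for this size.

## Trajectory conventions

Net displacement is the distance between the first and last *observed*
group means — matching the "net movement" reading of recovery — not path
length; missing timepoints are omitted, never interpolated or zero-filled.
Group means are per-sample (subjects with more samples weigh more); a
per-subject weighting would be the natural alternative where dropout is
outcome-correlated, and per-subject paths are exposed so users can build
it. The recovery index regresses on `log(hours + 1)` because the design
spans 0 to 8,760 hours with dense early sampling; plain hours is an
option.

## Known limitations

- The factorization is a point estimator; it reports no uncertainty over
  `A` or `P`, and pattern identity across different K or different seeds is
  only as stable as the data make it.
- Greedy cosine matching of recovered to true patterns can be fooled when
  two true patterns are highly correlated; it is a diagnostic, not part of
  the inference path.
- The in-sample AUROC table will flatter small timepoints; cells with
  fewer than 5 subjects per class are flagged unreliable rather than
  suppressed.
- The pipeline driver's importance stage presumes a binary outcome; no
  competing-risk or time-to-event modeling is included.
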