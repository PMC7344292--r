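---
title: "Consensus factor analysis for multi-omics subtyping and risk prediction"
author: "consensusFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus factor analysis for multi-omics subtyping and risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusFA)
```

## The problem

Molecular disease subtypes -- patient subgroups with genuinely different
clinical trajectories -- are rarely visible in any single measurement
platform. `consensusFA` integrates several omics matrices measured on the
same patients (for example mRNA expression, DNA methylation beta values and
miRNA expression, each a patients x features matrix) to

1. discover subtypes whose survival profiles differ (unsupervised), and
2. predict a per-patient survival risk score from molecular data alone
   (supervised), given a training cohort with follow-up information.

Both tasks share one front end: noise-robust feature filtering followed by
repeated factor analysis of the patient-patient correlation matrix.

## The model, stage by stage

### Feature filtering by encoder-weight variability

Tens of thousands of features per platform are mostly uninformative for
distinguishing patients. We train a one-hidden-layer linear autoencoder
whose encoder weights are clamped non-negative after every optimizer step,
on the per-feature standardized matrix, and score each feature by the
variance of its encoder weights across hidden units
(`train_weight_profile()`). Features that participate in structure shared
across patients acquire large weights on some hidden units and none on
others (high variance); features carrying only independent noise keep
small, near-uniform weights; constant features never move from their
constant initialisation and score exactly zero.

Two implementation choices matter and are deliberate:

* **Plain SGD with momentum, not an adaptive optimizer.** The selection
  signal lives in the *relative magnitude* of gradients: shared structure
  generates large, coherent gradients. Adaptive per-parameter step scaling
  (Adam-style) normalizes that signal away -- in our experiments it
  reliably inverted the ranking, because late-phase training dedicates
  hidden units to reconstructing individual noise features.
* **Strong decoupled L2 weight decay (`weight_decay = 80` on the
  per-feature-normalized loss).** With far fewer hidden units than
  features, a unit spent on a lone noise feature buys one feature's
  variance of loss reduction, while a unit aligned with a correlated block
  buys many times that; weight decay prices the noise pathways out. The
  decay is applied multiplicatively outside the momentum buffer so the
  strong pull cannot be amplified into oscillations, keeping the logged
  objective non-increasing up to mini-batch noise. The default was chosen
  from the wide stability plateau (decay 50--100 x learning rate
  0.001--0.005 behave identically on planted-signal benchmarks).

Defaults: `hidden_dim = 50`, `epochs = 50`, batch size 32, learning rate
0.003. `select_features()` keeps the `n_keep` (default `min(2000, p)`)
highest-variability features, ties resolved toward the lower column index.
A deterministic variance ranking (`variance_profile()`,
`filter.method = "variance"`) is available when an optimizer-free filter is
preferred; it ranks by raw feature variance, which is informative only
before standardization. When `n_keep >= p` the filter is a no-op and
training is skipped.

### Patient-mode minimum-residual factor analysis

Classical factor analysis models the feature-feature correlation matrix --
a p x p object, hopeless at p in the tens of thousands. We instead fit the
**patient-patient** Pearson correlation matrix C (n x n, with features
standardized first so no platform scale dominates): find the n x k loading
matrix Lambda minimizing

    sum_{i != j} (C_ij - (Lambda Lambda^T)_ij)^2,

the minimum-residual (MINRES) objective -- the diagonal (communalities) is
free. Lambda itself is the k-dimensional patient embedding: it preserves
pairwise patient correlations, which is exactly what the downstream
clustering consumes, and the cost scales with the number of patients
(hundreds), not features. Optimization is L-BFGS-B with the analytic
gradient `-4 (C - Lambda Lambda^T)_offdiag Lambda`, initialised from the k
leading eigencomponents (`v_j sqrt(lambda_j)`, each eigenvector's
largest-magnitude element made positive, so the fit is deterministic with
no rotation applied). Convergence: objective improvement below `fa.tol`
(default 1e-6) or `fa.max_iter` (default 1000) iterations; the returned
fit never regresses behind its initialisation.

Because any single factor count k can misrepresent the data, the pipeline
fits a whole grid (`fa.factor_counts`, default 2..10, capped at n-1) per
omics and carries all representations forward. Nine embeddings per omics
balances ensemble diversity against runtime; the residual is non-increasing
in k, so the grid spans coarse to fine structure.

We use the loading matrix Lambda directly as patient scores rather than
regression-estimated factor scores: for a correlation-preserving embedding
consumed by k-means the distinction is immaterial, and Lambda requires no
second estimation step.

### Consensus ensemble subtyping

Each representation is clustered with k-means, with two safeguards:

* **Cluster count**: for k in `[cluster.k_min, cluster.k_max]` (default
  [2, 10]) we compute the explained-variance index r_k = BSS/TSS from the
  best of `cluster.n_starts` (default 20) restarts and pick the smallest k
  whose gain r_{k+1} - r_k falls below `cluster.delta` (default 0.05), i.e.
  the point where the within-cluster sum of squares stops improving. For
  structureless data the gains sit below the threshold immediately and the
  minimum k is returned; note that in very low embedding dimensions pure
  noise can produce gains above 0.05, which the ensemble absorbs.
* **Multi-start k-means**: `n_starts` seeded restarts, keeping the run with
  the smallest within-cluster SSE; labels are canonicalized by first
  patient occurrence.

Every partition becomes a binary connectivity matrix (1 where two patients
share a cluster). The ensemble is merged by weighted meta-clustering:

1. pair weight s_ij = mean connectivity over all matrices (the consensus
   matrix, entries = co-clustering frequency);
2. patient weight v_i = sum_{j != i} s_ij (patients that co-cluster
   consistently carry more weight);
3. all clusters from all partitions are pooled and compared by weighted
   Jaccard similarity sim(A, B) = sum(v over A intersect B) / sum(v over
   A union B);
4. average-linkage hierarchical clustering of the pooled clusters on
   distance 1 - sim, cut into `k_final` meta-clusters (default: the mode of
   the per-representation cluster counts, ties toward the smaller count);
   each patient joins the meta-cluster holding the plurality of its source
   clusters, ties resolved toward the larger summed similarity.

These concrete weight formulas were chosen so that every step is testable
and the procedure provably reduces to the input partition when the ensemble
is unanimous (and the consensus matrix is then binary). Average linkage was
chosen for its robustness to chaining on similarity matrices. Every
representation counts once, so an omics contributes in proportion to its
number of representations (equal under the default shared grid).

### Risk prediction

For the supervised task, training and test patients are merged per omics
before filtering and factor analysis, so both cohorts live in one embedding
(the test rows therefore influence the embedding -- not the hazard model;
a leakage-free variant, `risk.fit_fa_on_train_only = TRUE`, fits the
factor model on the training correlation matrix only and places test
patients at the least-squares position implied by their correlations with
training patients). For each representation we fit a Cox
proportional-hazards model with the elastic-net penalty (mixing weight
`risk.alpha_mix = 0.5`; the penalty choice between pure lasso and pure
ridge is not critical and 0.5 takes both effects) via `glmnet`, choosing
lambda by `risk.folds = 5`-fold cross-validated partial-likelihood
deviance with fold assignment stratified by event status so small cohorts
cannot produce event-free folds. Ties use Efron's method. A patient's risk
under one model is the relative hazard `exp(sum_i beta_i x_i)`; the final
score is the geometric mean over all representations of all omics (flat
across the pool, matching "all representations from all data types").
Representations whose cross-validation fails (for instance, a degenerate
fold on a tiny cohort) are dropped with a warning rather than failing the
run; the run fails only if every representation drops.

### Evaluation metrics

* `cox_subtype_pvalue()`: likelihood-ratio test of a Cox model with
  subtype as categorical covariate (LRT is more stable than Wald on small
  groups; Efron ties).
* `concordance_index()`: Harrell's C by exhaustive pair enumeration; a
  pair is comparable when the strictly earlier observed time belongs to an
  event (tied times never comparable, including two events at the same
  time); tied risks count 0.5.
* `adjusted_rand_index()` / `normalized_mutual_information()`: contingency
  formula under the permutation model; NMI normalized by the arithmetic
  mean of entropies, with both-constant partitions defined as 0.

## The synthetic cohort generator

`simulate_cohort()` produces the test bed the whole package is validated
on: G subtypes with largest-remainder apportionment of the requested
proportions, and per omics a Gaussian matrix (sd `noise_sd`) in which a
random informative feature subset carries subtype-specific mean shifts of
`effect_size` standard deviations. By default informative features are
split evenly across subtypes within every omics (each omics separates all
subtypes); with `signal_split = TRUE` omics d elevates its block only for
subtype ((d-1) mod G)+1, so *no single omics separates all subtypes* and
only integration recovers the full partition -- the configuration used to
demonstrate that multi-omics integration beats single-platform analysis.

Survival: event times from a proportional-hazards exponential model
(optionally Weibull via `shape`), hazard = `hazard_ratios[subtype] /
baseline_scale`; censoring times share the distribution shape with rate
calibrated by root finding so the expected censored fraction equals
`censor_rate`. Under the exponential model a group's mean event time is
`baseline_scale / hazard_ratio`, which the tests exploit as a closed-form
oracle.

What the generator deliberately does **not** emulate: count distributions
(negative binomial overdispersion), batch effects, missing-data patterns,
or feature-feature correlation beyond the planted blocks. Passing tests
therefore demonstrate correctness of the machinery on linearly separable
Gaussian structure, not performance on real TCGA-scale data.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(
  n_patients = 150, subtype_proportions = rep(1/3, 3),
  omics_specs = list(
    list(n_features = 500, n_informative = 100, data_type = "mRNA"),
    list(n_features = 500, n_informative = 100, data_type = "meth"),
    list(n_features = 500, n_informative = 100, data_type = "miRNA")),
  effect_size = 5, hazard_ratios = c(4, 2, 1), censor_rate = 0.2, seed = 1)

res <- subtype_omics(cohort$omics, build_config(list(seed = 1)))
adjusted_rand_index(res$labels, cohort$true_labels)
cox_subtype_pvalue(res$labels, cohort$survival)
```

## Numerical choices and degenerate inputs

* All randomness flows from one configuration seed through named stage
  derivation (`derive_seed(seed, stage, index)`), so identical
  configurations give byte-identical outputs and any stage can be re-run
  in isolation.
* Zero-variance features are dropped before correlation; a patient whose
  standardized profile is flat is a validation error naming the patient.
* k-means candidates are capped at the number of distinct embedding
  points; failed starts are skipped, and only if all starts fail does the
  run abort with a numerical error.
* `glmnet` requires two or more predictors; a k = 1 representation is
  padded with a zero column whose coefficient is necessarily zero.
* Validation failures and numerical failures carry distinct condition
  classes, mapped to exit codes 2 and 3 by the command-line wrapper.

## Problem sizes used in the automated checks

The test suite and the acceptance script validate on cohorts of 90--300
patients, 100--500 features per omics with 30--100 informative, three
subtypes with hazard ratios (4, 2, 1) and 20% censoring, averaging over
5--20 generator seeds per property. These sizes keep every planted
property comfortably identifiable while the full suite runs in minutes.

## Known limitations

* With purely subtype-level hazards, Harrell's C is structurally bounded
  well below 1: within-subtype pairs are risk ties (counted 0.5) and a
  between-group pair with hazards a > b is concordant with probability
  a/(a+b) under exponential survival. For three equal groups with hazard
  ratios (4, 2, 1) the ceiling -- attained by the *true* risk -- is about
  0.64-0.65, and the pipeline reaches it; reported C-indices should be
  read against that ceiling, which the acceptance script recomputes
  (`true_risk_c_index_ceiling`).
* The merged-embedding design follows the original workflow and lets test
  patients influence the embedding (not the hazard model); use
  `risk.fit_fa_on_train_only = TRUE` when strict separation matters.
* The cluster-count plateau rule can overestimate k in very low embedding
  dimensions on structureless data; the consensus step absorbs this in
  practice.
* The autoencoder filter assumes informative structure is shared across
  many features; a subtype marked by a handful of isolated features can be
  missed at aggressive `n_keep`.
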