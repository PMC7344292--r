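# consensusFA

Multi-omics cancer subtyping and patient risk prediction via consensus
factor analysis.

## What it does

Given several omics matrices (patients × features; e.g. mRNA expression,
DNA methylation, miRNA expression) measured on one patient cohort,
`consensusFA`:

1. **filters** features that play no role in differentiating patients,
   scoring each feature by the variance of its encoder weights across the
   hidden units of a non-negative autoencoder;
2. **embeds** patients by minimum-residual (MINRES) factor analysis of the
   patient–patient Pearson correlation matrix `C`: it finds the `n × k`
   loading matrix `Λ` minimising `Σ_{i≠j} (C_ij − (ΛΛᵀ)_ij)²` for a grid of
   factor counts `k`, giving an ensemble of correlation-preserving
   embeddings whose cost scales with patients, not features;
3. **subtypes** patients by clustering every embedding with multi-start
   k-means (cluster count chosen by a BSS/TSS explained-variance plateau),
   converting each partition into a binary connectivity matrix, and merging
   the ensemble by weighted meta-clustering — consensus matrix, weighted
   Jaccard cluster–cluster similarity, average-linkage hierarchical cut;
4. **predicts risk** with one penalized Cox proportional-hazards model
   (elastic net, 5-fold cross-validated λ) per embedding; a patient's score
   under one model is the relative hazard `exp(Σ βᵢxᵢ)` and the final score
   is the geometric mean over all embeddings of all omics;
5. **evaluates** with the Cox likelihood-ratio p-value across subtypes,
   Harrell's concordance index (exhaustive pair enumeration), adjusted Rand
   index and normalized mutual information.

A synthetic-cohort generator (`simulate_cohort()`) plants subtype structure
across omics and survival times whose hazard depends on subtype, so the
whole pipeline is testable end to end without any external download.

## Worked example

```r
library(consensusFA)

cohort <- simulate_cohort(
  n_patients = 150, subtype_proportions = rep(1/3, 3),
  omics_specs = list(
    list(n_features = 500, n_informative = 100, data_type = "mRNA"),
    list(n_features = 500, n_informative = 100, data_type = "meth"),
    list(n_features = 500, n_informative = 100, data_type = "miRNA")),
  effect_size = 5, hazard_ratios = c(4, 2, 1), censor_rate = 0.2, seed = 1)

res <- subtype_omics(cohort$omics, build_config(list(seed = 1)))
res
#> Consensus subtyping: 150 patients, 3 subtypes (from 27 partitions)
#> subtype
#>  1  2  3
#> 50 50 50

adjusted_rand_index(res$labels, cohort$true_labels)
#> [1] 1

cox_subtype_pvalue(res$labels, cohort$survival)
#> [1] 1.386966e-09
```

The discovered subtypes reproduce the planted partition exactly (ARI = 1),
and a Cox model on the discovered labels confirms the planted survival
separation (hazard ratios 4 : 2 : 1 across the three subtypes).

Risk prediction on a train/test split:

```r
rr <- predict_risk(train_omics, train_survival, test_omics,
                   build_config(list(seed = 1)))
concordance_index(rr$risk, test_survival)
```

A command-line wrapper with `simulate`, `subtype`, `predict-risk` and
`evaluate` subcommands is installed under `exec/consensusfa`.

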