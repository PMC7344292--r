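# Shared fixtures and independent oracles, all built in code at test time.

# Standard three-omics cohort used across pipeline tests.
make_cohort <- function(seed, n = 150, n_features = 500, n_informative = 100,
                        effect_size = 5, signal_split = FALSE,
                        hazard_ratios = c(4, 2, 1), censor_rate = 0.2,
                        n_omics = 3) {
  types <- c("mRNA", "meth", "miRNA")[seq_len(n_omics)]
  simulate_cohort(
    n, rep(1 / 3, 3),
    lapply(types, function(t) list(n_features = n_features,
                                   n_informative = n_informative,
                                   data_type = t)),
    effect_size = effect_size, signal_split = signal_split,
    hazard_ratios = hazard_ratios, baseline_scale = 1000,
    censor_rate = censor_rate, seed = seed)
}

subset_omics <- function(m, rows) {
  out <- m[rows, , drop = FALSE]
  attr(out, "data_type") <- attr(m, "data_type")
  out
}

# Deterministic 50/50 split of a cohort into train/test pieces.
split_cohort <- function(cohort, seed) {
  n <- length(cohort$true_labels)
  ids <- names(cohort$true_labels)
  set.seed(derive_seed(seed, "split"))
  tr <- sort(sample.int(n, n %/% 2))
  te <- setdiff(seq_len(n), tr)
  list(
    train_omics = lapply(cohort$omics, subset_omics, rows = tr),
    test_omics = lapply(cohort$omics, subset_omics, rows = te),
    train_surv = cohort$survival[cohort$survival$patient_id %in% ids[tr], ],
    test_surv = cohort$survival[cohort$survival$patient_id %in% ids[te], ],
    train_ids = ids[tr], test_ids = ids[te])
}

# Train on one half, score the other, return the test C-index.
run_risk_ci <- function(seed, cohort = NULL, omics_idx = NULL,
                        permute_train_surv = FALSE, config_overrides = list()) {
  if (is.null(cohort)) cohort <- make_cohort(seed, n = 200)
  sp <- split_cohort(cohort, seed)
  train_om <- sp$train_omics
  test_om <- sp$test_omics
  if (!is.null(omics_idx)) {
    train_om <- train_om[omics_idx]
    test_om <- test_om[omics_idx]
  }
  surv_tr <- sp$train_surv
  if (permute_train_surv) {
    set.seed(derive_seed(seed, "permute"))
    perm <- sample.int(nrow(surv_tr))
    surv_tr[, c("time", "event")] <- surv_tr[perm, c("time", "event")]
  }
  cfg <- build_config(utils::modifyList(list(seed = seed), config_overrides))
  rr <- predict_risk(train_om, surv_tr, test_om, cfg)
  as.numeric(concordance_index(rr$risk, sp$test_surv))
}

# Independent concordance oracle: explicit double loop over all pairs.
concordance_oracle <- function(risk, time, event) {
  n <- length(risk)
  num <- 0
  comp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        comp <- comp + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (comp == 0) return(NA_real_)
  num / comp
}

# Independent ARI oracle: direct contingency-table formula.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  tot <- ch2(sum(tab))
  (sij - sa * sb / tot) / ((sa + sb) / 2 - sa * sb / tot)
}

# Minimal partition object for meta-clustering tests.
make_partition <- function(labels, ids = NULL) {
  ids <- ids %||% paste0("P", seq_along(labels))
  structure(list(labels = stats::setNames(as.integer(labels), ids),
                 k = length(unique(labels)), sse = 0, source = list()),
            class = "partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
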