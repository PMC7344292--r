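# Supervised risk scoring. Each factor representation of each omics yields
# one penalized Cox proportional-hazards model (elastic net, lambda chosen
# by cross-validated partial-likelihood deviance); a patient's risk under
# one model is the relative hazard exp(sum(beta * x)), and the final risk
# is the geometric mean over all representations of all data types.

#' Fit a Cox elastic-net model on one factor representation
#'
#' Fits the penalized Cox partial likelihood (Efron tie handling, as
#' implemented in \pkg{glmnet}) with the elastic-net penalty
#' `alpha_mix * L1 + (1 - alpha_mix)/2 * L2`, choosing `lambda` by
#' `folds`-fold cross-validated partial-likelihood deviance over
#' \pkg{glmnet}'s log-spaced grid. Fold assignment is stratified by event
#' status (so no fold is left without events on small cohorts) and seeded,
#' making the fit deterministic.
#'
#' @param rep_train `"factor_representation"` (or score matrix) of the
#'   training patients.
#' @param surv survival `data.frame` with `patient_id`, `time` (> 0) and
#'   `event` (0/1) columns, covering the training patients.
#' @param folds number of cross-validation folds.
#' @param alpha_mix elastic-net mixing weight in `[0, 1]` (1 = lasso,
#'   0 = ridge).
#' @param seed integer seed for fold assignment.
#' @return A list of class `"cox_model"`: `beta` (one coefficient per
#'   factor), `k`, `penalty` (`alpha_mix`, `lambda`), `cv_meta`
#'   (`folds`, `seed`).
#' @export
fit_cox_elastic_net <- function(rep_train, surv, folds = 5L,
                                alpha_mix = 0.5, seed = 1) {
  x <- rep_scores(rep_train)
  surv <- validate_survival(surv)
  if (alpha_mix < 0 || alpha_mix > 1) cfa_stop("`alpha_mix` must lie in [0, 1]")
  ord <- match(rownames(x), surv$patient_id)
  if (anyNA(ord)) {
    cfa_stop(sprintf("no survival record for patient(s): %s",
                     paste(utils::head(rownames(x)[is.na(ord)], 5L),
                           collapse = ", ")))
  }
  surv <- surv[ord, ]
  n_events <- sum(surv$event)
  if (n_events < 2L) cfa_stop("at least 2 events are required to fit a model")
  if (n_events < folds) {
    cfa_stop(sprintf("need at least `folds` = %d events, got %d",
                     folds, n_events))
  }

  foldid <- stratified_folds(surv$event, folds, derive_seed(seed, "cvfolds"))
  y <- survival::Surv(surv$time, surv$event)
  if (all(apply(x, 2L, stats::sd) == 0)) {
    # no usable predictors: the penalty forces the null model
    return(structure(list(beta = rep(0, ncol(x)), k = ncol(x),
                          penalty = list(alpha_mix = alpha_mix,
                                         lambda = Inf),
                          cv_meta = list(folds = as.integer(folds),
                                         seed = seed)),
                     class = "cox_model"))
  }
  # glmnet needs >= 2 columns; pad a k = 1 representation with a zero column
  # whose coefficient is necessarily zero, and drop it afterwards
  padded <- ncol(x) == 1L
  xx <- if (padded) cbind(x, 0) else x
  cv <- glmnet::cv.glmnet(xx, y, family = "cox", alpha = alpha_mix,
                          foldid = foldid, standardize = TRUE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  if (padded) beta <- beta[1L]
  structure(list(beta = beta, k = ncol(x),
                 penalty = list(alpha_mix = alpha_mix,
                                lambda = cv$lambda.min),
                 cv_meta = list(folds = as.integer(folds), seed = seed)),
            class = "cox_model")
}

# Event-stratified fold assignment: permute within each event stratum and
# deal folds cyclically.
stratified_folds <- function(event, folds, seed) {
  set.seed(seed)
  foldid <- integer(length(event))
  for (e in unique(event)) {
    idx <- which(event == e)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

#' Relative-hazard risk scores under a fitted Cox model
#'
#' Computes `exp(sum_i beta_i * x_i)` per patient: the relative hazard
#' `h(t) / h0(t)` under proportional hazards. Strictly positive and
#' monotone in the linear predictor.
#'
#' @param model a `"cox_model"`.
#' @param rep `"factor_representation"` (or score matrix) with the model's
#'   dimension.
#' @return Named positive numeric vector.
#' @export
#' @examples
#' m <- structure(list(beta = log(2), k = 1L), class = "cox_model")
#' risk_score(m, matrix(1, 1, 1))  # 2
risk_score <- function(model, rep) {
  x <- rep_scores(rep)
  if (ncol(x) != model$k) {
    cfa_stop(sprintf("representation has %d factors but the model expects %d",
                     ncol(x), model$k))
  }
  drop(exp(x %*% model$beta))
}

#' Geometric-mean aggregation of per-representation risks
#'
#' @param per_rep positive numeric matrix, patients x representations.
#' @return Per-patient geometric mean, `exp(rowMeans(log(per_rep)))`;
#'   invariant to column order and bounded by each row's min and max.
#' @export
#' @examples
#' aggregate_risk(cbind(4, 16))  # 8
aggregate_risk <- function(per_rep) {
  per_rep <- as.matrix(per_rep)
  if (ncol(per_rep) < 1L) cfa_stop("at least one representation required")
  if (anyNA(per_rep) || any(per_rep <= 0)) {
    cfa_stop("risk scores must be strictly positive")
  }
  out <- exp(rowMeans(log(per_rep)))
  names(out) <- rownames(per_rep)
  out
}

#' Predict risk scores for new patients from multi-omics data
#'
#' Supervised end-to-end pipeline. For each omics, training and test
#' patients are merged, features filtered, and factor representations
#' generated on the merged matrix (so train and test live in one embedding;
#' set `risk.fit_fa_on_train_only = TRUE` for a leakage-free variant that
#' fits the embedding on training patients only and projects test patients
#' into it by least squares on their correlations with the training set).
#' For each representation a Cox elastic net is fitted on the training rows
#' only and the test rows are scored; representations whose
#' cross-validation fails (e.g. a degenerate fold) are dropped with a
#' warning. The final per-patient risk is the geometric mean over all
#' retained representations of all omics.
#'
#' @param train_omics,test_omics lists of omics matrices with matching
#'   data types and feature spaces; train and test patient sets must be
#'   disjoint.
#' @param train_surv survival table covering the training patients.
#' @param config configuration from [build_config()].
#' @return A list of class `"risk_result"`: `patient_ids`, `risk` (named
#'   positive vector, geometric mean), `per_representation_risks`
#'   (patients x representations matrix), `models` (list of
#'   `"cox_model"`), `dropped` (indices of failed representations).
#' @export
predict_risk <- function(train_omics, train_surv, test_omics,
                         config = build_config()) {
  train_omics <- align_omics(train_omics)
  test_omics <- align_omics(test_omics)
  if (length(train_omics) != length(test_omics)) {
    cfa_stop("train and test must provide the same omics data types")
  }
  train_surv <- validate_survival(train_surv)
  train_ids <- rownames(train_omics[[1L]])
  test_ids <- rownames(test_omics[[1L]])
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap)) {
    cfa_stop(sprintf("train and test patient sets overlap: %s",
                     paste(utils::head(overlap, 5L), collapse = ", ")))
  }
  seed <- config$seed
  ks <- config$fa$factor_counts

  per_rep <- list()
  models <- list()
  dropped <- integer(0)
  rep_counter <- 0L
  for (d in seq_along(train_omics)) {
    tr <- train_omics[[d]]
    te <- test_omics[[d]]
    missing_feat <- setdiff(colnames(tr), colnames(te))
    extra_feat <- setdiff(colnames(te), colnames(tr))
    if (length(missing_feat) || length(extra_feat)) {
      cfa_stop(sprintf(
        "omics %d: feature spaces differ between train and test (%s)", d,
        paste(utils::head(c(missing_feat, extra_feat), 5L), collapse = ", ")))
    }
    te <- te[, colnames(tr), drop = FALSE]
    merged <- rbind(tr, te)
    attr(merged, "data_type") <- omics_data_type(tr)
    merged <- filter_omics(merged, config, derive_seed(seed, "filter", d))
    ks_d <- unique(pmin(ks, nrow(merged) - 1L))

    if (isTRUE(config$risk$fit_fa_on_train_only)) {
      reps <- project_representations(merged[train_ids, , drop = FALSE],
                                      merged[test_ids, , drop = FALSE],
                                      ks_d, config)
    } else {
      reps <- generate_representations(merged, ks_d,
                                       max_iter = config$fa$max_iter,
                                       tol = config$fa$tol)
    }

    for (r in seq_along(reps)) {
      rep_counter <- rep_counter + 1L
      scores <- rep_scores(reps[[r]])
      fit <- tryCatch(
        fit_cox_elastic_net(scores[train_ids, , drop = FALSE], train_surv,
                            folds = config$risk$folds,
                            alpha_mix = config$risk$alpha_mix,
                            seed = derive_seed(seed, "cox", d, r)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("representation %d (omics %d, k = %d) dropped: %s",
                        rep_counter, d, ks_d[r], conditionMessage(fit)),
                call. = FALSE)
        dropped <- c(dropped, rep_counter)
        next
      }
      per_rep[[length(per_rep) + 1L]] <-
        risk_score(fit, scores[test_ids, , drop = FALSE])
      models[[length(models) + 1L]] <- fit
    }
  }
  if (length(per_rep) == 0L) {
    cfa_numerical_stop("every representation failed cross-validation")
  }
  per_rep <- do.call(cbind, per_rep)
  rownames(per_rep) <- test_ids
  colnames(per_rep) <- paste0("rep", seq_len(ncol(per_rep)))
  structure(list(patient_ids = test_ids,
                 risk = aggregate_risk(per_rep),
                 per_representation_risks = per_rep,
                 models = models,
                 dropped = dropped),
            class = "risk_result")
}

# Leakage-free embedding: fit the factor model on the training correlation
# matrix only, then place each test patient at the least-squares position
# implied by its correlations with the training patients.
project_representations <- function(train_m, test_m, factor_counts, config) {
  cc_train <- patient_correlation(train_m)
  xs_train <- standardize_columns(train_m)
  # test profiles standardized with the merged matrix's own feature scale
  xs_test <- standardize_columns(test_m)
  cross <- stats::cor(t(xs_test), t(xs_train))
  lapply(factor_counts, function(k) {
    fit <- fit_factor_model(cc_train, k, max_iter = config$fa$max_iter,
                            tol = config$fa$tol)
    lam <- fit$scores
    proj <- cross %*% lam %*% solve(crossprod(lam) +
                                      diag(1e-8, ncol(lam)))
    scores <- rbind(lam, proj)
    rownames(scores) <- c(rownames(train_m), rownames(test_m))
    fit$scores <- scores
    fit
  })
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Risk prediction: %d patients, %d representations (%d dropped)\n",
              length(x$risk), ncol(x$per_representation_risks),
              length(x$dropped)))
  cat(sprintf("  risk range: %.3g .. %.3g (geometric mean of relative hazards)\n",
              min(x$risk), max(x$risk)))
  invisible(x)
}
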