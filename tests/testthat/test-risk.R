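# Cox elastic-net fitting, risk scoring, geometric-mean aggregation, and the
# end-to-end supervised pipeline.

make_surv_from_lp <- function(lp, seed, censor_rate = 0) {
  # exponential survival driven by a known linear predictor
  set.seed(seed)
  n <- length(lp)
  time <- stats::rexp(n) / exp(lp)
  event <- rep(1L, n)
  if (censor_rate > 0) {
    cens <- stats::rexp(n) / (censor_rate / (1 - censor_rate) * mean(exp(lp)))
    event <- as.integer(time <= cens)
    time <- pmin(time, cens)
  }
  data.frame(patient_id = names(lp) %||% paste0("P", seq_len(n)),
             time = time, event = event, stringsAsFactors = FALSE)
}

test_that("an all-zero predictor matrix yields the null model", {
  set.seed(40)
  x <- matrix(0, 60, 3, dimnames = list(paste0("P", 1:60), NULL))
  lp <- stats::setNames(rep(0, 60), rownames(x))
  surv <- make_surv_from_lp(lp, seed = 40)
  fit <- fit_cox_elastic_net(x, surv, seed = 1)
  expect_equal(fit$beta, rep(0, 3))
  expect_equal(unname(risk_score(fit, x)), rep(1, 60))
})

test_that("a hazard-driving factor earns the dominant coefficient", {
  set.seed(41)
  n <- 400
  x <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(paste0("P", 1:n), NULL))
  lp <- stats::setNames(1.0 * x[, 2], rownames(x))
  surv <- make_surv_from_lp(lp, seed = 41)
  fit <- fit_cox_elastic_net(x, surv, seed = 2)
  expect_gt(fit$beta[2], 0)
  expect_true(all(abs(fit$beta[-2]) <= abs(fit$beta[2])))
  # determinism of the cross-validated fit
  fit2 <- fit_cox_elastic_net(x, surv, seed = 2)
  expect_identical(fit$beta, fit2$beta)
})

test_that("fitting validates events, folds and alignment", {
  set.seed(42)
  x <- matrix(stats::rnorm(40), 20, 2, dimnames = list(paste0("P", 1:20), NULL))
  surv <- data.frame(patient_id = paste0("P", 1:20),
                     time = stats::rexp(20) + 0.1, event = 0L)
  surv$event[1] <- 1L
  expect_error(fit_cox_elastic_net(x, surv, seed = 1), "2 events")
  surv$event[2:4] <- 1L
  expect_error(fit_cox_elastic_net(x, surv, folds = 5, seed = 1), "folds")
  surv2 <- surv; surv2$patient_id[1] <- "STRANGER"
  expect_error(fit_cox_elastic_net(x, surv2, seed = 1), "no survival record")
})

test_that("risk scores are the exponential of the linear predictor", {
  m <- structure(list(beta = log(2), k = 1L), class = "cox_model")
  expect_equal(unname(risk_score(m, matrix(1, 1, 1))), 2)
  m0 <- structure(list(beta = rep(0, 4), k = 4L), class = "cox_model")
  expect_equal(unname(risk_score(m0, matrix(rnorm(20), 5, 4))), rep(1, 5))
  set.seed(43)
  scores <- matrix(stats::rnorm(100), 20, 5)
  beta <- stats::rnorm(5)
  mm <- structure(list(beta = beta, k = 5L), class = "cox_model")
  byhand <- vapply(1:20, function(i) exp(sum(beta * scores[i, ])), numeric(1))
  expect_equal(unname(risk_score(mm, scores)), byhand, tolerance = 1e-12)
  expect_error(risk_score(mm, scores[, 1:3]), "expects")
  # positive rescaling of beta preserves the patient ranking
  m2 <- structure(list(beta = 3.7 * beta, k = 5L), class = "cox_model")
  expect_identical(order(risk_score(mm, scores)), order(risk_score(m2, scores)))
})

test_that("geometric-mean aggregation honours its invariants", {
  expect_equal(unname(aggregate_risk(cbind(4, 16))), 8)
  expect_equal(unname(aggregate_risk(matrix(c(3, 3, 3), 1))), 3)
  expect_equal(unname(aggregate_risk(matrix(c(2, 5), 2, 1))), c(2, 5))
  set.seed(44)
  m <- matrix(stats::rexp(60) + 0.01, 10, 6)
  agg <- aggregate_risk(m)
  expect_equal(agg, aggregate_risk(m[, sample(6)]))
  expect_true(all(agg >= apply(m, 1, min) - 1e-12))
  expect_true(all(agg <= apply(m, 1, max) + 1e-12))
  expect_error(aggregate_risk(cbind(1, -1)), "positive")
})

test_that("predicted risk tracks true risk under a planted hazard", {
  set.seed(45)
  n <- 400
  scores <- matrix(stats::rnorm(n * 5), n, 5,
                   dimnames = list(paste0("P", 1:n), NULL))
  beta <- c(0.8, 0, -0.5, 0, 0.3)
  lp <- stats::setNames(drop(scores %*% beta), rownames(scores))
  surv <- make_surv_from_lp(lp, seed = 45, censor_rate = 0.2)
  fit <- fit_cox_elastic_net(scores, surv, seed = 3)
  predicted <- risk_score(fit, scores)
  expect_gte(stats::cor(predicted, exp(lp), method = "spearman"), 0.6)
})

test_that("the supervised pipeline validates patients and features", {
  cohort <- make_cohort(46, n = 60, n_features = 120, n_informative = 40,
                        n_omics = 2)
  sp <- split_cohort(cohort, 46)
  cfg <- build_config(list(seed = 46, fa = list(factor_counts = 2:3)))
  expect_error(predict_risk(sp$train_omics, sp$train_surv, sp$train_omics, cfg),
               "overlap")
  broken <- sp$test_omics
  colnames(broken[[1]])[1] <- "ALIEN_FEATURE"
  expect_error(predict_risk(sp$train_omics, sp$train_surv, broken, cfg),
               "feature spaces")
  expect_error(predict_risk(sp$train_omics[1], sp$train_surv, sp$test_omics,
                            cfg), "same omics")
})

test_that("risk prediction recovers planted survival structure end to end", {
  ci <- run_risk_ci(47, config_overrides = list(fa = list(factor_counts = 2:6)))
  expect_gt(ci, 0.58)
  # determinism contract for the whole pipeline
  cohort <- make_cohort(48, n = 80, n_features = 150, n_informative = 50,
                        n_omics = 2)
  sp <- split_cohort(cohort, 48)
  cfg <- build_config(list(seed = 48, fa = list(factor_counts = 2:4)))
  r1 <- predict_risk(sp$train_omics, sp$train_surv, sp$test_omics, cfg)
  r2 <- predict_risk(sp$train_omics, sp$train_surv, sp$test_omics, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$risk > 0))
  expect_equal(r1$risk, aggregate_risk(r1$per_representation_risks))
})

test_that("the leakage-free embedding variant remains predictive", {
  cohort <- make_cohort(49, n = 100, n_features = 200, n_informative = 60,
                        n_omics = 2)
  sp <- split_cohort(cohort, 49)
  cfg <- build_config(list(seed = 49, fa = list(factor_counts = 2:4),
                           risk = list(fit_fa_on_train_only = TRUE)))
  rr <- predict_risk(sp$train_omics, sp$train_surv, sp$test_omics, cfg)
  ci <- as.numeric(concordance_index(rr$risk, sp$test_surv))
  expect_gt(ci, 0.55)
})

test_that("a training set with too few events fails loudly", {
  cohort <- make_cohort(50, n = 60, n_features = 100, n_informative = 30,
                        n_omics = 1, censor_rate = 0)
  sp <- split_cohort(cohort, 50)
  sp$train_surv$event <- 0L
  sp$train_surv$event[1:3] <- 1L   # fewer events than folds: every rep drops
  cfg <- build_config(list(seed = 50, fa = list(factor_counts = 2:3)))
  expect_error(
    suppressWarnings(predict_risk(sp$train_omics, sp$train_surv,
                                  sp$test_omics, cfg)),
    "every representation failed")
})
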