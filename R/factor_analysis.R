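# Patient-mode factor analysis. Instead of modelling the feature-feature
# correlation matrix (p x p, intractable for tens of thousands of features),
# the patient-patient Pearson correlation matrix (n x n) is approximated by
# Lambda %*% t(Lambda) with communalities free on the diagonal. The loading
# matrix Lambda (n patients x k factors) is the low-dimensional embedding:
# it preserves pairwise patient correlations rather than Euclidean
# distances, which is what the downstream clustering consumes. Fitting is
# minimum-residual (MINRES): least squares on the off-diagonal entries,
# initialised from the k leading eigencomponents.

#' Patient-patient Pearson correlation matrix
#'
#' Standardizes every feature to mean 0 / sd 1 across patients (so that
#' high-magnitude platforms cannot dominate the patient profiles), then
#' computes the Pearson correlation between every pair of patient profiles.
#' Zero-variance features are dropped with a message before standardization.
#'
#' @param m omics matrix (patients x features) with at least 2
#'   non-constant features.
#' @return Symmetric `n x n` correlation matrix with unit diagonal and
#'   patient IDs as dimnames.
#' @export
patient_correlation <- function(m) {
  m <- as_omics(m)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("patient_correlation: dropping %d zero-variance feature(s)",
                    sum(sds == 0)))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2L) {
    cfa_stop("at least 2 features with nonzero variance are required")
  }
  xs <- standardize_columns(m)
  profile_sd <- apply(xs, 1L, stats::sd)
  if (any(profile_sd == 0)) {
    cfa_stop(sprintf("patient(s) with zero-variance profile: %s",
                     paste(rownames(m)[profile_sd == 0], collapse = ", ")))
  }
  cc <- stats::cor(t(xs))
  diag(cc) <- 1
  dimnames(cc) <- list(rownames(m), rownames(m))
  cc
}

#' Fit a k-factor minimum-residual model to a correlation matrix
#'
#' Finds the `n x k` loading matrix `Lambda` minimizing the sum of squared
#' off-diagonal residuals between the correlation matrix and
#' `Lambda %*% t(Lambda)` (the diagonal -- the communalities -- is excluded
#' from the objective). Optimization starts from the `k` leading
#' eigencomponents (`v_j * sqrt(lambda_j)`, each eigenvector's
#' largest-magnitude element made positive) and proceeds by L-BFGS-B with
#' an analytic gradient; the fit is fully deterministic.
#'
#' @param c_mat symmetric correlation matrix (unit diagonal).
#' @param k number of factors, `1 <= k <= n - 1`.
#' @param max_iter iteration cap.
#' @param tol stop when the objective improves by less than `tol`.
#' @return A list of class `"factor_representation"`: `scores` (the loading
#'   matrix, patients x k, rownames preserved), `k`, `source`
#'   (`data_type`, `k`), `fit_residual` (root-mean-square off-diagonal
#'   residual), `converged`, `iterations`.
#' @export
#' @examples
#' cc <- diag(5)
#' fit <- fit_factor_model(cc, 2)
#' fit$fit_residual  # 0: an identity matrix has no off-diagonal structure
fit_factor_model <- function(c_mat, k, max_iter = 1000L, tol = 1e-6) {
  if (!is.matrix(c_mat) || nrow(c_mat) != ncol(c_mat)) {
    cfa_stop("`c_mat` must be a square correlation matrix")
  }
  n <- nrow(c_mat)
  if (max(abs(c_mat - t(c_mat))) > 1e-8) {
    cfa_stop("`c_mat` must be symmetric")
  }
  if (length(k) != 1L || !is.finite(k) || k < 1L || k > n - 1L) {
    cfa_stop(sprintf("`k` must lie in [1, %d]", n - 1L))
  }
  k <- as.integer(k)

  lambda0 <- eigen_init(c_mat, k)
  off <- 1 - diag(n)

  objective <- function(par) {
    l <- matrix(par, n, k)
    e <- (c_mat - tcrossprod(l)) * off
    sum(e * e)
  }
  gradient <- function(par) {
    l <- matrix(par, n, k)
    e <- (c_mat - tcrossprod(l)) * off
    as.vector(-4 * (e %*% l))
  }

  f0 <- objective(as.vector(lambda0))
  if (!is.finite(f0)) cfa_numerical_stop("non-finite objective at initialization")
  opt <- stats::optim(as.vector(lambda0), objective, gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = as.integer(max_iter),
                                     factr = tol / .Machine$double.eps))
  if (!is.finite(opt$value)) {
    cfa_numerical_stop(sprintf(
      "factor fit diverged (k = %d, n = %d): non-finite objective", k, n))
  }
  # L-BFGS-B line search is monotone, but keep the guarantee explicit
  if (opt$value <= f0) {
    lambda <- matrix(opt$par, n, k)
    fval <- opt$value
  } else {
    lambda <- lambda0
    fval <- f0
  }
  rownames(lambda) <- rownames(c_mat)
  colnames(lambda) <- paste0("factor", seq_len(k))

  structure(list(
    scores = lambda,
    k = k,
    source = list(data_type = attr(c_mat, "data_type") %||% "omics", k = k),
    fit_residual = sqrt(fval / (n * (n - 1))),
    converged = opt$convergence == 0L,
    iterations = opt$counts[["function"]]),
    class = "factor_representation")
}

# Leading eigencomponents of c, scaled by sqrt of (non-negative) eigenvalues,
# with a fixed sign convention so the initialization is reproducible.
eigen_init <- function(c_mat, k) {
  es <- eigen(c_mat, symmetric = TRUE)
  v <- es$vectors[, seq_len(k), drop = FALSE]
  lam <- pmax(es$values[seq_len(k)], 0)
  for (j in seq_len(k)) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  sweep(v, 2L, sqrt(lam), "*")
}

#' Generate factor representations over a grid of factor counts
#'
#' Computes the patient correlation matrix once and fits one
#' minimum-residual factor model per requested factor count. Using several
#' factor counts yields an ensemble of embeddings that is robust to any
#' single count misrepresenting the data.
#'
#' @param m omics matrix.
#' @param factor_counts integer vector of factor numbers, each within
#'   `[1, n_patients - 1]`.
#' @inheritParams fit_factor_model
#' @return List of `"factor_representation"` objects in `factor_counts`
#'   order.
#' @export
generate_representations <- function(m, factor_counts = 2:10,
                                     max_iter = 1000L, tol = 1e-6) {
  m <- as_omics(m)
  if (length(factor_counts) == 0L) cfa_stop("`factor_counts` must be non-empty")
  n <- nrow(m)
  if (any(factor_counts < 1L) || any(factor_counts > n - 1L)) {
    cfa_stop(sprintf("factor counts must lie in [1, %d]", n - 1L))
  }
  cc <- patient_correlation(m)
  attr(cc, "data_type") <- omics_data_type(m)
  lapply(factor_counts, function(k) {
    tryCatch(fit_factor_model(cc, k, max_iter = max_iter, tol = tol),
             error = function(e) {
               stop(errorCondition(
                 sprintf("factor fit failed at k = %d: %s", k, conditionMessage(e)),
                 class = class(e)))
             })
  })
}

#' @export
print.factor_representation <- function(x, ...) {
  cat(sprintf("Factor representation: %d patients x %d factors (%s), RMS residual %.3g\n",
              nrow(x$scores), x$k, x$source$data_type, x$fit_residual))
  invisible(x)
}
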