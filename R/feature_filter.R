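# Noise-robust feature filtering. Features that play no role in
# differentiating patients are identified by training a one-hidden-layer
# autoencoder whose encoder weights are constrained non-negative: features
# that carry shared structure acquire large weights in some hidden units and
# small weights in others, so the variance of a feature's encoder weights
# across hidden units ranks its contribution. A plain variance ranking is
# available as a deterministic alternative ranking method.

#' Train an encoder-weight variability profile
#'
#' Fits a non-negative linear autoencoder (encoder `p -> hidden_dim` with
#' weights clamped to be non-negative after every optimizer step, linear
#' decoder `hidden_dim -> p`) to the per-feature standardized matrix by
#' minimizing L2-regularized mean squared reconstruction error with
#' mini-batch stochastic gradient descent plus momentum. The returned
#' variability score of feature `j` is the variance of its encoder weights
#' across hidden units; constant features receive score 0 and features
#' carrying shared patient structure score high.
#'
#' The L2 penalty is what makes the heuristic selective: with far fewer
#' hidden units than features, a unit spent reconstructing a lone noise
#' feature buys a loss reduction of one feature's variance, whereas a unit
#' aligned with structure shared by many correlated features buys many
#' times that, so under weight decay only the shared-structure pathways
#' stay profitable and pure-noise features keep small, near-uniform
#' weights. Plain (non-adaptive) gradient descent preserves this
#' gradient-magnitude ordering (adaptive per-parameter scaling would
#' equalize it). The encoder weight matrix is initialised at a small
#' positive constant so that weight variance is exactly zero until training
#' moves a feature's weights; symmetry across hidden units is broken by the
#' random Gaussian decoder initialisation.
#'
#' @param m omics matrix (patients x features), at least 10 patients.
#' @param hidden_dim bottleneck width (< number of features).
#' @param epochs training epochs.
#' @param seed integer seed (initialisation and batch shuffling).
#' @param batch_size mini-batch size.
#' @param learning_rate gradient-descent step size.
#' @param momentum heavy-ball momentum coefficient.
#' @param weight_decay L2 shrinkage strength, applied in decoupled form:
#'   each step multiplies the weight matrices by
#'   `1 - 2 * learning_rate * weight_decay` before the momentum update (so
#'   momentum cannot amplify the penalty into oscillations). The logged
#'   loss is `MSE + weight_decay / p * (||W_enc||_F^2 + ||W_dec||_F^2)`.
#' @return A list of class `"weight_profile"`: `variability` (named
#'   non-negative vector, one entry per feature), `hidden_dim`, and
#'   `training_meta` (`epochs`, `seed`, `final_loss` and per-epoch
#'   `loss_trace` of the penalized objective, `final_mse`).
#' @seealso [select_features()], [filter_matrix()]
#' @export
train_weight_profile <- function(m, hidden_dim = 50L, epochs = 50L, seed = 1,
                                 batch_size = 32L, learning_rate = 0.003,
                                 momentum = 0.9, weight_decay = 80) {
  m <- as_omics(m)
  n <- nrow(m)
  p <- ncol(m)
  if (n < 10L) cfa_stop("autoencoder training requires at least 10 patients")
  if (hidden_dim >= p) {
    cfa_stop("`hidden_dim` must be smaller than the number of features")
  }
  if (hidden_dim < 1L || epochs < 1L) {
    cfa_stop("`hidden_dim` and `epochs` must be positive")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    cfa_stop("input matrix contains non-finite values")
  }

  x <- standardize_columns(m)
  set.seed(derive_seed(seed, "autoencoder"))
  w_enc <- matrix(0.01, p, hidden_dim)           # constant start: zero variance
  w_dec <- matrix(stats::rnorm(hidden_dim * p, sd = sqrt(1 / hidden_dim)),
                  hidden_dim, p)
  b_dec <- numeric(p)

  # heavy-ball momentum state; loss is averaged over samples and features
  vel <- list(we = w_enc * 0, wd = w_dec * 0, bd = b_dec * 0)
  batch_size <- min(batch_size, n)
  loss_trace <- numeric(epochs)

  for (epoch in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      rows <- idx[start:min(start + batch_size - 1L, n)]
      xb <- x[rows, , drop = FALSE]
      nb <- nrow(xb)
      h <- xb %*% w_enc
      xhat <- h %*% w_dec
      xhat <- sweep(xhat, 2L, b_dec, "+")
      err <- xhat - xb
      g_out <- 2 * err / (nb * p)                  # d(mean sq error)/d(xhat)
      g_wd <- crossprod(h, g_out)
      g_bd <- colSums(g_out)
      g_h <- g_out %*% t(w_dec)
      g_we <- crossprod(xb, g_h)

      # gradients scale with 1/p; rescale so the step size is O(learning_rate).
      # Weight decay is decoupled (applied outside the momentum buffer) so the
      # strong L2 pull cannot be amplified into oscillations by momentum.
      shrink <- 1 - 2 * learning_rate * weight_decay
      vel$we <- momentum * vel$we - learning_rate * p * g_we
      w_enc <- pmax(shrink * w_enc + vel$we, 0)    # non-negativity constraint
      vel$wd <- momentum * vel$wd - learning_rate * p * g_wd
      w_dec <- shrink * w_dec + vel$wd
      vel$bd <- momentum * vel$bd - learning_rate * p * g_bd
      b_dec <- b_dec + vel$bd
    }
    xhat <- sweep((x %*% w_enc) %*% w_dec, 2L, b_dec, "+")
    loss_trace[epoch] <- mean((x - xhat)^2) +
      weight_decay / p * (sum(w_enc^2) + sum(w_dec^2))
  }

  variability <- apply(w_enc, 1L, stats::var)
  names(variability) <- colnames(m)
  structure(list(
    variability = variability,
    hidden_dim = as.integer(hidden_dim),
    training_meta = list(epochs = as.integer(epochs), seed = seed,
                         final_loss = loss_trace[epochs],
                         loss_trace = loss_trace,
                         final_mse = mean((x - xhat)^2),
                         method = "autoencoder")),
    class = "weight_profile")
}

#' Rank features by raw variance
#'
#' Deterministic alternative to [train_weight_profile()]: scores each
#' feature by its variance across patients on the original (unstandardized)
#' scale. Useful as a fast, optimizer-free ranking; selected via
#' `filter.method = "variance"` in the configuration.
#'
#' @inheritParams train_weight_profile
#' @return A `"weight_profile"` whose `variability` holds feature variances.
#' @export
variance_profile <- function(m) {
  m <- as_omics(m)
  variability <- apply(m, 2L, stats::var)
  names(variability) <- colnames(m)
  structure(list(
    variability = variability,
    hidden_dim = NA_integer_,
    training_meta = list(method = "variance")),
    class = "weight_profile")
}

#' Select the most variable features
#'
#' Returns the (1-based) column positions of the `n_keep` largest
#' variability scores, in ascending index order. Ties are broken in favour
#' of the lower index; requesting at least as many features as exist
#' returns every index.
#'
#' @param w a `"weight_profile"` from [train_weight_profile()] or
#'   [variance_profile()].
#' @param n_keep number of features to retain (>= 1).
#' @return Sorted integer vector of column positions.
#' @export
#' @examples
#' w <- structure(list(variability = c(3, 1, 2)), class = "weight_profile")
#' select_features(w, 2)  # 1 and 3
select_features <- function(w, n_keep) {
  if (!inherits(w, "weight_profile")) {
    cfa_stop("`w` must be a weight_profile")
  }
  v <- w$variability
  if (any(v < 0) || anyNA(v)) cfa_stop("variability scores must be non-negative")
  if (length(n_keep) != 1L || !is.finite(n_keep) || n_keep < 1) {
    cfa_stop("`n_keep` must be a positive integer")
  }
  if (n_keep >= length(v)) return(seq_along(v))
  picked <- order(-v, seq_along(v))[seq_len(n_keep)]
  sort(picked)
}

#' Subset an omics matrix to selected feature columns
#'
#' @param m omics matrix.
#' @param s integer vector of column positions (unique, within range,
#'   non-empty).
#' @return The column-subset matrix; patient order and the `data_type`
#'   attribute are preserved.
#' @export
filter_matrix <- function(m, s) {
  m <- as_omics(m)
  if (length(s) == 0L) cfa_stop("feature index set must not be empty")
  s <- as.integer(s)
  if (anyNA(s) || any(s < 1L) || any(s > ncol(m))) {
    cfa_stop(sprintf("feature indices out of range [1, %d]", ncol(m)))
  }
  if (anyDuplicated(s)) cfa_stop("feature indices must be unique")
  out <- m[, s, drop = FALSE]
  attr(out, "data_type") <- omics_data_type(m)
  out
}

# Internal: apply the configured filter to one omics matrix. Training is
# skipped entirely when it could not change the result (filter disabled or
# n_keep covers all features).
filter_omics <- function(m, config, seed) {
  f <- config$filter
  if (!isTRUE(f$enabled) || f$n_keep >= ncol(m)) return(m)
  w <- switch(f$method,
    autoencoder = train_weight_profile(
      m, hidden_dim = min(f$hidden_dim, ncol(m) - 1L),
      epochs = f$epochs, seed = seed),
    variance = variance_profile(m),
    cfa_stop(sprintf("unknown filter method '%s'", f$method)))
  filter_matrix(m, select_features(w, f$n_keep))
}
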