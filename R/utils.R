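# Internal helpers: error signalling, seed derivation, small numeric utilities.

# Validation failures (bad user input) and numerical failures (optimizer
# breakdown) carry distinct condition classes so callers -- in particular the
# command-line wrapper -- can map them to distinct exit codes.
cfa_stop <- function(msg, class = "cfa_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cfa_error", "error", "condition")))
}

cfa_numerical_stop <- function(msg) {
  cfa_stop(msg, class = "cfa_numerical_error")
}

#' Derive a reproducible stage seed from the run seed
#'
#' All randomness in the package flows from a single integer seed. Each
#' stochastic stage (label shuffling, autoencoder initialisation, each k-means
#' start, cross-validation folds, ...) derives its own seed from the run seed
#' plus a path of stage names/indices, so any stage can be re-run in isolation
#' and results do not depend on execution order.
#'
#' @param seed integer run seed.
#' @param ... stage path components (strings or integers).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "kmeans", 3, 7)
derive_seed <- function(seed, ...) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    cfa_stop("`seed` must be a single finite integer")
  }
  path <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  # 31-bit multiplicative string hash; exact in double precision (< 2^53)
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(path)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Column standardization that tolerates zero-variance columns (left at 0).
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  xs <- sweep(x, 2L, mu, "-")
  nz <- sd > 0
  xs[, nz] <- sweep(xs[, nz, drop = FALSE], 2L, sd[nz], "/")
  xs[, !nz] <- 0
  xs
}

# Relabel cluster ids to 1..k in order of first appearance.
canonicalize_labels <- function(labels) {
  first <- unique(labels)
  match(labels, first)
}

# Statistical mode with smallest-value tie-break.
mode_smallest <- function(x) {
  tab <- table(x)
  min(as.numeric(names(tab)[tab == max(tab)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
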