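# Run configuration: one nested list drives every stage of the pipeline.

#' Default run configuration
#'
#' Returns the full set of tunable parameters with their defaults. Every
#' pipeline entry point ([subtype_omics()], [predict_risk()]) accepts a
#' configuration built by [build_config()]; all defaults are resolvable
#' without any configuration file.
#'
#' Sections:
#' \describe{
#'   \item{seed}{integer; the single source of all randomness (see
#'     [derive_seed()]).}
#'   \item{filter}{`enabled`, `method` ("autoencoder" or "variance"),
#'     `hidden_dim` (autoencoder bottleneck width), `epochs`, `n_keep`
#'     (features retained per omics; `n_keep >= p` disables filtering for
#'     that matrix).}
#'   \item{fa}{`factor_counts` (grid of factor numbers, default 2..10),
#'     `max_iter`, `tol` (minimum objective improvement).}
#'   \item{cluster}{`k_min`, `k_max` (cluster-count search range),
#'     `n_starts` (k-means restarts), `delta` (BSS/TSS gain plateau
#'     threshold), `k_final` ("auto" or an integer).}
#'   \item{risk}{`folds` (cross-validation folds), `alpha_mix` (elastic-net
#'     mixing weight, 0 = ridge, 1 = lasso), `fit_fa_on_train_only`
#'     (leakage-free embedding variant).}
#'   \item{io}{`delimiter`, `max_missing` (row/column missingness threshold
#'     before dropping).}
#' }
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    filter = list(
      enabled = TRUE,
      method = "autoencoder",
      hidden_dim = 50L,
      epochs = 50L,
      n_keep = 2000L
    ),
    fa = list(
      factor_counts = 2:10,
      max_iter = 1000L,
      tol = 1e-6
    ),
    cluster = list(
      k_min = 2L,
      k_max = 10L,
      n_starts = 20L,
      delta = 0.05,
      k_final = "auto"
    ),
    risk = list(
      folds = 5L,
      alpha_mix = 0.5,
      fit_fa_on_train_only = FALSE
    ),
    io = list(
      delimiter = "\t",
      max_missing = 0.2
    )
  )
}

#' Build a run configuration from overrides
#'
#' Starts from [default_config()] and applies overrides from a YAML file
#' and/or a nested list (list overrides win). Unknown keys are rejected, so
#' typos fail loudly instead of silently running with defaults.
#'
#' @param overrides nested named list of settings to change, e.g.
#'   `list(seed = 7, cluster = list(n_starts = 10))`.
#' @param file optional path to a YAML file with the same structure.
#' @return The merged configuration list.
#' @export
#' @examples
#' cfg <- build_config(list(seed = 42, filter = list(method = "variance")))
#' cfg$filter$method
build_config <- function(overrides = list(), file = NULL) {
  cfg <- default_config()
  if (!is.null(file)) {
    cfg <- merge_config(cfg, yaml::read_yaml(file), path = "")
  }
  merge_config(cfg, overrides, path = "")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0L) return(base)
  keys <- names(overrides)
  if (is.null(keys) || any(keys == "")) {
    cfa_stop(sprintf("configuration overrides%s must be a named list",
                     if (nzchar(path)) paste0(" under '", path, "'") else ""))
  }
  for (key in keys) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      cfa_stop(sprintf("unknown configuration key: '%s'", full))
    }
    if (is.list(base[[key]])) {
      if (!is.list(overrides[[key]])) {
        cfa_stop(sprintf("configuration section '%s' must be a list", full))
      }
      base[[key]] <- merge_config(base[[key]], overrides[[key]], full)
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}
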