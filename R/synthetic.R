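# Synthetic multi-omics cohorts with planted subtypes and survival structure.
# These are the test bed for the whole pipeline: every downstream stage can be
# exercised against known ground truth without any external download.

#' Generate multi-omics matrices with planted subtype structure
#'
#' Draws `n_patients` patients from `G = length(subtype_proportions)`
#' subtypes and, for each requested omics, a Gaussian matrix in which a
#' subset of "informative" features carries subtype-specific mean shifts of
#' size `effect_size` (in units of `noise_sd`); all remaining features are
#' pure noise. The same subtype labels drive every omics, but each omics
#' draws its own informative feature set, mirroring the premise that each
#' data type contributes its own view of the shared structure.
#'
#' Subtype counts follow `subtype_proportions` by largest-remainder
#' apportionment (every subtype receives at least one patient when
#' `n_patients >= G`), then patients are shuffled. By default the
#' informative features of each omics are split evenly across subtypes:
#' the features in subtype g's block are shifted upward only for patients
#' of subtype g, so all subtypes are separable within every omics. With
#' `signal_split = TRUE`, omics `d` instead elevates its informative block
#' only for subtype `((d - 1) mod G) + 1`: no single omics separates all
#' subtypes, and only integration across omics recovers the full partition.
#'
#' @param n_patients number of patients (>= number of subtypes).
#' @param subtype_proportions probability vector, one entry per subtype;
#'   must be non-negative and sum to 1.
#' @param omics_specs list of specs, one per omics: each a list with
#'   `n_features`, `n_informative`, and optionally `data_type`.
#' @param effect_size mean separation between subtypes on informative
#'   features, in units of `noise_sd` (>= 0; 0 plants no signal).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param signal_split logical; distribute subtype contrasts across omics
#'   (see Details).
#' @param seed integer seed; generation is a pure function of the arguments.
#' @return A list of class `"synthetic_cohort"` with elements `omics`
#'   (list of omics matrices), `true_labels` (integer subtype per patient,
#'   named), `informative` (per-omics integer vectors of informative column
#'   positions), and `seed`.
#' @seealso [generate_survival()], [simulate_cohort()]
#' @export
#' @examples
#' cohort <- generate_multiomics(60, c(0.5, 0.3, 0.2),
#'   list(list(n_features = 40, n_informative = 10)),
#'   effect_size = 3, seed = 1)
#' table(cohort$true_labels)
generate_multiomics <- function(n_patients, subtype_proportions, omics_specs,
                                effect_size = 5, noise_sd = 1,
                                signal_split = FALSE, seed = 1) {
  G <- length(subtype_proportions)
  if (G < 1L) cfa_stop("at least one subtype proportion is required")
  if (any(subtype_proportions < 0) ||
      abs(sum(subtype_proportions) - 1) > 1e-8) {
    cfa_stop("`subtype_proportions` must be non-negative and sum to 1")
  }
  if (n_patients < G) cfa_stop("`n_patients` must be >= the number of subtypes")
  if (effect_size < 0) cfa_stop("`effect_size` must be >= 0")
  if (noise_sd <= 0) cfa_stop("`noise_sd` must be > 0")
  if (!is.list(omics_specs) || length(omics_specs) == 0L) {
    cfa_stop("`omics_specs` must be a non-empty list of specs")
  }

  counts <- apportion_counts(n_patients, subtype_proportions)
  set.seed(derive_seed(seed, "labels"))
  true_labels <- sample(rep.int(seq_len(G), counts))
  patient_ids <- sprintf("P%03d", seq_len(n_patients))
  names(true_labels) <- patient_ids

  omics <- vector("list", length(omics_specs))
  informative <- vector("list", length(omics_specs))
  for (d in seq_along(omics_specs)) {
    spec <- omics_specs[[d]]
    p <- spec$n_features
    p_inf <- spec$n_informative %||% 0L
    if (is.null(p) || p < 1L) cfa_stop(sprintf("omics %d: `n_features` >= 1 required", d))
    if (p_inf > p) {
      cfa_stop(sprintf("omics %d: n_informative (%d) exceeds n_features (%d)",
                       d, p_inf, p))
    }
    dt <- spec$data_type %||% paste0("omics", d)
    set.seed(derive_seed(seed, "omics", d))
    x <- matrix(stats::rnorm(n_patients * p, sd = noise_sd), n_patients, p)
    inf_idx <- integer(0)
    if (p_inf > 0L) {
      inf_idx <- sort(sample.int(p, p_inf))
      shift <- effect_size * noise_sd
      if (signal_split) {
        # this omics' whole informative block marks one subtype
        g <- (d - 1L) %% G + 1L
        x[true_labels == g, inf_idx] <- x[true_labels == g, inf_idx] + shift
      } else {
        blocks <- split(inf_idx, rep_len(seq_len(G), p_inf))
        for (g in seq_len(G)) {
          if (length(blocks[[g]])) {
            x[true_labels == g, blocks[[g]]] <-
              x[true_labels == g, blocks[[g]]] + shift
          }
        }
      }
    }
    omics[[d]] <- omics_matrix(x, patient_ids,
                               sprintf("%s_f%04d", dt, seq_len(p)),
                               data_type = dt)
    informative[[d]] <- inf_idx
  }

  structure(list(omics = omics, true_labels = true_labels,
                 informative = informative, seed = seed),
            class = "synthetic_cohort")
}

# Largest-remainder apportionment of n into groups with target proportions;
# guarantees every positive-proportion group at least one member when n >= G.
apportion_counts <- function(n, proportions) {
  G <- length(proportions)
  target <- n * proportions
  counts <- floor(target)
  remainder <- n - sum(counts)
  if (remainder > 0) {
    frac_order <- order(target - counts, decreasing = TRUE)
    counts[frac_order[seq_len(remainder)]] <- counts[frac_order[seq_len(remainder)]] + 1
  }
  if (n >= G) {
    while (any(counts == 0)) {
      counts[which.max(counts)] <- counts[which.max(counts)] - 1
      counts[which(counts == 0)[1L]] <- 1
    }
  }
  as.integer(counts)
}

#' Simulate survival times under a proportional-hazards model
#'
#' Draws event times with per-patient hazard `baseline x risk multiplier`
#' under an exponential (default) or Weibull model, plus an independent
#' censoring process calibrated so that approximately `censor_rate` of
#' patients are censored. The observed time is the minimum of event and
#' censoring time; the event indicator is 1 when the event came first.
#'
#' The risk multiplier is either given directly (`true_risk`) or derived
#' from subtype labels via `hazard_ratios` (one positive ratio per subtype).
#' Under the exponential model the mean event time of a group is
#' `baseline_scale / hazard_ratio`, so a ratio of 4 halves-and-halves the
#' expected survival twice over. Censoring times share the event
#' distribution's shape, with rate chosen by root finding so that the mean
#' of `c / (c + rate_i)` equals `censor_rate`.
#'
#' @param true_labels integer subtype per patient (used with
#'   `hazard_ratios`); ignored when `true_risk` is given.
#' @param true_risk positive per-patient relative hazard multiplier.
#' @param hazard_ratios positive vector, one entry per subtype.
#' @param baseline_scale mean event time (e.g. days) at risk multiplier 1
#'   (> 0).
#' @param censor_rate target fraction of censored patients, in `[0, 1)`.
#' @param dist `"exponential"` or `"weibull"`.
#' @param shape Weibull shape (1 recovers the exponential model).
#' @param seed integer seed.
#' @param patient_ids optional identifiers (defaults to names of the risk
#'   or label vector).
#' @return A `data.frame` with columns `patient_id`, `time` (> 0), `event`
#'   (0 censored / 1 event), plus attribute `true_risk`.
#' @export
#' @examples
#' surv <- generate_survival(true_labels = rep(1:2, each = 20),
#'   hazard_ratios = c(4, 1), baseline_scale = 365,
#'   censor_rate = 0.2, seed = 1)
#' head(surv)
generate_survival <- function(true_labels = NULL, true_risk = NULL,
                              hazard_ratios = NULL, baseline_scale = 1000,
                              censor_rate = 0.3, dist = c("exponential", "weibull"),
                              shape = 1, seed = 1, patient_ids = NULL) {
  dist <- match.arg(dist)
  if (dist == "exponential") shape <- 1
  if (baseline_scale <= 0) cfa_stop("`baseline_scale` must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) {
    cfa_stop("`censor_rate` must lie in [0, 1)")
  }
  if (shape <= 0) cfa_stop("`shape` must be > 0")
  if (is.null(true_risk)) {
    if (is.null(true_labels) || is.null(hazard_ratios)) {
      cfa_stop("provide `true_risk`, or `true_labels` with `hazard_ratios`")
    }
    if (any(hazard_ratios <= 0)) cfa_stop("`hazard_ratios` must be positive")
    if (max(true_labels) > length(hazard_ratios)) {
      cfa_stop("`hazard_ratios` needs one entry per subtype")
    }
    true_risk <- hazard_ratios[true_labels]
    patient_ids <- patient_ids %||% names(true_labels)
  } else {
    if (any(true_risk <= 0)) cfa_stop("`true_risk` must be positive")
    patient_ids <- patient_ids %||% names(true_risk)
  }
  n <- length(true_risk)
  patient_ids <- patient_ids %||% sprintf("P%03d", seq_len(n))

  rate <- true_risk / baseline_scale
  set.seed(derive_seed(seed, "survival"))
  # cumulative hazard H(t) = rate * t^shape  =>  T = (E / rate)^(1/shape)
  event_time <- (stats::rexp(n) / rate)^(1 / shape)
  if (censor_rate > 0) {
    # with a shared shape, P(censor first) = c / (c + rate_i) per patient
    c_rate <- stats::uniroot(
      function(cc) mean(cc / (cc + rate)) - censor_rate,
      lower = min(rate) * 1e-8, upper = max(rate) * 1e8,
      tol = 1e-12)$root
    censor_time <- (stats::rexp(n) / c_rate)^(1 / shape)
    time <- pmin(event_time, censor_time)
    event <- as.integer(event_time <= censor_time)
  } else {
    time <- event_time
    event <- rep(1L, n)
  }
  time <- pmax(time, .Machine$double.eps)
  out <- data.frame(patient_id = as.character(patient_ids),
                    time = time, event = event,
                    stringsAsFactors = FALSE)
  attr(out, "true_risk") <- stats::setNames(true_risk, patient_ids)
  out
}

#' Simulate a complete multi-omics cohort with survival
#'
#' Convenience wrapper combining [generate_multiomics()] and
#' [generate_survival()] into one cohort object whose survival hazard
#' depends on the planted subtype.
#'
#' @inheritParams generate_multiomics
#' @inheritParams generate_survival
#' @return A `"synthetic_cohort"` list with `omics`, `true_labels`,
#'   `informative`, `true_risk`, `survival`, and `seed`.
#' @export
simulate_cohort <- function(n_patients, subtype_proportions, omics_specs,
                            effect_size = 5, noise_sd = 1,
                            signal_split = FALSE,
                            hazard_ratios = rep(1, length(subtype_proportions)),
                            baseline_scale = 1000, censor_rate = 0.3,
                            dist = "exponential", shape = 1, seed = 1) {
  cohort <- generate_multiomics(n_patients, subtype_proportions, omics_specs,
                                effect_size = effect_size, noise_sd = noise_sd,
                                signal_split = signal_split, seed = seed)
  cohort$survival <- generate_survival(
    true_labels = cohort$true_labels, hazard_ratios = hazard_ratios,
    baseline_scale = baseline_scale, censor_rate = censor_rate,
    dist = dist, shape = shape, seed = seed)
  cohort$true_risk <- attr(cohort$survival, "true_risk")
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic multi-omics cohort: %d patients, %d subtypes, %d omics\n",
              length(x$true_labels), length(unique(x$true_labels)),
              length(x$omics)))
  for (d in seq_along(x$omics)) {
    cat(sprintf("  %s: %d features (%d informative)\n",
                omics_data_type(x$omics[[d]]), ncol(x$omics[[d]]),
                length(x$informative[[d]])))
  }
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: %d events / %d patients\n",
                sum(x$survival$event), nrow(x$survival)))
  }
  invisible(x)
}
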