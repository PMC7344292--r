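# Evaluation metrics: survival separation of discovered subtypes (Cox
# likelihood-ratio p-value), ranking accuracy of predicted risks (Harrell's
# concordance index), and partition agreement (adjusted Rand index,
# normalized mutual information).

#' Cox p-value for survival differences between subtypes
#'
#' Fits a Cox proportional-hazards model (Efron tie handling) with the
#' subtype as a categorical covariate and returns the likelihood-ratio test
#' p-value against the null of no subtype effect. Invariant to relabeling
#' of subtype ids.
#'
#' @param labels subtype assignment per patient (>= 2 distinct values,
#'   each group containing at least one event).
#' @param surv survival `data.frame` (`patient_id`, `time`, `event`); when
#'   `labels` is named, patients are matched by ID, otherwise by position.
#' @return p-value in `(0, 1]`.
#' @export
cox_subtype_pvalue <- function(labels, surv) {
  surv <- validate_survival(surv)
  surv <- align_surv_to(labels, surv)
  groups <- factor(labels)
  if (nlevels(groups) < 2L) {
    cfa_stop("at least 2 subtypes are required for a survival comparison")
  }
  events_per_group <- tapply(surv$event, groups, sum)
  if (any(events_per_group == 0)) {
    cfa_stop(sprintf("subtype(s) without any event: %s",
                     paste(names(events_per_group)[events_per_group == 0],
                           collapse = ", ")))
  }
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ groups,
                         ties = "efron")
  lrt <- 2 * (fit$loglik[2L] - fit$loglik[1L])
  stats::pchisq(lrt, df = nlevels(groups) - 1L, lower.tail = FALSE)
}

#' Harrell's concordance index by exhaustive pair enumeration
#'
#' The probability that, of a comparable patient pair, the patient with the
#' higher predicted risk experiences the event first. A pair is comparable
#' when the strictly earlier observed time belongs to an event (tied
#' observed times are never comparable, including two events at the same
#' time); tied risks in a comparable pair count 0.5. Every pair is
#' enumerated explicitly.
#'
#' @param risk numeric predicted risk per patient (higher = worse).
#' @param surv survival `data.frame`; matched to `risk` by name when
#'   `risk` is named, else by position.
#' @return Concordance in `[0, 1]`, with attribute `n_comparable` (the
#'   number of comparable pairs).
#' @export
#' @examples
#' surv <- data.frame(patient_id = c("a", "b", "c"),
#'                    time = c(1, 2, 3), event = 1)
#' concordance_index(c(3, 2, 1), surv)  # 1: perfect ranking
concordance_index <- function(risk, surv) {
  surv <- validate_survival(surv)
  surv <- align_surv_to(risk, surv)
  n <- length(risk)
  time <- surv$time
  event <- surv$event
  # ordered pairs (i, j): comparable when t_i < t_j and patient i had the event
  earlier <- outer(time, time, "<")
  comparable <- earlier & matrix(event == 1, n, n)
  n_comp <- sum(comparable)
  if (n_comp == 0L) cfa_stop("no comparable pairs (check censoring/times)")
  risk_gt <- outer(risk, risk, ">")
  risk_eq <- outer(risk, risk, "==")
  concordant <- sum(comparable & risk_gt)
  tied <- sum(comparable & risk_eq)
  out <- (concordant + 0.5 * tied) / n_comp
  attr(out, "n_comparable") <- n_comp
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-adjusted pair-counting agreement computed from the contingency
#' table under the permutation model: 1 for identical partitions (up to
#' relabeling), expectation approximately 0 for independent partitions.
#'
#' @param a,b partitions (vectors of cluster labels, equal length >= 2).
#' @return ARI, at most 1.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
adjusted_rand_index <- function(a, b) {
  check_partition_pair(a, b)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(sum(tab))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies, in `[0, 1]`; 1 for identical partitions with more than one
#' cluster. When both partitions are constant (both entropies zero) the
#' value is defined as 0.
#'
#' @inheritParams adjusted_rand_index
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(a, b) {
  check_partition_pair(a, b)
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (entropy(pa) + entropy(pb)) / 2
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

check_partition_pair <- function(a, b) {
  if (length(a) != length(b)) {
    cfa_stop("partitions must have equal length")
  }
  if (length(a) < 2L) cfa_stop("partitions must cover at least 2 items")
}

#' Evaluation report for a subtyping or risk-prediction run
#'
#' Computes every metric the supplied inputs allow: `cox_p` (needs
#' `labels` + `surv`), `c_index` and `n_pairs_comparable` (needs `risk` +
#' `surv`), `ari` and `nmi` (needs `labels` + `truth`).
#'
#' @param labels discovered subtype per patient (optional).
#' @param risk predicted risk per patient (optional).
#' @param surv survival table (optional).
#' @param truth reference partition (optional).
#' @return Named list with the available metrics.
#' @export
evaluation_report <- function(labels = NULL, risk = NULL, surv = NULL,
                              truth = NULL) {
  report <- list()
  if (!is.null(labels) && !is.null(surv)) {
    report$cox_p <- cox_subtype_pvalue(labels, surv)
  }
  if (!is.null(risk) && !is.null(surv)) {
    ci <- concordance_index(risk, surv)
    report$c_index <- as.numeric(ci)
    report$n_pairs_comparable <- attr(ci, "n_comparable")
  }
  if (!is.null(labels) && !is.null(truth)) {
    report$ari <- adjusted_rand_index(labels, truth)
    report$nmi <- normalized_mutual_information(labels, truth)
  }
  report
}

# Match a survival table to a metric's first argument: by patient ID when
# names are available, by position otherwise.
align_surv_to <- function(x, surv) {
  n <- length(x)
  ids <- names(x)
  if (!is.null(ids)) {
    ord <- match(ids, surv$patient_id)
    if (anyNA(ord)) {
      cfa_stop(sprintf("no survival record for patient(s): %s",
                       paste(utils::head(ids[is.na(ord)], 5L), collapse = ", ")))
    }
    return(surv[ord, ])
  }
  if (nrow(surv) != n) {
    cfa_stop("survival table length does not match the input vector")
  }
  surv
}
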