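# Consensus ensemble subtyping. Every factor representation is clustered by
# multi-start k-means at a cluster count chosen by an explained-variance
# plateau; each partition becomes a binary patient-patient connectivity
# matrix; the full collection is merged by weighted meta-clustering into one
# final subtype assignment.

#' Choose the cluster count by explained-variance plateau
#'
#' For each candidate `k`, runs multi-start k-means and records the
#' explained-variance index `r_k = BSS / TSS` (between-cluster over total
#' sum of squares). Returns the smallest `k` whose gain `r_{k+1} - r_k`
#' falls below `delta` (the increase of within-cluster sum of squares has
#' levelled off), or `k_max` when no plateau occurs in range.
#'
#' @param rep a `"factor_representation"` (or a plain score matrix).
#' @param k_min,k_max candidate range, `2 <= k_min <= k_max <= n - 1`.
#' @param n_starts k-means restarts per candidate.
#' @param seed integer seed.
#' @param delta plateau threshold on the BSS/TSS gain.
#' @return The selected integer cluster count.
#' @export
optimal_cluster_count <- function(rep, k_min = 2L, k_max = 10L,
                                  n_starts = 20L, seed = 1, delta = 0.05) {
  x <- rep_scores(rep)
  n <- nrow(x)
  if (k_min < 2L || k_min > k_max || k_max > n - 1L) {
    cfa_stop(sprintf("require 2 <= k_min <= k_max <= %d", n - 1L))
  }
  n_distinct <- nrow(unique(x))
  k_hi <- min(k_max, n_distinct)
  if (k_min > k_hi) return(as.integer(k_min))
  if (k_min == k_hi) return(as.integer(k_min))

  tss <- sum(sweep(x, 2L, colMeans(x), "-")^2)
  ks <- k_min:k_hi
  r <- vapply(ks, function(k) {
    sse <- best_kmeans(x, k, n_starts, derive_seed(seed, "kscan", k))$sse
    1 - sse / tss
  }, numeric(1))
  gains <- diff(r)
  plateau <- which(gains < delta)
  if (length(plateau)) as.integer(ks[plateau[1L]]) else as.integer(k_hi)
}

#' Cluster one factor representation with multi-start k-means
#'
#' Runs `n_starts` k-means initialisations (seeds derived deterministically
#' from `seed`) and keeps the run with the smallest within-cluster sum of
#' squared errors. Labels are canonicalized so cluster ids follow first
#' patient occurrence, making results comparable across runs.
#'
#' @inheritParams optimal_cluster_count
#' @param k number of clusters, `2 <= k <= n - 1` and at most the number
#'   of distinct points.
#' @return A list of class `"partition"`: `labels` (named integer vector),
#'   `k`, `sse` (winning within-cluster sum of squares), `source`.
#' @export
cluster_representation <- function(rep, k, n_starts = 20L, seed = 1) {
  x <- rep_scores(rep)
  n <- nrow(x)
  if (k < 2L || k > n - 1L) {
    cfa_stop(sprintf("`k` must lie in [2, %d]", n - 1L))
  }
  if (nrow(unique(x)) < k) {
    cfa_stop(sprintf("k = %d exceeds the number of distinct points", k))
  }
  best <- best_kmeans(x, k, n_starts, derive_seed(seed, "cluster", k))
  labels <- canonicalize_labels(best$labels)
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = as.integer(k), sse = best$sse,
                 source = rep_source(rep)),
            class = "partition")
}

# Internal: best-of-n_starts k-means (smallest total within-cluster SSE).
best_kmeans <- function(x, k, n_starts, seed) {
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(derive_seed(seed, "start", s))
    km <- tryCatch(stats::kmeans(x, centers = k, iter.max = 100L, nstart = 1L),
                   error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$sse) {
      best <- list(labels = km$cluster, sse = km$tot.withinss)
    }
  }
  if (is.null(best)) {
    cfa_numerical_stop(sprintf("all %d k-means starts failed at k = %d",
                               n_starts, k))
  }
  best
}

rep_scores <- function(rep) {
  x <- if (inherits(rep, "factor_representation")) rep$scores else rep
  if (!is.matrix(x) || !is.numeric(x)) {
    cfa_stop("expected a factor_representation or a numeric score matrix")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  x
}

rep_source <- function(rep) {
  if (inherits(rep, "factor_representation")) rep$source else list()
}

#' Connectivity matrix of a partition
#'
#' Binary patient-patient co-membership indicator: entry `(i, j)` is 1
#' exactly when patients `i` and `j` share a cluster. Symmetric with unit
#' diagonal.
#'
#' @param p a `"partition"` (or a bare label vector).
#' @return `n x n` binary matrix with patient IDs as dimnames.
#' @export
#' @examples
#' connectivity_matrix(c(1, 1, 2))
connectivity_matrix <- function(p) {
  labels <- if (inherits(p, "partition")) p$labels else p
  if (length(labels) < 1L) cfa_stop("empty partition")
  cm <- outer(labels, labels, "==") + 0
  ids <- names(labels) %||% paste0("P", seq_along(labels))
  dimnames(cm) <- list(ids, ids)
  cm
}

#' Combine clusterings by weighted meta-clustering
#'
#' Merges an ensemble of partitions (with their connectivity matrices) into
#' one final subtype assignment in four steps: (1) the pairwise weight of
#' two patients is their co-clustering frequency across all connectivity
#' matrices (the consensus matrix); (2) each patient's weight accumulates
#' its pairwise weights; (3) all clusters from all partitions are pooled
#' and compared by weighted Jaccard similarity
#' `sim(A, B) = sum(v[A intersect B]) / sum(v[A union B])` over patient
#' weights `v`; (4) the pooled clusters are grouped by average-linkage
#' hierarchical clustering on `1 - sim`, cut into `k_final` meta-clusters,
#' and each patient joins the meta-cluster holding the plurality of its
#' source clusters (ties go to the meta-cluster with the larger summed
#' similarity to the patient's clusters).
#'
#' When every partition is identical the procedure reduces to that
#' partition and the consensus matrix is binary.
#'
#' @param connectivities list of connectivity matrices on one patient set.
#' @param partitions the matching list of `"partition"` objects.
#' @param k_final final subtype count, or `"auto"` (the mode of the
#'   per-partition cluster counts; ties resolved toward the smaller count).
#' @return A list of class `"subtype_result"`: `labels` (named integer
#'   vector), `k_final`, `consensus` (mean connectivity, entries in
#'   `[0, 1]`), `partitions`, `patient_weights`.
#' @export
weighted_meta_cluster <- function(connectivities, partitions,
                                  k_final = "auto") {
  if (length(connectivities) == 0L || length(partitions) == 0L) {
    cfa_stop("at least one connectivity matrix and partition required")
  }
  if (length(connectivities) != length(partitions)) {
    cfa_stop("`connectivities` and `partitions` must have equal length")
  }
  ids <- rownames(connectivities[[1L]])
  n <- length(ids)
  for (cm in connectivities) {
    if (nrow(cm) != n || !identical(rownames(cm), ids)) {
      cfa_stop("connectivity matrices must share one patient set and order")
    }
  }
  R <- length(connectivities)

  # (1) consensus = mean connectivity; (2) patient weights
  consensus <- Reduce(`+`, connectivities) / R
  diag(consensus) <- 1
  v <- rowSums(consensus) - 1

  # (3) pool clusters across partitions
  members <- list()
  part_of <- integer(0)
  for (r in seq_len(R)) {
    labs <- partitions[[r]]$labels
    if (length(labs) != n) cfa_stop("partition length does not match patients")
    for (g in sort(unique(labs))) {
      members[[length(members) + 1L]] <- which(labs == g)
      part_of <- c(part_of, r)
    }
  }
  n_cl <- length(members)
  sim <- matrix(1, n_cl, n_cl)
  for (a in seq_len(n_cl - 1L)) {
    for (b in (a + 1L):n_cl) {
      inter <- intersect(members[[a]], members[[b]])
      uni <- union(members[[a]], members[[b]])
      denom <- sum(v[uni])
      s <- if (denom > 0) sum(v[inter]) / denom else length(inter) / length(uni)
      sim[a, b] <- s
      sim[b, a] <- s
    }
  }

  if (identical(k_final, "auto")) {
    k_final <- mode_smallest(vapply(partitions, `[[`, integer(1), "k"))
  }
  k_final <- as.integer(k_final)
  if (k_final < 2L) cfa_stop("`k_final` must be at least 2")
  k_cut <- min(k_final, n_cl)

  # (4) hierarchical cut of the cluster-to-cluster similarity
  if (n_cl > 1L) {
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    meta <- stats::cutree(hc, k = k_cut)
  } else {
    meta <- 1L
  }

  # patient -> meta-cluster by plurality of its source clusters
  labels <- integer(n)
  for (i in seq_len(n)) {
    mine <- which(vapply(members, function(mm) i %in% mm, logical(1)))
    votes <- table(meta[mine])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) > 1L) {
      score <- vapply(top, function(m) {
        sum(sim[mine, meta == m, drop = FALSE])
      }, numeric(1))
      top <- top[order(-score, top)][1L]
    }
    labels[i] <- top
  }
  labels <- canonicalize_labels(labels)
  names(labels) <- ids

  structure(list(labels = labels,
                 k_final = length(unique(labels)),
                 consensus = consensus,
                 partitions = partitions,
                 patient_weights = stats::setNames(v, ids)),
            class = "subtype_result")
}

#' Discover consensus subtypes from multi-omics data
#'
#' End-to-end unsupervised pipeline: for every omics matrix, filter
#' features, generate factor representations over the configured factor
#' grid, choose a cluster count and partition each representation with
#' multi-start k-means, build connectivity matrices, and merge everything
#' with [weighted_meta_cluster()]. Fully deterministic given
#' `config$seed`.
#'
#' @param omics_list list of omics matrices sharing one patient-ID set
#'   (order may differ; matrices are aligned by ID).
#' @param config configuration from [build_config()].
#' @return A `"subtype_result"` (see [weighted_meta_cluster()]) with an
#'   additional `representation_meta` data.frame of provenance (data type,
#'   factor count, chosen cluster count, fit residual per representation).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_multiomics(60, rep(1 / 3, 3),
#'   list(list(n_features = 100, n_informative = 40)),
#'   effect_size = 4, seed = 1)
#' res <- subtype_omics(cohort$omics,
#'   build_config(list(fa = list(factor_counts = 2:4))))
#' table(res$labels, cohort$true_labels)
#' }
subtype_omics <- function(omics_list, config = build_config()) {
  omics_list <- align_omics(omics_list)
  n <- nrow(omics_list[[1L]])
  if (n < 10L) cfa_stop("subtyping requires at least 10 patients")
  seed <- config$seed
  cl <- config$cluster

  partitions <- list()
  connectivities <- list()
  meta <- list()
  for (d in seq_along(omics_list)) {
    m <- filter_omics(omics_list[[d]], config, derive_seed(seed, "filter", d))
    ks <- pmin(config$fa$factor_counts, n - 1L)
    ks <- unique(ks)
    reps <- generate_representations(m, ks, max_iter = config$fa$max_iter,
                                     tol = config$fa$tol)
    for (r in seq_along(reps)) {
      k_max <- min(cl$k_max, n - 1L)
      k_opt <- optimal_cluster_count(reps[[r]], k_min = cl$k_min,
                                     k_max = k_max, n_starts = cl$n_starts,
                                     seed = derive_seed(seed, "kopt", d, r),
                                     delta = cl$delta)
      part <- cluster_representation(reps[[r]], k_opt,
                                     n_starts = cl$n_starts,
                                     seed = derive_seed(seed, "part", d, r))
      partitions[[length(partitions) + 1L]] <- part
      connectivities[[length(connectivities) + 1L]] <- connectivity_matrix(part)
      meta[[length(meta) + 1L]] <- data.frame(
        data_type = omics_data_type(omics_list[[d]]),
        n_factors = reps[[r]]$k, k_clusters = k_opt,
        fit_residual = reps[[r]]$fit_residual,
        stringsAsFactors = FALSE)
    }
  }
  result <- weighted_meta_cluster(connectivities, partitions,
                                  k_final = cl$k_final)
  result$representation_meta <- do.call(rbind, meta)
  result
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("Consensus subtyping: %d patients, %d subtypes (from %d partitions)\n",
              length(x$labels), x$k_final, length(x$partitions)))
  print(table(subtype = x$labels))
  invisible(x)
}
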