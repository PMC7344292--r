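# Cluster-count selection, multi-start k-means, connectivity matrices, and
# weighted meta-clustering.

make_blobs <- function(seed, n_per = 50, centers = rbind(c(0, 0), c(10, 0),
                                                         c(20, 0))) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
    sweep(matrix(stats::rnorm(n_per * ncol(centers)), n_per), 2,
          centers[g, ], "+")
  }))
  rownames(x) <- paste0("P", seq_len(nrow(x)))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("cluster-count selection finds well-separated blobs", {
  hits <- vapply(1:20, function(s) {
    b <- make_blobs(s)
    optimal_cluster_count(b$x, 2, 8, n_starts = 10, seed = s) == 3L
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("cluster-count selection matches the brute-force index oracle", {
  b <- make_blobs(42)
  k_sel <- optimal_cluster_count(b$x, 2, 6, n_starts = 10, seed = 1,
                                 delta = 0.05)
  # oracle: recompute BSS/TSS over the grid with generous restarts and apply
  # the plateau rule directly
  tss <- sum(scale(b$x, scale = FALSE)^2)
  r <- vapply(2:6, function(k) {
    set.seed(k)
    1 - stats::kmeans(b$x, k, nstart = 50, iter.max = 100)$tot.withinss / tss
  }, numeric(1))
  gains <- diff(r)
  k_oracle <- if (any(gains < 0.05)) (2:6)[which(gains < 0.05)[1]] else 6L
  expect_equal(k_sel, k_oracle)
})

test_that("a single spherical blob yields the minimum cluster count", {
  for (s in 1:3) {
    set.seed(s)
    y <- matrix(stats::rnorm(300 * 25), ncol = 25)
    rownames(y) <- paste0("P", 1:300)
    # premise of the plateau rule: all gains below delta for structureless data
    tss <- sum(scale(y, scale = FALSE)^2)
    r <- vapply(2:6, function(k) {
      set.seed(k)
      1 - stats::kmeans(y, k, nstart = 10, iter.max = 100)$tot.withinss / tss
    }, numeric(1))
    expect_lt(max(diff(r)), 0.05)
    expect_equal(optimal_cluster_count(y, 2, 6, n_starts = 10, seed = s), 2L)
  }
  expect_equal(optimal_cluster_count(make_blobs(1)$x, 2, 2, seed = 1), 2L)
})

test_that("multi-start k-means recovers planted blobs deterministically", {
  b <- make_blobs(5, centers = rbind(c(0, 0), c(10, 10)))
  p1 <- cluster_representation(b$x, 2, n_starts = 10, seed = 5)
  expect_equal(adjusted_rand_index(p1$labels, b$truth), 1.0)
  p2 <- cluster_representation(b$x, 2, n_starts = 10, seed = 5)
  expect_identical(p1, p2)
  # canonical labels: first patient opens cluster 1
  expect_equal(unname(p1$labels[1]), 1L)
  # argmin contract: winning SSE is no worse than each individual start
  sses <- vapply(1:10, function(s) {
    set.seed(derive_seed(derive_seed(5, "cluster", 2), "start", s))
    stats::kmeans(b$x, 2, iter.max = 100, nstart = 1)$tot.withinss
  }, numeric(1))
  expect_lte(p1$sse, min(sses))
  expect_error(cluster_representation(b$x, 1, seed = 1), "must lie")
  tiny <- matrix(rep(c(0, 1), each = 6), 4, 3)
  rownames(tiny) <- paste0("P", 1:4)
  expect_error(cluster_representation(tiny, 3, seed = 1), "distinct")
})

test_that("connectivity matrices encode co-membership", {
  expect_equal(unname(connectivity_matrix(c(1, 1, 2))),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(unname(connectivity_matrix(rep(1, 4))), matrix(1, 4, 4))
  set.seed(20)
  for (i in 1:5) {
    cm <- connectivity_matrix(sample(1:4, 30, replace = TRUE))
    expect_identical(cm, t(cm))
    expect_true(all(diag(cm) == 1))
    expect_true(all(cm %in% c(0, 1)))
  }
})

test_that("a unanimous ensemble reproduces its partition with binary consensus", {
  labs <- rep(1:3, each = 10)
  parts <- replicate(4, make_partition(labs), simplify = FALSE)
  conns <- lapply(parts, connectivity_matrix)
  res <- weighted_meta_cluster(conns, parts)
  expect_equal(adjusted_rand_index(res$labels, labs), 1.0)
  expect_true(all(res$consensus %in% c(0, 1)))
  expect_equal(res$k_final, 3L)
})

test_that("meta-clustering is invariant to ensemble order and relabeling", {
  set.seed(21)
  labs1 <- rep(1:3, each = 30)
  labs2 <- labs1; labs2[1:5] <- 2L
  labs3 <- sample(1:2, 90, replace = TRUE)
  parts <- lapply(list(labs1, labs1, labs2, labs3), make_partition)
  conns <- lapply(parts, connectivity_matrix)
  res <- weighted_meta_cluster(conns, parts, k_final = 3)
  perm <- c(3, 1, 4, 2)
  res_perm <- weighted_meta_cluster(conns[perm], parts[perm], k_final = 3)
  expect_identical(res$labels, res_perm$labels)
  # relabeling the cluster ids of an input partition cannot change the result
  relab <- lapply(list(labs1, labs1, labs2, labs3), function(l) {
    make_partition(c(9, 7, 8)[l])
  })
  res_relab <- weighted_meta_cluster(lapply(relab, connectivity_matrix),
                                     relab, k_final = 3)
  expect_identical(res$labels, res_relab$labels)
})

test_that("a three-to-one majority ensemble follows the majority", {
  maj <- rep(1:3, each = 30)
  dis <- rep(c(1, 2, 3), 30)
  parts <- lapply(list(maj, maj, maj, dis), make_partition)
  conns <- lapply(parts, connectivity_matrix)
  res <- weighted_meta_cluster(conns, parts)
  expect_equal(adjusted_rand_index(res$labels, maj), 1.0)
})

test_that("the consensus matrix equals the brute-force mean of connectivities", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(10:25, 1)
    R <- sample(2:5, 1)
    parts <- replicate(R, make_partition(sample(1:3, n, replace = TRUE)),
                       simplify = FALSE)
    conns <- lapply(parts, connectivity_matrix)
    res <- weighted_meta_cluster(conns, parts, k_final = 2)
    brute <- Reduce(`+`, conns) / R
    expect_equal(unname(res$consensus), unname(brute), tolerance = 1e-12)
    expect_true(all(res$consensus >= 0 & res$consensus <= 1))
  }
})

test_that("meta-clustering validates its inputs", {
  p <- make_partition(rep(1:2, 5))
  expect_error(weighted_meta_cluster(list(), list()), "at least one")
  q <- make_partition(rep(1:2, 4))
  expect_error(weighted_meta_cluster(list(connectivity_matrix(p),
                                          connectivity_matrix(q)),
                                     list(p, q)), "patient set")
})

test_that("the end-to-end subtype pipeline recovers planted subtypes", {
  cohort <- make_cohort(31, n = 150)
  cfg <- build_config(list(seed = 31))
  res <- subtype_omics(cohort$omics, cfg)
  expect_gte(adjusted_rand_index(res$labels, cohort$true_labels), 0.9)
  expect_equal(res$k_final, 3L)
  # provenance covers every representation of every omics
  expect_equal(nrow(res$representation_meta),
               3 * length(default_config()$fa$factor_counts))
  # single-omics input degenerates gracefully
  res1 <- subtype_omics(cohort$omics[1], cfg)
  expect_s3_class(res1, "subtype_result")
  expect_gte(res1$k_final, 2L)
})

test_that("subtyping aligns patients by ID, not by row order", {
  cohort <- make_cohort(32, n = 60, n_features = 150, n_informative = 50,
                        n_omics = 2)
  cfg <- build_config(list(seed = 32, fa = list(factor_counts = 2:4)))
  res <- subtype_omics(cohort$omics, cfg)
  shuffled <- cohort$omics
  set.seed(1)
  shuffled[[2]] <- subset_omics(shuffled[[2]], sample(nrow(shuffled[[2]])))
  res_sh <- subtype_omics(shuffled, cfg)
  expect_identical(res$labels, res_sh$labels)
  # mismatched patient sets are refused with the offenders named
  bad <- cohort$omics
  rownames(bad[[2]])[1] <- "INTRUDER"
  expect_error(subtype_omics(bad, cfg), "INTRUDER|differ")
})

test_that("recovered signal strengthens monotonically with effect size", {
  mean_ari <- vapply(c(0, 2, 5), function(es) {
    mean(vapply(1:10, function(s) {
      cohort <- make_cohort(s, n = 90, n_features = 150, n_informative = 50,
                            effect_size = es, n_omics = 2)
      cfg <- build_config(list(seed = s, fa = list(factor_counts = 2:5),
                               cluster = list(n_starts = 10)))
      adjusted_rand_index(subtype_omics(cohort$omics, cfg)$labels,
                          cohort$true_labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) >= 0))
  expect_lt(mean_ari[1], 0.3)
  expect_gt(mean_ari[3], 0.9)
})
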