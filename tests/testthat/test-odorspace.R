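test_that("odor distances match a brute-force loop for all metrics", {
  st <- tiny_trains(seed = 41)
  pn <- build_response_matrix(st, "first_round")
  for (metric in c("cosine", "euclidean", "correlation")) {
    D <- odor_distance_matrix(pn, metric)
    expect_equal(unclass(D), distance_oracle(unclass(pn), metric),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(isSymmetric(unclass(D)))
    expect_equal(unname(diag(D)), rep(0, ncol(pn)))
    expect_true(all(D >= 0))
  }
})

test_that("odor distance identities and degenerate vectors", {
  m <- cbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 2, 0), z = c(0, 0, 0))
  rownames(m) <- paste0("cl", 1:3)
  for (metric in c("cosine", "euclidean"))
    expect_equal(suppressWarnings(
      odor_distance_matrix(m, metric))["a", "b"], 0)
  expect_equal(suppressWarnings(odor_distance_matrix(m, "cosine"))["a", "c"],
               1)  # orthogonal non-negative vectors
  expect_warning(D <- odor_distance_matrix(m, "cosine"), "zero-norm")
  expect_equal(unname(D["z", c("a", "b", "c")]), rep(1, 3))
  expect_error(odor_distance_matrix(m[, 1, drop = FALSE]), "at least 2")
})

test_that("Ward clustering: pair merge height, tie-break, planted recovery", {
  # two items: single merge at their distance
  d2 <- matrix(c(0, 3.2, 3.2, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  dend <- hierarchical_cluster(olfmap:::new_distance_matrix(d2, "euclidean"))
  expect_equal(dend$height, 3.2)
  # three equidistant items: first merge is the smallest label pair
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  dend3 <- hierarchical_cluster(olfmap:::new_distance_matrix(d3, "euclidean"))
  expect_equal(sort(-dend3$merge[1, ]), c(1, 2))
  # planted 3-group matrices: cutting the tree into the planted number of
  # groups recovers the labels (ARI >= 0.9 over 20 seeds)
  aris <- sapply(1:20, function(s) {
    p <- generate_panel(8, 9, seed = s)
    m <- generate_model(p, n_classes = 31, n_groups = 3,
                        within_group_gain = 10, seed = s)
    D <- odor_distance_matrix(new_response_matrix(m$mean_rate), "cosine")
    adjusted_rand(cutree(hierarchical_cluster(D), k = 3), m$group_of_odor)
  })
  expect_true(all(aris >= 0.9))
})

test_that("dendrogram cuts behave and are monotone in the threshold", {
  st <- tiny_trains(seed = 42)
  pn <- build_response_matrix(st, "first_round")
  dend <- hierarchical_cluster(odor_distance_matrix(pn, "cosine"))
  expect_equal(length(unique(cut_dendrogram(dend, max(dend$height) * 1.01))),
               1)
  expect_equal(length(unique(cut_dendrogram(dend, min(dend$height) * 0.99))),
               ncol(pn))
  ths <- seq(0.05, 2, by = 0.05)
  ns <- sapply(ths, function(h) length(unique(cut_dendrogram(dend, h))))
  expect_true(all(diff(ns) <= 0))
  # fraction-of-max mode agrees with the absolute cut at that height
  expect_equal(cut_dendrogram(dend, 0.7, "fraction_of_max"),
               cut_dendrogram(dend, 0.7 * max(dend$height), "absolute"))
})

test_that("cluster-signature glomeruli follow the mean-rate threshold", {
  st <- tiny_trains(seed = 43)
  pn <- build_response_matrix(st, "first_round")
  clusters <- setNames(rep(1:2, length.out = ncol(pn)), colnames(pn))
  sig <- cluster_signature_glomeruli(pn, clusters, rate_threshold = 30)
  glom <- attr(pn, "glomerulus")
  for (k in 1:2) {
    odors <- names(clusters)[clusters == k]
    expected <- unname(glom[rowMeans(unclass(pn)[, odors]) >= 30])
    expect_setequal(sig[[paste0("cluster", k)]], expected)
  }
  zero <- new_response_matrix(matrix(0, 3, 4,
                                     dimnames = list(paste0("g", 1:3),
                                                     paste0("o", 1:4))))
  sig0 <- cluster_signature_glomeruli(zero, setNames(c(1, 1, 2, 2),
                                                     paste0("o", 1:4)), 30)
  expect_true(all(lengths(sig0) == 0))
  pos <- new_response_matrix(matrix(1, 3, 4,
                                    dimnames = dimnames(unclass(zero))))
  sigp <- cluster_signature_glomeruli(pos, setNames(c(1, 1, 2, 2),
                                                    paste0("o", 1:4)), 0)
  expect_true(all(lengths(sigp) == 3))
})

test_that("PCA: rank-1 limit, two-route eigenvalue check, centering", {
  # rank-1 input: PC1 carries everything
  u <- outer(1:5, c(2, 1, 3, 0.5))
  dimnames(u) <- list(paste0("c", 1:5), paste0("o", 1:4))
  p1 <- odor_pca(u, items = "odors")
  expect_equal(p1$explained_variance_fraction[1], 1)
  # eigenvalues equal squared singular values/(n-1): cross-check against an
  # independent covariance eigendecomposition
  st <- tiny_trains(seed = 44)
  pn <- build_response_matrix(st, "first_round")
  p <- odor_pca(pn, items = "odors")
  x <- t(unclass(pn))
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10]
  frac <- ev / sum(ev)
  k <- seq_along(frac)
  expect_equal(p$explained_variance_fraction[k], frac, tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance_fraction) <= 1e-12))
  expect_equal(sum(p$explained_variance_fraction), 1, tolerance = 1e-9)
  # adding a constant to one feature column changes nothing (centering)
  x2 <- x; x2[, 3] <- x2[, 3] + 100
  p2 <- odor_pca(x2, items = "rows")
  expect_equal(p2$explained_variance_fraction,
               p$explained_variance_fraction, tolerance = 1e-9)
})

test_that("ANOSIM: extremes, oracle agreement, rank invariance", {
  # perfectly separated groups -> R = 1
  m <- cbind(matrix(abs(rnorm(20, 1, 0.01)), 4),
             matrix(abs(rnorm(20, 100, 0.01)), 4))
  dimnames(m) <- list(paste0("c", 1:4), paste0("o", 1:10))
  g <- rep(c("A", "B"), each = 5)
  fit <- anosim_odors(new_response_matrix(m), g, n_perm = 99, seed = 1)
  expect_equal(fit$statistic, 1, tolerance = 1e-9)
  expect_lte(fit$p, 0.05)  # permutation minimum, up to label-swap ties
  # R statistic equals a from-scratch rank computation on a shared distance
  st <- tiny_trains(seed = 45)
  pn <- build_response_matrix(st, "first_round")
  D <- odor_distance_matrix(pn, "euclidean")
  gv <- attr(st, "panel")$valence
  fit2 <- anosim_odors(D, gv, n_perm = 99, seed = 1)
  expect_equal(fit2$statistic, anosim_oracle_R(unclass(D), gv),
               tolerance = 1e-12)
  # rank-based: invariant under monotone transforms of the distances
  D2 <- olfmap:::new_distance_matrix(sqrt(unclass(D)), "euclidean")
  fit3 <- anosim_odors(D2, gv, n_perm = 99, seed = 1)
  expect_equal(fit3$statistic, fit2$statistic, tolerance = 1e-12)
  expect_true(fit2$statistic >= -1 && fit2$statistic <= 1)
  expect_error(anosim_odors(D, c("A", rep("B", length(gv) - 1))), "groups")
})

test_that("matrix correlation: identity, shuffle control, label checks", {
  st <- tiny_trains(seed = 46)
  pn <- build_response_matrix(st, "first_round")
  D <- odor_distance_matrix(pn, "cosine")
  mc <- matrix_correlation(D, D)
  expect_equal(mc$r, 1)
  expect_equal(mc$n_pairs, choose(ncol(pn), 2))
  # label-shuffled copies decorrelate on average
  mc2 <- matrix_correlation(D, D, n_runs = 100, seed = 2)
  expect_lt(abs(mc2$shuffle_mean), 3 * mc2$shuffle_sd / sqrt(100) + 0.1)
  # independent random distance matrices are uncorrelated in >= 90% of seeds
  ps <- sapply(1:20, function(s) {
    set.seed(s)
    mk <- function() {
      x <- matrix(rnorm(60), 10)
      rownames(x) <- paste0("i", 1:10)
      olfmap:::new_distance_matrix(as.matrix(dist(x)), "euclidean")
    }
    matrix_correlation(mk(), mk())$p
  })
  expect_gte(mean(ps > 0.05), 0.9)
  bad <- unclass(D)[1:5, 1:5]
  expect_error(matrix_correlation(D, olfmap:::new_distance_matrix(
    bad, "cosine")), "label set")
})
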