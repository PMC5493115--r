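new_distance_matrix <- function(values, metric) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)))
  values[abs(values) < 1e-15] <- 0
  if (max(abs(values - t(values))) > 1e-10)
    stop("distance matrix must be symmetric", call. = FALSE)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (any(values < 0)) stop("negative distances", call. = FALSE)
  structure(values, metric = metric,
            class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix, %d items\n", attr(x, "metric"), nrow(x)))
  print(round(unclass(x)[seq_len(min(6, nrow(x))),
                         seq_len(min(6, ncol(x))), drop = FALSE], 3))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Pairwise odor distances in neural response space
#'
#' Treats each odor as a vector of class responses (one matrix column) and
#' computes pairwise distances: cosine (\eqn{1 - u\cdot v/(\|u\|\|v\|)},
#' amplitude-insensitive), Euclidean (amplitude-sensitive), or correlation
#' (\eqn{1 - } Pearson r). Zero-norm (or zero-variance, for correlation)
#' vectors make the distance undefined; those pairs are set to 1 with a
#' warning.
#'
#' @param matrix a \code{response_matrix} or plain class x odor matrix.
#' @param metric \code{"cosine"}, \code{"euclidean"}, or
#'   \code{"correlation"}.
#' @param rectify set negative responses to zero first (default FALSE; the
#'   response matrix keeps negative control-subtracted values unless an
#'   analysis rectifies explicitly).
#' @return A \code{distance_matrix} over odors.
#' @export
odor_distance_matrix <- function(matrix,
                                 metric = c("cosine", "euclidean",
                                            "correlation"),
                                 rectify = FALSE) {
  metric <- match.arg(metric)
  m <- unclass(matrix)
  if (ncol(m) < 2) stop("need at least 2 odors", call. = FALSE)
  if (rectify) m <- pmax(m, 0)
  v <- t(m)                                # odors in rows
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(v)),
    cosine = {
      nrm <- sqrt(rowSums(v^2))
      bad <- nrm == 0
      if (any(bad)) {
        warning(sum(bad), " zero-norm odor vectors; cosine distance set to 1",
                call. = FALSE)
        nrm[bad] <- 1
      }
      u <- v / nrm
      d <- 1 - tcrossprod(u)
      d[bad, ] <- 1; d[, bad] <- 1; diag(d) <- 0
      d
    },
    correlation = {
      sds <- apply(v, 1, stats::sd)
      bad <- sds == 0
      if (any(bad))
        warning(sum(bad),
                " zero-variance odor vectors; correlation distance set to 1",
                call. = FALSE)
      vc <- v
      vc[bad, ] <- seq_len(ncol(v))        # placeholder, overwritten below
      d <- 1 - stats::cor(t(vc))
      d[bad, ] <- 1; d[, bad] <- 1; diag(d) <- 0
      d
    })
  dimnames(d) <- list(rownames(v), rownames(v))
  new_distance_matrix(pmax(d, 0), metric = metric)
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Ward linkage applied to the supplied distances via the Lance-Williams
#' recurrence (\code{stats::hclust}, method \code{"ward.D2"}; for two
#' singletons the merge height equals their distance). Using Ward on
#' non-Euclidean cosine/correlation distances follows common practice in the
#' numerical tooling this analysis style comes from, and is a documented
#' deviation from Ward's Euclidean derivation.
#'
#' @param D a \code{distance_matrix}.
#' @return An \code{hclust} object.
#' @export
hierarchical_cluster <- function(D) {
  stopifnot(inherits(D, "distance_matrix"))
  stats::hclust(stats::as.dist(unclass(D)), method = "ward.D2")
}

#' Cut a dendrogram at a fixed linkage distance
#'
#' @param dend an \code{hclust} object.
#' @param threshold cut height; with \code{mode = "fraction_of_max"} it is
#'   interpreted as a fraction of the maximum linkage distance (e.g. 0.7).
#' @param mode \code{"absolute"} or \code{"fraction_of_max"}.
#' @return Named integer vector of cluster labels (connected components below
#'   the cut).
#' @export
cut_dendrogram <- function(dend, threshold = 0.6,
                           mode = c("absolute", "fraction_of_max")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  h <- if (mode == "absolute") threshold else threshold * max(dend$height)
  stats::cutree(dend, h = h)
}

#' Cluster-signature glomeruli
#'
#' For each odor cluster, averages the response intensities over the
#' cluster's odors and extracts the glomeruli (rows) whose mean response
#' meets the rate threshold — the glomeruli that mainly carry that cluster's
#' representation.
#'
#' @param matrix a \code{response_matrix}.
#' @param clusters named integer vector (odor id -> cluster), e.g. from
#'   [cut_dendrogram()].
#' @param rate_threshold mean spikes/s threshold (default 30).
#' @return Named list (cluster id) of character vectors of glomerulus labels.
#' @export
cluster_signature_glomeruli <- function(matrix, clusters,
                                        rate_threshold = 30) {
  m <- unclass(matrix)
  stopifnot(all(names(clusters) %in% colnames(m)))
  glom <- attr(matrix, "glomerulus") %||% rownames(m)
  out <- lapply(sort(unique(clusters)), function(k) {
    odors <- names(clusters)[clusters == k]
    mu <- rowMeans(m[, odors, drop = FALSE])
    unname(glom[mu >= rate_threshold])
  })
  names(out) <- paste0("cluster", sort(unique(clusters)))
  out
}

#' PCA of the odor (or time-point) representation
#'
#' Column-mean-centered, unscaled principal component analysis via singular
#' value decomposition of the items x features matrix (odors as items,
#' classes as features, by default).
#'
#' @param matrix a \code{response_matrix} (items are its columns when
#'   \code{items = "odors"}) or a plain items x features matrix.
#' @param items \code{"odors"} (transpose the class x odor matrix) or
#'   \code{"rows"} (use rows as items as-is).
#' @param scale. standardize features before PCA (default FALSE: variance
#'   fractions are reported on the raw scale).
#' @return List of class \code{odor_pca}: \code{scores}, \code{loadings},
#'   \code{explained_variance_fraction}.
#' @export
odor_pca <- function(matrix, items = c("odors", "rows"), scale. = FALSE) {
  items <- match.arg(items)
  x <- unclass(matrix)
  if (items == "odors") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 items", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- p$sdev^2
  structure(list(scores = p$x, loadings = p$rotation,
                 explained_variance_fraction = ev / sum(ev)),
            class = "odor_pca")
}

#' @export
print.odor_pca <- function(x, ...) {
  f <- x$explained_variance_fraction
  k <- seq_len(min(3, length(f)))
  cat("PCA:", nrow(x$scores), "items;",
      paste0("PC", k, " ", sprintf("%.1f%%", 100 * f[k]), collapse = ", "),
      "\n")
  invisible(x)
}

#' One-way ANOSIM on odor representations
#'
#' Analysis of similarities: a rank-based permutation test of whether
#' between-group distances exceed within-group distances,
#' \eqn{R = (\bar{r}_B - \bar{r}_W) / (M/2)} with \eqn{M = n(n-1)/2}. Given a
#' raw response matrix, odors are the items and Bray-Curtis dissimilarity is
#' computed on rectified intensities (Bray-Curtis requires non-negative
#' data); a precomputed \code{distance_matrix} is used as-is. The permutation
#' p-value uses the add-one estimator. Computation is delegated to
#' \code{vegan::anosim}.
#'
#' @param x a \code{response_matrix} (class x odor) or a
#'   \code{distance_matrix} over odors.
#' @param group_labels factor-like vector of group labels, one per odor (in
#'   column/label order), e.g. valence.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return List: \code{statistic} (R), \code{p}, \code{n_perm},
#'   \code{groups}.
#' @export
anosim_odors <- function(x, group_labels, n_perm = 10000, seed = 1) {
  g <- as.factor(group_labels)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  d <- if (inherits(x, "distance_matrix")) {
    stats::as.dist(unclass(x))
  } else {
    v <- t(pmax(unclass(x), 0))            # odors as items, rectified
    vegan::vegdist(v, method = "bray")
  }
  if (length(g) != attr(d, "Size"))
    stop("group_labels length must match the number of items", call. = FALSE)
  fit <- with_seed(seed, vegan::anosim(d, g, permutations = n_perm))
  list(statistic = unname(fit$statistic), p = fit$signif, n_perm = n_perm,
       groups = levels(g))
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over the upper-triangle pairs of two distance matrices
#' on the same label set, with a parametric t-test p-value (df = number of
#' pairs - 2). Optionally a label-shuffle control: the labels of the second
#' matrix are permuted \code{n_runs} times and the mean and s.d. of the
#' shuffled correlations reported.
#'
#' @param D1,D2 \code{distance_matrix} objects with identical label sets.
#' @param n_runs optional number of shuffle runs (0 = no control).
#' @param seed integer seed for the shuffle control.
#' @return List: \code{r}, \code{p}, \code{n_pairs}; with control also
#'   \code{shuffle_mean}, \code{shuffle_sd}, \code{n_runs}.
#' @export
matrix_correlation <- function(D1, D2, n_runs = 0, seed = 1) {
  stopifnot(inherits(D1, "distance_matrix"), inherits(D2, "distance_matrix"))
  l1 <- rownames(D1); l2 <- rownames(D2)
  if (!setequal(l1, l2))
    stop("distance matrices must share the same label set", call. = FALSE)
  m2 <- unclass(D2)[l1, l1]
  m1 <- unclass(D1)
  ut <- upper.tri(m1)
  ct <- stats::cor.test(m1[ut], m2[ut])
  out <- list(r = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ut))
  if (n_runs > 0) {
    rs <- with_seed(seed, vapply(seq_len(n_runs), function(i) {
      perm <- sample(l1)
      mp <- m2[perm, perm]
      stats::cor(m1[ut], mp[ut])
    }, numeric(1)))
    out$shuffle_mean <- mean(rs)
    out$shuffle_sd <- stats::sd(rs)
    out$n_runs <- n_runs
  }
  out
}
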