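# Shared fixtures and small independent oracles for the test suite.

tiny_panel <- function(seed = 1) generate_panel(3, 3, seed = seed)

tiny_model <- function(seed = 1, n_classes = 6, gain = 10, trial_sd = 1) {
  generate_model(tiny_panel(seed), n_classes = n_classes, n_groups = 2,
                 within_group_gain = gain, trial_sd = trial_sd, seed = seed)
}

tiny_trains <- function(seed = 1, n_trials = 2, n_sisters = 2, ...) {
  suppressWarnings(simulate_spike_trains(tiny_model(seed, ...),
                                         n_trials = n_trials,
                                         n_sisters_per_class = n_sisters,
                                         seed = seed))
}

# adjusted Rand index between two labelings (independent of the package)
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force lifetime sparseness, straight from the formula
sparseness_oracle <- function(r, n = length(r)) {
  r <- ifelse(r < 0, 0, r)
  (1 / (1 - 1 / n)) * (1 - (sum(r) / n)^2 / (sum(r^2) / n))
}

# brute-force pairwise distance loop
distance_oracle <- function(m, metric) {
  # m: class x odor; items are odors
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- m[, i]; v <- m[, j]
    d[i, j] <- switch(metric,
      euclidean = sqrt(sum((u - v)^2)),
      cosine = 1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2))),
      correlation = 1 - stats::cor(u, v))
  }
  d
}

# rank-based ANOSIM statistic computed from first principles
anosim_oracle_R <- function(d, groups) {
  dm <- as.matrix(d)
  ut <- upper.tri(dm)
  rk <- rank(dm[ut])
  same <- outer(groups, groups, `==`)[ut]
  M <- sum(ut)
  (mean(rk[!same]) - mean(rk[same])) / (M / 2)
}

# a small deterministic skeleton: straight 10-um segment split in two edges
straight_skeleton <- function() {
  olfmap:::new_skeleton(data.frame(
    id = 1:3, type = 2L,
    x = c(0, 5, 10), y = c(0, 0, 0), z = c(0, 0, 0),
    radius = 1, parent = c(-1L, 1L, 2L)))
}

small_grid <- function(n = 21, vs = 1) grid_spec(c(0, 0, 0), rep(n, 3), vs)

delta_map <- function(n = 21, at = (n + 1) / 2, mass = 1) {
  a <- array(0, dim = rep(n, 3))
  a[at, at, at] <- mass
  olfmap:::new_voxel_map(a, small_grid(n))
}
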