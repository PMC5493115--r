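#' Generate a ground-truth tuning model with planted odor/glomerulus groups
#'
#' Creates the synthetic population used by the whole pipeline: each neuron
#' class innervates one glomerulus, each glomerulus belongs to one planted
#' group, and each odor belongs to one planted group. A class responds to
#' every odor with a small baseline tuning drawn at random, amplified by
#' \code{within_group_gain} for odors of its own group. Groups are
#' valence-pure: the planted groups partition the attractive odors and the
#' aversive odors separately (proportionally to the valence split), so the
#' planted cluster structure carries a valence signal, mirroring the
#' observation that attractive and aversive odors engage different clusters
#' of glomeruli.
#'
#' @param panel an \code{odor_panel} from [generate_panel()].
#' @param n_classes number of neuron classes (one glomerulus each).
#' @param n_groups number of planted groups (must be \code{<= n_classes} and
#'   at least 2 so both valences are covered).
#' @param within_group_gain multiplicative gain (> 1 plants structure;
#'   1 means no structure).
#' @param trial_sd additive trial-to-trial s.d. of the response amplitude,
#'   spikes/s.
#' @param baseline_rate spontaneous firing rate, spikes/s.
#' @param onset_peak_time time of the onset transient peak, seconds after
#'   stimulus onset (default 0.15 s).
#' @param seed integer seed.
#'
#' @return A list of class \code{ground_truth_model} with elements
#'   \code{class_ids}, \code{glomerulus_of_class}, \code{group_of_glomerulus},
#'   \code{group_of_odor}, \code{mean_rate} (class x odor, spikes/s),
#'   \code{trial_sd}, \code{baseline_rate}, \code{onset_peak_time},
#'   \code{panel}.
#' @export
#' @examples
#' panel <- generate_panel(8, 9, seed = 1)
#' m <- generate_model(panel, n_classes = 31, seed = 1)
#' dim(m$mean_rate)
generate_model <- function(panel, n_classes = 31, n_groups = 3,
                           within_group_gain = 10, trial_sd = 3,
                           baseline_rate = 5, onset_peak_time = 0.15,
                           seed = 1) {
  validate_panel(panel)
  if (n_groups > n_classes || n_groups < 1)
    stop("n_groups must be between 1 and n_classes", call. = FALSE)
  n_odors <- nrow(panel)
  if (n_groups > n_odors)
    stop("n_groups must not exceed the number of odors", call. = FALSE)
  with_seed(seed, {
    class_ids <- sprintf("PN%02d", seq_len(n_classes))
    glomeruli <- sprintf("G%02d", seq_len(n_classes))
    names(glomeruli) <- class_ids

    group_of_odor <- plant_odor_groups(panel, n_groups)
    # classes spread across the groups as evenly as possible
    group_of_class <- rep(seq_len(n_groups), length.out = n_classes)
    group_of_glom <- stats::setNames(group_of_class, glomeruli)

    base <- matrix(stats::runif(n_classes * n_odors, 0, 10),
                   nrow = n_classes,
                   dimnames = list(class_ids, panel$odor_id))
    gain <- matrix(1, n_classes, n_odors)
    for (i in seq_len(n_classes))
      gain[i, group_of_odor == group_of_class[i]] <- within_group_gain
    mean_rate <- base * gain

    structure(list(
      class_ids = class_ids,
      glomerulus_of_class = glomeruli,
      group_of_glomerulus = group_of_glom,
      group_of_odor = group_of_odor,
      mean_rate = mean_rate,
      trial_sd = trial_sd,
      baseline_rate = baseline_rate,
      onset_peak_time = onset_peak_time,
      panel = panel
    ), class = "ground_truth_model")
  })
}

# Partition odors into valence-pure planted groups. Group counts per valence
# are proportional to the valence split (at least one each when n_groups >= 2).
plant_odor_groups <- function(panel, n_groups) {
  n <- nrow(panel)
  if (n_groups == 1)
    return(stats::setNames(rep(1L, n), panel$odor_id))
  attr_idx <- which(panel$valence == "attractive")
  aver_idx <- which(panel$valence == "aversive")
  k_attr <- round(n_groups * length(attr_idx) / n)
  k_attr <- max(min(k_attr, n_groups - (length(aver_idx) > 0)),
                as.integer(length(attr_idx) > 0))
  k_aver <- n_groups - k_attr
  grp <- integer(n)
  if (length(attr_idx))
    grp[attr_idx] <- rep(seq_len(max(k_attr, 1L)), length.out = length(attr_idx))
  if (length(aver_idx))
    grp[aver_idx] <- k_attr +
      rep(seq_len(max(k_aver, 1L)), length.out = length(aver_idx))
  stats::setNames(grp, panel$odor_id)
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat("Ground-truth tuning model:",
      length(x$class_ids), "classes x", ncol(x$mean_rate), "odors;",
      max(x$group_of_odor), "planted groups\n")
  cat("baseline", x$baseline_rate, "spikes/s; trial sd", x$trial_sd,
      "spikes/s; onset peak", x$onset_peak_time, "s\n")
  invisible(x)
}

#' Generate a glomerulus atlas with tunable spatial clustering
#'
#' Places one 3D centroid (micrometres) per glomerulus inside the antennal-lobe
#' bounding box. At \code{spatial_clustering = 1} centroids of glomeruli in
#' the same planted group are drawn tightly around a common group center; at 0
#' they are uniform in the box. Intermediate values interpolate linearly
#' between the group center and an independent uniform draw, emulating the
#' observation that neighboring glomeruli tend to share odor response
#' properties.
#'
#' @param model a \code{ground_truth_model}.
#' @param spatial_clustering real in \code{[0, 1]}.
#' @param seed integer seed.
#' @param box antennal-lobe bounding box (3x2 matrix of min/max, micrometres).
#' @return A data.frame of class \code{glomerulus_atlas} with columns
#'   \code{glomerulus_id}, \code{x}, \code{y}, \code{z}, \code{group}.
#' @export
generate_atlas <- function(model, spatial_clustering = 1, seed = 1,
                           box = cbind(min = c(0, 0, 0),
                                       max = c(100, 100, 50))) {
  stopifnot(inherits(model, "ground_truth_model"),
            spatial_clustering >= 0, spatial_clustering <= 1)
  gloms <- names(model$group_of_glomerulus)
  groups <- model$group_of_glomerulus
  n_groups <- max(groups)
  with_seed(seed, {
    span <- box[, "max"] - box[, "min"]
    centers <- matrix(stats::runif(3 * n_groups), ncol = 3)
    # keep group centers off the walls so jitter stays inside
    centers <- sweep(sweep(centers * 0.6 + 0.2, 2, span, `*`),
                     2, box[, "min"], `+`)
    uni <- matrix(stats::runif(3 * length(gloms)), ncol = 3)
    uni <- sweep(sweep(uni, 2, span, `*`), 2, box[, "min"], `+`)
    jitter_sd <- 0.03 * min(span)
    pos <- spatial_clustering * centers[groups, , drop = FALSE] +
      (1 - spatial_clustering) * uni +
      matrix(stats::rnorm(3 * length(gloms), 0, jitter_sd), ncol = 3)
    atlas <- data.frame(glomerulus_id = gloms,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        group = as.integer(groups),
                        stringsAsFactors = FALSE)
    class(atlas) <- c("glomerulus_atlas", "data.frame")
    atlas
  })
}

#' Pairwise anatomical distances between glomerulus centroids
#'
#' Euclidean distances between atlas centroids, returned as a symmetric
#' labelled matrix compatible with [matrix_correlation()].
#'
#' @param atlas a \code{glomerulus_atlas}.
#' @return A \code{distance_matrix} (metric \code{"euclidean"}).
#' @export
atlas_distances <- function(atlas) {
  stopifnot(inherits(atlas, "glomerulus_atlas"))
  m <- as.matrix(stats::dist(as.matrix(atlas[, c("x", "y", "z")])))
  dimnames(m) <- list(atlas$glomerulus_id, atlas$glomerulus_id)
  new_distance_matrix(m, metric = "euclidean")
}
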