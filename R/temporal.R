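#' Population PC-space trajectories per odor
#'
#' Fits one PCA on the pooled (time x odor) x class observations of a
#' population rate tensor (each time bin of each odor is an observation, the
#' class rates its coordinates), then returns each odor's path through the
#' shared PC space.
#'
#' @param tensor a \code{population_tensor} from [psth()].
#' @param n_components number of components to keep (default 3); must not
#'   exceed the number of classes.
#' @return List: \code{paths} (named list, odor -> time x component score
#'   matrix), \code{pca} (the shared \code{odor_pca} basis), \code{time}.
#' @export
trajectories <- function(tensor, n_components = 3) {
  stopifnot(inherits(tensor, "population_tensor"))
  d <- dim(tensor)                          # time x class x odor
  if (n_components > d[2])
    stop("more components than classes", call. = FALSE)
  # pooled observations: rows = (time, odor), cols = classes
  x <- matrix(aperm(unclass(tensor), c(1, 3, 2)), d[1] * d[3], d[2])
  colnames(x) <- dimnames(tensor)[[2]]
  p <- odor_pca(x, items = "rows")
  sc <- p$scores[, seq_len(n_components), drop = FALSE]
  odors <- dimnames(tensor)[[3]]
  paths <- lapply(seq_along(odors), function(k)
    sc[(k - 1L) * d[1] + seq_len(d[1]), , drop = FALSE])
  names(paths) <- odors
  list(paths = paths, pca = p, time = attr(tensor, "time"))
}

#' Mean inter-odor population distance over time
#'
#' For each time bin, the mean over odor pairs of the Euclidean distance
#' between class rate vectors, plus the location of the separation peak
#' (earliest bin on ties).
#'
#' @param tensor a \code{population_tensor}.
#' @return List: \code{time} (bin left edges), \code{distance},
#'   \code{peak_time}, \code{peak_index}.
#' @export
inter_odor_distance_timecourse <- function(tensor) {
  stopifnot(inherits(tensor, "population_tensor"))
  d <- dim(tensor)
  if (d[3] < 2) stop("need >= 2 odors", call. = FALSE)
  dist_t <- vapply(seq_len(d[1]), function(t) {
    m <- matrix(unclass(tensor)[t, , ], d[2], d[3])
    mean(stats::dist(t(m)))
  }, numeric(1))
  tm <- attr(tensor, "time")
  peak <- which.max(dist_t)                 # which.max takes the earliest tie
  list(time = tm, distance = dist_t,
       peak_time = tm[peak], peak_index = peak)
}

#' Odor distance matrices at selected time points
#'
#' One odor x odor distance matrix per requested time, computed from the
#' population tensor slice whose bin contains that time (reusing the static
#' odor-space distance code).
#'
#' @param tensor a \code{population_tensor}.
#' @param times numeric vector of times (seconds); each must lie within the
#'   tensor span.
#' @param metric distance metric, as in [odor_distance_matrix()].
#' @return Named list of \code{distance_matrix} objects.
#' @export
time_resolved_distance_matrices <- function(tensor, times,
                                            metric = c("cosine", "euclidean",
                                                       "correlation")) {
  metric <- match.arg(metric)
  stopifnot(inherits(tensor, "population_tensor"))
  tm <- attr(tensor, "time")
  bw <- attr(tensor, "bin_width")
  out <- lapply(times, function(t0) {
    if (t0 < tm[1] || t0 >= tm[length(tm)] + bw)
      stop(sprintf("time %.3f s outside tensor span", t0), call. = FALSE)
    i <- findInterval(t0, tm)
    m <- matrix(unclass(tensor)[i, , ], dim(tensor)[2], dim(tensor)[3],
                dimnames = dimnames(tensor)[2:3])
    suppressWarnings(odor_distance_matrix(m, metric))
  })
  names(out) <- sprintf("t=%gs", times)
  out
}

#' Average a population tensor over the stimulus response window
#'
#' Mean rate per class and odor over all bins inside \code{window}; the
#' resulting class x odor matrix feeds the static odor-space analyses and, by
#' construction, gives distances identical to time-resolved distances of the
#' window-averaged tensor.
#'
#' @param tensor a \code{population_tensor}.
#' @param window length-2 numeric, seconds (default \code{c(0.05, 1.05)}).
#' @return A plain class x odor matrix of mean rates.
#' @export
window_mean_matrix <- function(tensor, window = c(0.05, 1.05)) {
  stopifnot(inherits(tensor, "population_tensor"))
  tm <- attr(tensor, "time")
  bw <- attr(tensor, "bin_width")
  keep <- tm + bw / 2 >= window[1] & tm + bw / 2 < window[2]
  if (!any(keep)) stop("window contains no bins", call. = FALSE)
  apply(unclass(tensor)[keep, , , drop = FALSE], c(2, 3), mean)
}
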