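#' Reconstruct a virtual odor activity map from density maps and responses
#'
#' For one odor, every class's rectified response intensity (negative values
#' set to zero) is multiplied by the class's axonal density map and the
#' products summed over classes — a virtual activity map of the odor in the
#' region. Classes present in the response matrix but without a density map
#' are skipped and recorded (mirroring partial morphological coverage);
#' classes with a density map but no response row are an error.
#'
#' @param density named list (class id) of density \code{voxel_map}s on one
#'   shared grid.
#' @param responses a \code{response_matrix} with rows covering the density
#'   classes.
#' @param odor_id odor column to reconstruct.
#' @return A \code{voxel_map} of kind \code{"functional"} with attributes
#'   \code{contributing_classes} and \code{skipped_classes}.
#' @export
functional_map <- function(density, responses, odor_id) {
  stopifnot(length(density) >= 1, !is.null(names(density)))
  m <- unclass(responses)
  if (!odor_id %in% colnames(m))
    stop("unknown odor: ", odor_id, call. = FALSE)
  no_resp <- setdiff(names(density), rownames(m))
  if (length(no_resp))
    stop("density classes without a response row: ",
         paste(no_resp, collapse = ", "), call. = FALSE)
  skipped <- setdiff(rownames(m), names(density))
  g0 <- density[[1]]$grid
  acc <- array(0, dim = g0$dim)
  for (cl in names(density)) {
    if (!identical(density[[cl]]$grid, g0))
      stop("all density maps must share one grid", call. = FALSE)
    w <- max(m[cl, odor_id], 0)
    if (w > 0) acc <- acc + w * density[[cl]]$values
  }
  fm <- new_voxel_map(acc, g0, kind = "functional", label = odor_id)
  attr(fm, "contributing_classes") <- names(density)
  attr(fm, "skipped_classes") <- skipped
  fm
}

#' Cluster odors by functional-map similarity
#'
#' Correlation distance between flattened functional maps, Ward clustering,
#' and a cut at a fixed linkage distance (default 0.6).
#'
#' @param maps named list (odor id) of functional \code{voxel_map}s on one
#'   shared grid.
#' @param cut linkage-distance cut (default 0.6).
#' @param mode cut mode, as in [cut_dendrogram()].
#' @return List: \code{distances}, \code{dendrogram}, \code{clusters}.
#' @export
functional_map_clustering <- function(maps, cut = 0.6,
                                      mode = c("absolute",
                                               "fraction_of_max")) {
  mode <- match.arg(mode)
  sim <- density_map_similarity(maps)
  sim$clusters <- cut_dendrogram(sim$dendrogram, cut, mode)
  sim
}

#' Regional mass fractions of a functional map
#'
#' Fraction of the map's total mass inside each named boolean region mask.
#' Masks forming a partition give fractions summing to 1.
#'
#' @param map a \code{voxel_map}.
#' @param region_masks named list of logical arrays with the map's dimensions.
#' @return Named numeric vector of mass fractions.
#' @export
regional_summary <- function(map, region_masks) {
  stopifnot(inherits(map, "voxel_map"), length(region_masks) >= 1)
  total <- sum(map$values)
  if (total <= 0)
    stop("regional fractions undefined for a zero-mass map", call. = FALSE)
  vapply(region_masks, function(msk) {
    stopifnot(identical(dim(msk), dim(map$values)))
    sum(map$values[msk]) / total
  }, numeric(1))
}

#' Dorsal/ventral half-space masks for a region grid
#'
#' Splits the grid into two halves along the third (ventral-to-dorsal) axis.
#'
#' @param grid a \code{grid_spec}.
#' @return List with logical arrays \code{ventral} and \code{dorsal}.
#' @export
dorsoventral_masks <- function(grid) {
  k <- array(rep(seq_len(grid$dim[3]), each = grid$dim[1] * grid$dim[2]),
             dim = grid$dim)
  half <- grid$dim[3] / 2
  list(ventral = k <= half, dorsal = k > half)
}
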