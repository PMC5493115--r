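#' Define a voxel grid
#'
#' @param origin 3-vector, world coordinates (micrometres) of the grid corner.
#' @param dim integer 3-vector, number of voxels per axis; default the
#'   template grid 135 x 135 x 105.
#' @param voxel_size isotropic voxel edge length, micrometres (default 1).
#' @return A \code{grid_spec} list.
#' @export
grid_spec <- function(origin = c(0, 0, 0), dim = c(135, 135, 105),
                      voxel_size = 1) {
  stopifnot(length(origin) == 3, length(dim) == 3, all(dim > 0),
            voxel_size > 0)
  structure(list(origin = as.numeric(origin), dim = as.integer(dim),
                 voxel_size = voxel_size),
            class = "grid_spec")
}

#' Grid covering one higher-brain-center region
#'
#' A voxel grid snapped to the region bounding box plus a margin (so boxcar
#' smoothing does not push mass off the grid edge).
#'
#' @param region \code{"calyx"} or \code{"LH"}.
#' @param margin margin in micrometres added on every side (default 6).
#' @param voxel_size voxel edge length, micrometres.
#' @return A \code{grid_spec}.
#' @export
region_grid <- function(region = c("calyx", "LH"), margin = 6,
                        voxel_size = 1) {
  region <- match.arg(region)
  box <- region_box(region)
  origin <- box[, "min"] - margin
  dims <- ceiling((box[, "max"] - box[, "min"] + 2 * margin) / voxel_size)
  grid_spec(origin, dims, voxel_size)
}

new_voxel_map <- function(values, grid, kind = "density", label = NULL) {
  stopifnot(inherits(grid, "grid_spec"),
            identical(dim(values), as.integer(grid$dim)))
  structure(list(values = values, grid = grid, kind = kind, label = label),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("%s voxel map%s: %d x %d x %d @ %g um, total mass %.4g\n",
              x$kind,
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              x$grid$voxel_size, sum(x$values)))
  invisible(x)
}

#' Resample a skeleton into equal-length segment midpoints
#'
#' Subdivides every parent-child edge into \code{ceiling(len/step)} segments
#' of equal length (each at most \code{step}) and returns the segment
#' midpoints. The midpoints are the unit of mass for voxel density maps; the
#' total polyline length is preserved by construction. Zero-length edges are
#' skipped.
#'
#' @param skeleton a \code{neuron_skeleton}.
#' @param step target segment length, micrometres (default 0.5).
#' @return Numeric matrix of midpoints (n x 3).
#' @export
resample_skeleton <- function(skeleton, step = 0.5) {
  stopifnot(inherits(skeleton, "neuron_skeleton"), step > 0)
  xyz <- as.matrix(skeleton[, c("x", "y", "z")])
  child <- which(skeleton$parent != -1L)
  par <- match(skeleton$parent[child], skeleton$id)
  a <- xyz[par, , drop = FALSE]
  b <- xyz[child, , drop = FALSE]
  len <- sqrt(rowSums((b - a)^2))
  keep <- len > 0
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  nseg <- pmax(1L, as.integer(ceiling(len[keep] / step)))
  if (!length(nseg)) return(matrix(numeric(0), 0, 3))
  edge <- rep.int(seq_along(nseg), nseg)
  i <- sequence(nseg)
  t_mid <- (i - 0.5) / nseg[edge]
  a[edge, , drop = FALSE] + (b - a)[edge, , drop = FALSE] * t_mid
}

#' Bin points onto a voxel grid
#'
#' Each in-bounds point increments its containing voxel, using floor binning
#' with half-open voxel intervals (\code{floor((p - origin)/voxel_size)},
#' 0-based). Out-of-bounds points are counted and reported as an attribute,
#' not an error.
#'
#' @param points n x 3 matrix of world coordinates (micrometres).
#' @param grid a \code{grid_spec}.
#' @param label optional map label.
#' @return A \code{voxel_map} (kind \code{"density"}, unsmoothed) with
#'   attribute \code{n_out_of_bounds}.
#' @export
voxelize <- function(points, grid, label = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  points <- matrix(as.numeric(points), ncol = 3)
  idx <- floor(sweep(points, 2, grid$origin, `-`) / grid$voxel_size)
  inb <- idx[, 1] >= 0 & idx[, 1] < grid$dim[1] &
         idx[, 2] >= 0 & idx[, 2] < grid$dim[2] &
         idx[, 3] >= 0 & idx[, 3] < grid$dim[3]
  n_oob <- sum(!inb)
  if (n_oob) idx <- idx[inb, , drop = FALSE]
  lin <- idx[, 1] + grid$dim[1] * (idx[, 2] + grid$dim[2] * idx[, 3]) + 1
  arr <- array(tabulate(lin, nbins = prod(grid$dim)), dim = grid$dim)
  vm <- new_voxel_map(arr, grid, kind = "density", label = label)
  attr(vm, "n_out_of_bounds") <- n_oob
  vm
}

## zero-padded centered running mean of width w along the rows of a matrix
running_mean_rows <- function(m, w) {
  h <- (w - 1L) %/% 2L
  n <- nrow(m)
  pad <- matrix(0, h, ncol(m))
  f <- stats::filter(rbind(pad, m, pad), rep(1 / w, w), sides = 2)
  matrix(f[(h + 1L):(h + n), ], n, ncol(m))
}

#' Boxcar-smooth a voxel map
#'
#' Convolution with a normalized \code{width^3} uniform kernel (separable
#' running means along the three axes), zero-padded at the boundaries: mass
#' strictly in the interior is conserved, mass within \code{(width-1)/2}
#' voxels of an edge is attenuated.
#'
#' @param map a \code{voxel_map}.
#' @param width_voxels odd kernel width (default 9, i.e. a 9 x 9 x 9 kernel).
#' @return A smoothed \code{voxel_map}.
#' @export
boxcar_smooth <- function(map, width_voxels = 9) {
  stopifnot(inherits(map, "voxel_map"))
  w <- as.integer(width_voxels)
  if (w < 1 || w %% 2L == 0L)
    stop("width_voxels must be odd and positive", call. = FALSE)
  if (w == 1L) return(map)
  a <- map$values
  d <- dim(a)
  # axis 1
  a <- array(running_mean_rows(matrix(a, d[1], d[2] * d[3]), w), d)
  # axis 2
  a <- aperm(a, c(2, 1, 3))
  a <- array(running_mean_rows(matrix(a, d[2], d[1] * d[3]), w),
             c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  # axis 3
  a <- aperm(a, c(3, 2, 1))
  a <- array(running_mean_rows(matrix(a, d[3], d[2] * d[1]), w),
             c(d[3], d[2], d[1]))
  a <- aperm(a, c(3, 2, 1))
  new_voxel_map(a, map$grid, kind = map$kind, label = map$label)
}

#' Project a voxel map to 2D by integrating along one axis
#'
#' @param map a \code{voxel_map}.
#' @param axis \code{"x"}, \code{"y"}, or \code{"z"}.
#' @return A 2D numeric matrix whose sum equals the map's total mass.
#' @export
project2d <- function(map, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  apply(map$values, setdiff(1:3, k), sum)
}

#' Class density map from one or more sister skeletons
#'
#' Resamples each skeleton at \code{step}, voxelizes the segment midpoints,
#' averages the unsmoothed histograms across sister neurons, then applies the
#' boxcar filter. (\code{average = FALSE} keeps only the first skeleton, the
#' single-exemplar mode.)
#'
#' @param skeletons a \code{neuron_skeleton} or list of them (sisters of one
#'   class, same region).
#' @param grid a \code{grid_spec}.
#' @param step resampling step, micrometres (default 0.5).
#' @param width_voxels boxcar width (default 9).
#' @param average average sister histograms before smoothing (default TRUE).
#' @param label optional map label.
#' @return A smoothed density \code{voxel_map}.
#' @export
density_map <- function(skeletons, grid, step = 0.5, width_voxels = 9,
                        average = TRUE, label = NULL) {
  if (inherits(skeletons, "neuron_skeleton")) skeletons <- list(skeletons)
  if (!average) skeletons <- skeletons[1]
  hists <- lapply(skeletons, function(sk)
    voxelize(resample_skeleton(sk, step), grid)$values)
  mean_hist <- Reduce(`+`, hists) / length(hists)
  boxcar_smooth(new_voxel_map(mean_hist, grid, kind = "density",
                              label = label),
                width_voxels)
}

#' Correlation-distance similarity of density maps, with Ward clustering
#'
#' Pearson correlation distance (1 - r) between flattened voxel arrays for
#' every pair of maps, plus the Ward dendrogram of that matrix. Constant maps
#' have undefined correlation; their distances are set to 1 with a warning.
#'
#' @param maps named list of \code{voxel_map} objects on one shared grid.
#' @return List: \code{distances} (a \code{distance_matrix}),
#'   \code{dendrogram} (an \code{hclust}).
#' @export
density_map_similarity <- function(maps) {
  stopifnot(length(maps) >= 2)
  g0 <- maps[[1]]$grid
  for (m in maps)
    if (!identical(m$grid, g0))
      stop("all maps must share one grid", call. = FALSE)
  flat <- vapply(maps, function(m) as.numeric(m$values),
                 numeric(prod(g0$dim)))
  colnames(flat) <- names(maps) %||% paste0("map", seq_along(maps))
  # columns of `flat` are the items (maps), matching odor_distance_matrix
  D <- odor_distance_matrix(flat, metric = "correlation")
  list(distances = D, dendrogram = hierarchical_cluster(D))
}
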