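#' Plot a center-out tuning curve
#'
#' @param x a \code{tuning_curve}.
#' @param ... passed to \code{barplot}.
#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::barplot(x$ordered_responses, names.arg = x$ordered_odor_ids,
                    las = 2, ylab = "response (spikes / 1-s window)",
                    main = sprintf("S = %.2f", x$sparseness), ...)
  invisible(x)
}

#' Plot a 2D projection of a voxel map
#'
#' Integrates the map along one axis and shows the projection as an image,
#' scaled to its own maximum (as map figures conventionally are).
#'
#' @param x a \code{voxel_map}.
#' @param axis projection axis (default \code{"z"}).
#' @param ... passed to \code{image}.
#' @export
plot.voxel_map <- function(x, axis = "z", ...) {
  p <- project2d(x, axis)
  graphics::image(seq_len(nrow(p)), seq_len(ncol(p)), p,
                  xlab = "voxel", ylab = "voxel", useRaster = TRUE,
                  main = paste(x$kind, x$label %||% "", "proj", axis), ...)
  invisible(x)
}
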