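#' Generate a synthetic odor panel
#'
#' Builds an odor panel in the layout used throughout the package: one row per
#' odor with a behavioral valence label (attractive/aversive), the solvent
#' used to dilute it (mineral oil or water, which determines the matched
#' control stimulus), and the dilution. The default panel size of 17 odors
#' with an 8/9 attractive/aversive split mirrors the behaviorally annotated
#' panel the analyses are designed around.
#'
#' @param n_attractive number of attractive odors.
#' @param n_aversive number of aversive odors.
#' @param seed integer seed; the panel is a pure function of the arguments
#'   and the seed.
#' @param dilution volumetric dilution applied to every odor (default 1e-3).
#'
#' @return A data.frame of class \code{odor_panel} with columns
#'   \code{odor_id}, \code{name}, \code{valence}, \code{solvent},
#'   \code{dilution}.
#' @export
#' @examples
#' panel <- generate_panel(8, 9, seed = 1)
#' table(panel$valence)
generate_panel <- function(n_attractive = 8, n_aversive = 9, seed = 1,
                           dilution = 1e-3) {
  if (!is.numeric(n_attractive) || !is.numeric(n_aversive) ||
      n_attractive < 0 || n_aversive < 0 ||
      (n_attractive + n_aversive) < 2)
    stop("panel must contain at least 2 odors in total", call. = FALSE)
  n <- as.integer(n_attractive + n_aversive)
  with_seed(seed, {
    odor_id <- sprintf("O%02d", seq_len(n))
    valence <- c(rep("attractive", n_attractive), rep("aversive", n_aversive))
    # a couple of water-soluble acids per panel; the rest in mineral oil
    solvent <- rep("mineral_oil", n)
    n_water <- min(n, max(1L, round(n / 8)))
    solvent[sample.int(n, n_water)] <- "water"
    panel <- data.frame(
      odor_id = odor_id,
      name = paste0("synthetic_odor_", odor_id),
      valence = valence,
      solvent = solvent,
      dilution = dilution,
      stringsAsFactors = FALSE
    )
    class(panel) <- c("odor_panel", "data.frame")
    panel
  })
}

#' Control stimulus id matched to an odor's solvent
#'
#' @param solvent "mineral_oil" or "water".
#' @return Control stimulus id, e.g. \code{"CTRL_mineral_oil"}.
#' @export
control_id <- function(solvent) {
  stopifnot(all(solvent %in% c("mineral_oil", "water")))
  paste0("CTRL_", solvent)
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("odor_id", "valence", "solvent") %in% names(panel)))
  if (anyDuplicated(panel$odor_id))
    stop("odor ids must be unique", call. = FALSE)
  if (!all(panel$valence %in% c("attractive", "aversive")))
    stop("valence must be attractive or aversive", call. = FALSE)
  invisible(panel)
}
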