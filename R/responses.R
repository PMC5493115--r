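#' Control-subtracted spike count in a response window
#'
#' Counts spikes with \code{t_start <= t < t_end} (half-open window, so a
#' spike on the upper boundary is not counted) and subtracts the control
#' count. Negative results are preserved; rectification happens only where an
#' analysis explicitly requires it (lifetime sparseness, functional maps).
#'
#' @param spikes sorted numeric vector of spike times, seconds.
#' @param window length-2 numeric, \code{c(t_start, t_end)}; default the
#'   odor-arrival-corrected 1-s window \code{c(0.05, 1.05)}.
#' @param control_count spike count of the matched control stimulus in the
#'   same window.
#' @return A single number (possibly negative).
#' @export
#' @examples
#' count_response(c(0.04, 0.06, 1.04, 1.06), c(0.05, 1.05), 0)  # 2
count_response <- function(spikes, window = c(0.05, 1.05),
                           control_count = 0) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (is.unsorted(spikes))
    stop("spike times must be sorted", call. = FALSE)
  assert_scalar_number(control_count, "control_count")
  sum(spikes >= window[1] & spikes < window[2]) - control_count
}

#' Build a class x odor response matrix from spike trains
#'
#' For every (neuron, odor, trial) the in-window spike count is computed and
#' the neuron's matched-control count (same trial when available, otherwise
#' the neuron's mean control count) is subtracted. Trials are then reduced
#' per neuron — \code{"first_round"} keeps trial 1 only, \code{"mean"}
#' averages all trials — and neurons of the same class are averaged.
#'
#' @param train_set a \code{spike_train_set}.
#' @param aggregation \code{"first_round"} (default, matching the use of the
#'   first stimulation round for cross-neuron comparability) or \code{"mean"}.
#' @param neuron_type row metadata label, \code{"PN"} or \code{"OSN"}.
#' @return A \code{response_matrix}: numeric class x odor matrix (spikes per
#'   1-s window, control-subtracted) with attributes \code{glomerulus}
#'   (named by class), \code{neuron_type}, and \code{panel}.
#' @export
build_response_matrix <- function(train_set,
                                  aggregation = c("first_round", "mean"),
                                  neuron_type = "PN") {
  stopifnot(inherits(train_set, "spike_train_set"))
  aggregation <- match.arg(aggregation)
  window <- attr(train_set, "window")
  units <- attr(train_set, "units")
  panel <- attr(train_set, "panel")
  ctrl_of <- attr(train_set, "control_of_odor")

  # raw in-window count for every simulated unit (absent rows = 0 spikes)
  key <- function(d) paste(d$neuron_id, d$odor_id, d$trial, sep = "\r")
  inwin <- train_set$t_spike >= window[1] & train_set$t_spike < window[2]
  cnt <- table(key(train_set[inwin, , drop = FALSE]))
  units$count <- as.numeric(cnt[key(units)])
  units$count[is.na(units$count)] <- 0

  odors <- panel$odor_id
  if (aggregation == "first_round")
    units <- units[units$trial == 1L, , drop = FALSE]

  is_ctrl <- units$odor_id %in% unique(ctrl_of)
  ctrl <- units[is_ctrl, , drop = FALSE]
  resp <- units[!is_ctrl, , drop = FALSE]
  missing_cells <- setdiff(
    as.vector(outer(unique(units$class_id), odors, paste, sep = "/")),
    paste(resp$class_id, resp$odor_id, sep = "/"))
  if (length(missing_cells))
    stop("no records for cells: ", paste(missing_cells, collapse = ", "),
         call. = FALSE)

  # match control count by (neuron, trial); fall back to the neuron mean
  ckey <- paste(ctrl$neuron_id, ctrl$odor_id, ctrl$trial, sep = "\r")
  ctrl_cnt <- stats::setNames(ctrl$count, ckey)
  ctrl_mean <- tapply(ctrl$count, paste(ctrl$neuron_id, ctrl$odor_id,
                                        sep = "\r"), mean)
  want <- paste(resp$neuron_id, ctrl_of[resp$odor_id], resp$trial, sep = "\r")
  cc <- ctrl_cnt[want]
  miss <- is.na(cc)
  cc[miss] <- ctrl_mean[paste(resp$neuron_id[miss],
                              ctrl_of[resp$odor_id[miss]], sep = "\r")]
  cc[is.na(cc)] <- 0
  resp$value <- resp$count - as.numeric(cc)

  # neuron-level trial mean, then class-level neuron mean
  per_neuron <- stats::aggregate(value ~ neuron_id + class_id + odor_id,
                                 data = resp, FUN = mean)
  per_class <- stats::aggregate(value ~ class_id + odor_id,
                                data = per_neuron, FUN = mean)
  classes <- sort(unique(per_class$class_id))
  m <- matrix(0, length(classes), length(odors),
              dimnames = list(classes, odors))
  m[cbind(per_class$class_id, per_class$odor_id)] <- per_class$value

  glom <- attr(train_set, "glomerulus_of_class")
  new_response_matrix(m, glomerulus = glom[classes],
                      neuron_type = neuron_type, panel = panel)
}

#' Per-neuron response matrix from spike trains
#'
#' Like [build_response_matrix()] but stops at the neuron level: one row per
#' recorded neuron (control-subtracted in-window counts, trials reduced by
#' the chosen aggregation), for pairwise neuron-neuron analyses.
#'
#' @inheritParams build_response_matrix
#' @return List: \code{values} (neuron x odor matrix) and
#'   \code{glomerulus_of_neuron} (named character).
#' @export
per_neuron_responses <- function(train_set,
                                 aggregation = c("first_round", "mean")) {
  stopifnot(inherits(train_set, "spike_train_set"))
  aggregation <- match.arg(aggregation)
  window <- attr(train_set, "window")
  units <- attr(train_set, "units")
  panel <- attr(train_set, "panel")
  ctrl_of <- attr(train_set, "control_of_odor")
  key <- function(d) paste(d$neuron_id, d$odor_id, d$trial, sep = "\r")
  inwin <- train_set$t_spike >= window[1] & train_set$t_spike < window[2]
  cnt <- table(key(train_set[inwin, , drop = FALSE]))
  units$count <- as.numeric(cnt[key(units)])
  units$count[is.na(units$count)] <- 0
  if (aggregation == "first_round")
    units <- units[units$trial == 1L, , drop = FALSE]
  is_ctrl <- units$odor_id %in% unique(ctrl_of)
  ctrl <- units[is_ctrl, , drop = FALSE]
  resp <- units[!is_ctrl, , drop = FALSE]
  ctrl_cnt <- stats::setNames(ctrl$count,
                              paste(ctrl$neuron_id, ctrl$odor_id, ctrl$trial,
                                    sep = "\r"))
  cc <- ctrl_cnt[paste(resp$neuron_id, ctrl_of[resp$odor_id], resp$trial,
                       sep = "\r")]
  cc[is.na(cc)] <- 0
  resp$value <- resp$count - as.numeric(cc)
  per <- stats::aggregate(value ~ neuron_id + class_id + odor_id, data = resp,
                          FUN = mean)
  neurons <- sort(unique(per$neuron_id))
  m <- matrix(0, length(neurons), nrow(panel),
              dimnames = list(neurons, panel$odor_id))
  m[cbind(per$neuron_id, per$odor_id)] <- per$value
  glom_of_class <- attr(train_set, "glomerulus_of_class")
  cls <- per$class_id[match(neurons, per$neuron_id)]
  list(values = m,
       glomerulus_of_neuron = stats::setNames(unname(glom_of_class[cls]),
                                              neurons))
}

#' Construct a response matrix object
#'
#' @param values numeric class x odor matrix with dimnames.
#' @param glomerulus character vector of glomerulus labels, one per row
#'   (named by class id or in row order).
#' @param neuron_type \code{"PN"} or \code{"OSN"}.
#' @param panel optional \code{odor_panel} for the columns.
#' @return A \code{response_matrix}.
#' @export
new_response_matrix <- function(values, glomerulus = rownames(values),
                                neuron_type = "PN", panel = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)), all(is.finite(values)))
  if (is.null(names(glomerulus))) names(glomerulus) <- rownames(values)
  structure(values,
            glomerulus = glomerulus[rownames(values)],
            neuron_type = neuron_type,
            panel = panel,
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("%s response matrix: %d classes x %d odors (spikes per 1-s window, control-subtracted)\n",
              attr(x, "neuron_type"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE], 5))
  if (nrow(x) > 5 || ncol(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a class x odor response table from CSV
#'
#' Expects the supplementary-table layout: first column the class/glomerulus
#' label, header row the odor names, one numeric column per odor. An optional
#' \code{glomerulus} column is used for row metadata.
#'
#' @param path CSV path.
#' @param neuron_type row metadata, \code{"PN"} or \code{"OSN"}.
#' @return A \code{response_matrix}.
#' @export
read_response_table <- function(path, neuron_type = "PN") {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(d[[1]])
  d <- d[, -1, drop = FALSE]
  glom <- labels
  if ("glomerulus" %in% names(d)) {
    glom <- as.character(d[["glomerulus"]])
    d <- d[, setdiff(names(d), "glomerulus"), drop = FALSE]
  }
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("response table has non-numeric cells",
                           call. = FALSE)
  rownames(m) <- labels
  new_response_matrix(m, glomerulus = stats::setNames(glom, labels),
                      neuron_type = neuron_type)
}

#' Write a response matrix to CSV (round-trips with [read_response_table()])
#' @param x a \code{response_matrix}.
#' @param path output CSV path.
#' @export
write_response_table <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  d <- data.frame(class_id = rownames(x),
                  glomerulus = attr(x, "glomerulus"),
                  unclass(x), check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Pairwise neuron-neuron response correlations, split by glomerulus identity
#'
#' Pearson correlation over the odor panel for every unordered neuron pair,
#' partitioned into pairs innervating the same glomerulus vs different
#' glomeruli, with a two-sided Wilcoxon rank-sum test between the partitions.
#' Neurons with zero response variance (undefined r) are excluded with a
#' warning.
#'
#' @param per_neuron neuron x odor numeric matrix with rownames.
#' @param glomerulus_of_neuron named character vector mapping neuron id to
#'   glomerulus.
#' @return List with \code{same_glomerulus} and \code{different_glomerulus}
#'   (numeric vectors of r), \code{ranksum_p}, and \code{n_excluded}.
#' @export
pairwise_neuron_correlation <- function(per_neuron, glomerulus_of_neuron) {
  stopifnot(is.matrix(per_neuron), nrow(per_neuron) >= 2)
  keep <- apply(per_neuron, 1, stats::sd) > 0
  n_excluded <- sum(!keep)
  if (n_excluded)
    warning(sprintf("%d zero-variance neurons excluded", n_excluded),
            call. = FALSE)
  m <- per_neuron[keep, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 usable neurons", call. = FALSE)
  r <- stats::cor(t(m))
  glom <- glomerulus_of_neuron[rownames(m)]
  same <- outer(glom, glom, `==`)
  ut <- upper.tri(r)
  res <- list(same_glomerulus = r[ut & same],
              different_glomerulus = r[ut & !same],
              n_excluded = n_excluded)
  res$ranksum_p <-
    if (length(res$same_glomerulus) && length(res$different_glomerulus))
      stats::wilcox.test(res$same_glomerulus, res$different_glomerulus)$p.value
    else NA_real_
  res
}

#' Fraction of class-odor pairs at or above response thresholds
#'
#' @param matrix a \code{response_matrix} (or plain numeric matrix).
#' @param thresholds numeric vector, spikes per 1-s window.
#' @return data.frame with one row per threshold: \code{threshold},
#'   \code{count}, \code{total}, \code{fraction}.
#' @export
#' @examples
#' m <- new_response_matrix(matrix(c(60, 10, 40, 0), 2, 2,
#'   dimnames = list(c("a", "b"), c("o1", "o2"))))
#' threshold_fractions(m, c(30, 50))
threshold_fractions <- function(matrix, thresholds = c(30, 50)) {
  v <- as.numeric(matrix)
  data.frame(threshold = thresholds,
             count = vapply(thresholds, function(th) sum(v >= th), numeric(1)),
             total = length(v),
             fraction = vapply(thresholds, function(th) mean(v >= th),
                               numeric(1)))
}

#' Trial-averaged peristimulus time histogram tensor
#'
#' Bins every spike into fixed-width bins over the recording span and
#' averages rates (spikes/s) over neurons and trials of each class, for each
#' odor. Control stimuli are excluded.
#'
#' @param train_set a \code{spike_train_set}.
#' @param bin_width bin width in seconds; must divide the span length.
#' @return A \code{population_tensor}: 3-D array time x class x odor of
#'   firing rates with attributes \code{bin_width}, \code{t0} (stimulus
#'   onset), \code{time} (bin left edges), \code{panel}.
#' @export
psth <- function(train_set, bin_width = 0.1) {
  stopifnot(inherits(train_set, "spike_train_set"))
  span <- attr(train_set, "span")
  nb <- (span[2] - span[1]) / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide the recording span", call. = FALSE)
  nb <- as.integer(round(nb))
  units <- attr(train_set, "units")
  panel <- attr(train_set, "panel")
  odors <- panel$odor_id
  classes <- sort(unique(units$class_id))
  breaks <- seq(span[1], span[2], length.out = nb + 1L)

  arr <- array(0, dim = c(nb, length(classes), length(odors)),
               dimnames = list(NULL, classes, odors))
  d <- train_set[train_set$odor_id %in% odors, , drop = FALSE]
  if (nrow(d)) {
    bin <- findInterval(d$t_spike, breaks, rightmost.closed = TRUE)
    agg <- stats::aggregate(
      list(n = rep(1L, nrow(d))),
      by = list(bin = bin, class_id = d$class_id, odor_id = d$odor_id),
      FUN = sum)
    arr[cbind(agg$bin, match(agg$class_id, classes),
              match(agg$odor_id, odors))] <- agg$n
  }
  # normalize by number of (neuron, trial) units per class-odor and bin width
  nunits <- table(factor(units$class_id[units$odor_id %in% odors],
                         levels = classes),
                  factor(units$odor_id[units$odor_id %in% odors],
                         levels = odors))
  for (j in seq_along(classes))
    for (k in seq_along(odors))
      arr[, j, k] <- arr[, j, k] / (bin_width * max(1L, nunits[j, k]))

  structure(arr, bin_width = bin_width, t0 = attr(train_set, "stimulus")[1],
            time = breaks[-length(breaks)], panel = panel,
            class = c("population_tensor", "array"))
}
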