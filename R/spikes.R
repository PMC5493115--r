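## Normalized stimulus-locked rate profile on [0, 1] s: an onset transient
## peaking at `peak_time` relaxing to a sustained plateau. Integrates to 1
## over the stimulus second, so a class with mean_rate m contributes m
## expected spikes above baseline per stimulus window.
rate_profile <- function(t, peak_time = 0.15, transient_frac = 0.6) {
  g <- numeric(length(t))
  inside <- t >= 0 & t <= 1
  ts <- t[inside]
  tr <- (ts / peak_time) * exp(1 - ts / peak_time)   # alpha shape, peak 1
  # closed-form integral of the alpha shape over [0, 1]
  z <- exp(1) * peak_time *
    (1 - exp(-1 / peak_time) * (1 + 1 / peak_time))
  g[inside] <- transient_frac * tr / z + (1 - transient_frac)
  g
}

#' Simulate spike trains from a ground-truth model
#'
#' Generates inhomogeneous Poisson spike trains over the recording span
#' \code{[-1, 3]} s (stimulus at \code{[0, 1]} s) by thinning against the
#' maximum rate. The firing rate is the baseline outside the stimulus; during
#' the stimulus it is baseline plus the class-odor amplitude times a
#' normalized transient profile that peaks at \code{model$onset_peak_time}
#' and decays toward a sustained plateau. Sister neurons of one class share
#' the class rate profile; each (neuron, odor, trial) receives independent
#' additive amplitude noise of s.d. \code{model$trial_sd}. Matched control
#' stimuli (one per solvent, baseline rate only) are simulated alongside the
#' odors so responses can be control-subtracted downstream.
#'
#' @param model a \code{ground_truth_model}.
#' @param n_trials trials per (neuron, stimulus); must be >= 1.
#' @param n_sisters_per_class neurons per class (default 3, the typical
#'   number of sister projection neurons per glomerulus).
#' @param seed integer seed.
#' @return A data.frame of class \code{spike_train_set} with columns
#'   \code{neuron_id}, \code{class_id}, \code{odor_id}, \code{trial},
#'   \code{t_spike}; attributes \code{window} (the response window,
#'   \code{c(0.05, 1.05)}), \code{span} (\code{c(-1, 3)}),
#'   \code{stimulus} (\code{c(0, 1)}), \code{panel}, \code{control_of_odor}
#'   (named character), and \code{units} (a data.frame enumerating every
#'   (neuron, stimulus, trial) simulated, so silent trials are not lost).
#' @export
#' @examples
#' panel <- generate_panel(3, 3, seed = 1)
#' m <- generate_model(panel, n_classes = 4, n_groups = 2, seed = 1)
#' st <- simulate_spike_trains(m, n_trials = 2, seed = 1)
#' head(st)
simulate_spike_trains <- function(model, n_trials = 2,
                                  n_sisters_per_class = 3, seed = 1) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("n_trials must be >= 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  span <- c(-1, 3)
  stim <- c(0, 1)
  panel <- model$panel
  controls <- unique(control_id(panel$solvent))
  stim_ids <- c(panel$odor_id, controls)
  n_clipped <- 0L

  out <- with_seed(seed, {
    recs <- vector("list", 0L)
    units <- vector("list", 0L)
    for (ci in seq_along(model$class_ids)) {
      cl <- model$class_ids[ci]
      for (s in seq_len(n_sisters_per_class)) {
        nid <- sprintf("%s_n%d", cl, s)
        for (od in stim_ids) {
          amp0 <- if (od %in% controls) 0 else model$mean_rate[cl, od]
          for (tr in seq_len(n_trials)) {
            amp <- amp0 + stats::rnorm(1, 0, model$trial_sd)
            if (amp < 0) {
              amp <- 0
              n_clipped <- n_clipped + 1L
            }
            spk <- thin_poisson(model$baseline_rate, amp,
                                model$onset_peak_time, span)
            units[[length(units) + 1L]] <-
              data.frame(neuron_id = nid, class_id = cl, odor_id = od,
                         trial = tr, stringsAsFactors = FALSE)
            if (length(spk))
              recs[[length(recs) + 1L]] <-
                data.frame(neuron_id = nid, class_id = cl, odor_id = od,
                           trial = tr, t_spike = spk,
                           stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(recs = do.call(rbind, recs), units = do.call(rbind, units))
  })
  if (n_clipped > 0)
    warning(sprintf("%d negative trial amplitudes clipped at 0", n_clipped),
            call. = FALSE)

  st <- out$recs
  attr(st, "window") <- c(0.05, 1.05)
  attr(st, "span") <- span
  attr(st, "stimulus") <- stim
  attr(st, "panel") <- panel
  attr(st, "control_of_odor") <-
    stats::setNames(control_id(panel$solvent), panel$odor_id)
  attr(st, "glomerulus_of_class") <- model$glomerulus_of_class
  attr(st, "units") <- out$units
  class(st) <- c("spike_train_set", "data.frame")
  st
}

## One trial of an inhomogeneous Poisson train by thinning. Rate: baseline on
## [span], plus amp * rate_profile(t) during the stimulus second.
thin_poisson <- function(baseline, amp, peak_time, span) {
  prof_peak <- max(rate_profile(seq(0, 1, by = 0.005), peak_time))
  rmax <- baseline + amp * prof_peak
  if (rmax <= 0) return(numeric(0))
  n <- stats::rpois(1, rmax * diff(span))
  if (n == 0) return(numeric(0))
  t <- sort(stats::runif(n, span[1], span[2]))
  r <- baseline + amp * rate_profile(t, peak_time)
  t[stats::runif(n) * rmax < r]
}

#' @export
print.spike_train_set <- function(x, ...) {
  u <- attr(x, "units")
  cat("Spike train set:", nrow(x), "spikes;",
      length(unique(u$neuron_id)), "neurons x",
      length(unique(u$odor_id)), "stimuli x",
      max(u$trial), "trials\n")
  invisible(x)
}
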