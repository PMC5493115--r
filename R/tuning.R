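#' Lifetime sparseness of a response vector
#'
#' Normalized selectivity index of a neuron's tuning across a fixed odor
#' panel:
#' \deqn{S = \frac{1}{1 - 1/N}\left(1 - \frac{(\sum_j r_j / N)^2}{\sum_j r_j^2 / N}\right)}
#' where \eqn{N} is the panel size and \eqn{r_j} the response intensity to
#' odor \eqn{j}. Negative responses are set to zero before the computation.
#' \eqn{S = 0} for a uniform responder and \eqn{S = 1} for a single-odor
#' responder.
#'
#' @param responses numeric vector of response intensities (length \eqn{N}).
#' @param n_odors panel size \eqn{N}; defaults to \code{length(responses)}
#'   and must equal it.
#' @return Sparseness in \code{[0, 1]}. All-zero rectified input is an error
#'   (the index is undefined), not 0.
#' @export
#' @examples
#' lifetime_sparseness(c(40, rep(0, 16)))  # 1
#' lifetime_sparseness(rep(25, 17))        # 0
lifetime_sparseness <- function(responses, n_odors = length(responses)) {
  if (length(responses) != n_odors || n_odors < 2)
    stop("need n_odors = length(responses) >= 2", call. = FALSE)
  r <- pmax(responses, 0)
  if (all(r == 0))
    stop("lifetime sparseness undefined for an all-zero rectified vector",
         call. = FALSE)
  n <- n_odors
  s <- (1 / (1 - 1 / n)) * (1 - (sum(r) / n)^2 / (sum(r^2) / n))
  min(max(s, 0), 1)
}

#' Center-out ordering of a tuning curve
#'
#' Orders odors so the strongest response sits at the center and weaker
#' responses alternate right, then left, outward — the standard layout for
#' displaying tuning curves. Ties are broken by odor id.
#'
#' @param responses named numeric vector (names = odor ids; unnamed input is
#'   labelled positionally).
#' @return List of class \code{tuning_curve}: \code{ordered_odor_ids},
#'   \code{ordered_responses}, \code{sparseness} (NA if undefined).
#' @export
order_tuning_curve <- function(responses) {
  n <- length(responses)
  ids <- names(responses) %||% sprintf("odor%02d", seq_len(n))
  o <- order(-responses, ids)             # descending, ties by odor id
  # ranks 1,2,3,... go to positions center, center+1, center-1, center+2, ...
  # (center = floor(n/2), 0-based); offsets falling off one edge continue on
  # the other side so even-length panels fill completely
  center <- floor(n / 2) + 1L
  cand <- center + c(0L, as.vector(rbind(seq_len(n), -seq_len(n))))
  pos <- cand[cand >= 1L & cand <= n][seq_len(n)]
  perm <- integer(n)
  perm[pos] <- o
  s <- tryCatch(lifetime_sparseness(responses), error = function(e) NA_real_)
  structure(list(ordered_odor_ids = ids[perm],
                 ordered_responses = unname(responses[perm]),
                 sparseness = s),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("Tuning curve (center-out):", paste(x$ordered_odor_ids, collapse = " "),
      sprintf("\nlifetime sparseness S = %.3f\n", x$sparseness))
  invisible(x)
}

## rows of two response matrices matched on shared glomeruli
match_glomeruli <- function(pn, osn) {
  stopifnot(inherits(pn, "response_matrix"), inherits(osn, "response_matrix"))
  if (!identical(colnames(pn), colnames(osn)))
    stop("odor columns must be identical", call. = FALSE)
  gp <- attr(pn, "glomerulus"); go <- attr(osn, "glomerulus")
  shared <- intersect(gp, go)
  skipped <- c(setdiff(gp, go), setdiff(go, gp))
  list(shared = shared, skipped = skipped,
       pn = unclass(pn)[match(shared, gp), , drop = FALSE],
       osn = unclass(osn)[match(shared, go), , drop = FALSE])
}

#' Per-glomerulus correlation between OSN and PN odor responses
#'
#' For every glomerulus present in both matrices, the Pearson correlation of
#' the OSN and PN response vectors over the shared odor panel, with a
#' two-sided t-test p-value (df = N odors - 2). Glomeruli present in only one
#' matrix are skipped and listed. Two summaries are reported: over all shared
#' glomeruli, and over the subset where the correlation is defined (non-zero
#' variance on both sides).
#'
#' @param pn,osn \code{response_matrix} objects with identical odor columns.
#' @return List with \code{per_glomerulus} (data.frame: glomerulus, r, p),
#'   \code{summary} (mean, sd, n over defined r), \code{skipped}.
#' @export
osn_pn_correlation <- function(pn, osn) {
  mm <- match_glomeruli(pn, osn)
  if (!length(mm$shared)) stop("no shared glomeruli", call. = FALSE)
  res <- lapply(seq_along(mm$shared), function(i) {
    x <- mm$pn[i, ]; y <- mm$osn[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(glomerulus = mm$shared[i], r = NA_real_,
                        p = NA_real_))
    ct <- stats::cor.test(x, y)
    data.frame(glomerulus = mm$shared[i], r = unname(ct$estimate),
               p = ct$p.value)
  })
  per <- do.call(rbind, res)
  ok <- !is.na(per$r)
  list(per_glomerulus = per,
       summary = c(mean = mean(per$r[ok]), sd = stats::sd(per$r[ok]),
                   n = sum(ok)),
       skipped = mm$skipped)
}

#' Shuffle control for the OSN-PN per-glomerulus correlation
#'
#' Repeatedly permutes the OSN-to-PN glomerulus pairing uniformly (fixed
#' points allowed), recomputes the mean per-glomerulus Pearson r, and reports
#' the mean and s.d. of the run means — the chance level against which the
#' matched-pairing correlation is judged.
#'
#' @param pn,osn \code{response_matrix} objects.
#' @param n_runs number of shuffle runs (>= 2).
#' @param seed integer seed.
#' @return List: \code{mean}, \code{sd}, \code{n_runs}, \code{run_means}.
#' @export
shuffled_correlation_control <- function(pn, osn, n_runs = 100, seed = 1) {
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  mm <- match_glomeruli(pn, osn)
  n <- length(mm$shared)
  run_means <- with_seed(seed, vapply(seq_len(n_runs), function(run) {
    perm <- sample.int(n)
    r <- vapply(seq_len(n), function(i) {
      x <- mm$pn[i, ]; y <- mm$osn[perm[i], ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(x, y)
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1)))
  list(mean = mean(run_means), sd = stats::sd(run_means),
       n_runs = n_runs, run_means = run_means)
}

#' Paired lifetime sparseness of OSNs and PNs per glomerulus
#'
#' Computes lifetime sparseness of the OSN and the PN response vector for
#' every shared glomerulus. Glomeruli whose rectified responses are all zero
#' on either side (sparseness undefined) are excluded and reported.
#'
#' @param pn,osn \code{response_matrix} objects.
#' @return List: \code{pairs} (data.frame glomerulus, S_osn, S_pn),
#'   \code{excluded} (character).
#' @export
sparseness_comparison <- function(pn, osn) {
  mm <- match_glomeruli(pn, osn)
  s_of <- function(v) tryCatch(lifetime_sparseness(v),
                               error = function(e) NA_real_)
  s_pn <- apply(mm$pn, 1, s_of)
  s_osn <- apply(mm$osn, 1, s_of)
  ok <- !is.na(s_pn) & !is.na(s_osn)
  list(pairs = data.frame(glomerulus = mm$shared[ok],
                          S_osn = unname(s_osn[ok]),
                          S_pn = unname(s_pn[ok])),
       excluded = mm$shared[!ok])
}
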