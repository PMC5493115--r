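#' Analysis configuration
#'
#' Bundles the numeric constants of the standard analysis: the 1-s response
#' window shifted by the 50-ms odor-arrival delay, distance metric defaults
#' (cosine in the antennal-lobe odor space, correlation between maps), fixed
#' dendrogram cuts (0.6 absolute; 0.7 of the maximum linkage distance for
#' Euclidean clustering), the 30 spikes/s cluster-signature threshold, the
#' template voxel grid, the 9-voxel boxcar, 100 shuffle runs, 10,000 ANOSIM
#' permutations, and a single global seed from which every stochastic stage
#' derives a logged sub-seed.
#'
#' @param seed global seed.
#' @param n_classes,n_groups,within_group_gain,trial_sd synthetic-model
#'   conditions (defaults: 31 classes, 3 groups, gain 10, trial s.d. 3).
#' @param n_trials,n_sisters spike-simulation conditions.
#' @param n_attractive,n_aversive odor panel split (default 8/9).
#' @param window response window, seconds.
#' @param cut_absolute,cut_fraction dendrogram cuts.
#' @param signature_threshold spikes/s threshold for signature glomeruli.
#' @param thresholds response-intensity thresholds for the fraction table.
#' @param shuffle_runs pairing-shuffle control runs.
#' @param anosim_perm ANOSIM permutations.
#' @param boxcar_width boxcar kernel width, voxels.
#' @param resample_step skeleton resampling step, micrometres.
#' @param voxel_size voxel edge, micrometres.
#' @param psth_bin PSTH bin width, seconds.
#' @return A list of class \code{olf_config}.
#' @export
olf_config <- function(seed = 1,
                       n_classes = 31, n_groups = 3, within_group_gain = 10,
                       trial_sd = 3, n_trials = 2, n_sisters = 3,
                       n_attractive = 8, n_aversive = 9,
                       window = c(0.05, 1.05),
                       cut_absolute = 0.6, cut_fraction = 0.7,
                       signature_threshold = 30, thresholds = c(30, 50),
                       shuffle_runs = 100, anosim_perm = 10000,
                       boxcar_width = 9, resample_step = 0.5, voxel_size = 1,
                       psth_bin = 0.1) {
  cfg <- as.list(environment())
  for (nm in setdiff(names(cfg), c("window", "thresholds", "seed", "trial_sd")))
    assert_scalar_number(cfg[[nm]], nm, positive = TRUE)
  assert_scalar_number(cfg$seed, "seed")
  assert_scalar_number(cfg$trial_sd, "trial_sd")
  if (cfg$trial_sd < 0) stop("'trial_sd' must be non-negative", call. = FALSE)
  stopifnot(length(window) == 2, window[1] < window[2])
  cfg$thresholds <- thresholds
  structure(cfg, class = c("olf_config", "list"))
}

#' Run the full synthetic end-to-end analysis
#'
#' Orchestrates simulate -> responses -> tuning -> odor space -> density and
#' functional maps -> temporal analyses under one configuration, writing all
#' tables to a run directory with a checksum manifest. Identical config and
#' seed give identical manifests. When \code{stages} excludes the map stages
#' the run completes with those stages recorded as skipped.
#'
#' @param config an \code{olf_config}.
#' @param out_dir run directory (created if needed).
#' @param stages character subset of
#'   \code{c("responses","tuning","odorspace","maps","temporal")}.
#' @return Invisibly, a list with the in-memory results of every stage plus
#'   \code{out_dir}.
#' @export
run_olfactory_analysis <- function(config = olf_config(),
                                   out_dir = tempfile("olfrun"),
                                   stages = c("responses", "tuning",
                                              "odorspace", "maps",
                                              "temporal")) {
  stopifnot(inherits(config, "olf_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n",
                                    format(Sys.time(), "%H:%M:%S"),
                                    sprintf(...)),
                            file = log_path, append = TRUE)
  res <- list(config = config, out_dir = out_dir, skipped = character(0))
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ground truth + recordings (PN population, plus an OSN-like population
  ## sharing the same per-glomerulus tuning with independent noise)
  logf("generating synthetic population (seed %d)", config$seed)
  panel <- generate_panel(config$n_attractive, config$n_aversive,
                          seed = stage_seed(config$seed, "panel"))
  model <- generate_model(panel, n_classes = config$n_classes,
                          n_groups = config$n_groups,
                          within_group_gain = config$within_group_gain,
                          trial_sd = config$trial_sd,
                          seed = stage_seed(config$seed, "model"))
  res$panel <- panel
  res$model <- model
  utils::write.csv(panel, file.path(out_dir, "panel.csv"), row.names = FALSE)

  pn_trains <- simulate_spike_trains(model, n_trials = config$n_trials,
                                     n_sisters_per_class = config$n_sisters,
                                     seed = stage_seed(config$seed,
                                                       "pn_spikes"))
  osn_trains <- simulate_spike_trains(model, n_trials = config$n_trials,
                                      n_sisters_per_class = config$n_sisters,
                                      seed = stage_seed(config$seed,
                                                        "osn_spikes"))

  if ("responses" %in% stages) {
    logf("responses stage")
    pn <- build_response_matrix(pn_trains, "first_round", neuron_type = "PN")
    osn <- build_response_matrix(osn_trains, "first_round",
                                 neuron_type = "OSN")
    res$pn <- pn; res$osn <- osn
    res$threshold_fractions <- threshold_fractions(pn, config$thresholds)
    write_response_table(pn, file.path(out_dir, "pn_matrix.csv"))
    write_response_table(osn, file.path(out_dir, "osn_matrix.csv"))
    utils::write.csv(res$threshold_fractions,
                     file.path(out_dir, "threshold_fractions.csv"),
                     row.names = FALSE)
  } else res$skipped <- c(res$skipped, "responses")

  if ("tuning" %in% stages && !is.null(res$pn)) {
    logf("tuning stage")
    res$osn_pn <- osn_pn_correlation(res$pn, res$osn)
    res$shuffle <- shuffled_correlation_control(
      res$pn, res$osn, n_runs = config$shuffle_runs,
      seed = stage_seed(config$seed, "shuffle"))
    res$sparseness <- sparseness_comparison(res$pn, res$osn)
    utils::write.csv(res$osn_pn$per_glomerulus,
                     file.path(out_dir, "osn_pn_correlation.csv"),
                     row.names = FALSE)
    utils::write.csv(res$sparseness$pairs,
                     file.path(out_dir, "sparseness_pairs.csv"),
                     row.names = FALSE)
  } else res$skipped <- c(res$skipped, "tuning")

  if ("odorspace" %in% stages && !is.null(res$pn)) {
    logf("odor-space stage")
    D <- odor_distance_matrix(res$pn, "cosine")
    dend <- hierarchical_cluster(D)
    clusters <- cut_dendrogram(dend, config$cut_absolute, "absolute")
    res$odor_space <- list(
      distances = D, dendrogram = dend, clusters = clusters,
      signatures = cluster_signature_glomeruli(res$pn, clusters,
                                               config$signature_threshold),
      pca = odor_pca(res$pn, items = "odors"),
      anosim = anosim_odors(res$pn, panel$valence,
                            n_perm = config$anosim_perm,
                            seed = stage_seed(config$seed, "anosim")))
    utils::write.csv(as.data.frame(unclass(D)),
                     file.path(out_dir, "odor_distances_cosine.csv"))
    utils::write.csv(data.frame(odor_id = names(clusters),
                                cluster = unname(clusters)),
                     file.path(out_dir, "odor_clusters.csv"),
                     row.names = FALSE)
  } else res$skipped <- c(res$skipped, "odorspace")

  if ("maps" %in% stages && !is.null(res$pn)) {
    logf("morphology + functional map stage")
    skels <- generate_skeletons(model,
                                seed = stage_seed(config$seed, "skeletons"))
    res$maps <- lapply(c(LH = "LH", calyx = "calyx"), function(rg) {
      grid <- region_grid(rg, voxel_size = config$voxel_size)
      dens <- lapply(skels, function(s)
        density_map(s[[rg]], grid, step = config$resample_step,
                    width_voxels = config$boxcar_width))
      names(dens) <- names(skels)
      fmaps <- lapply(panel$odor_id, function(od)
        functional_map(dens, res$pn, od))
      names(fmaps) <- panel$odor_id
      fc <- functional_map_clustering(fmaps, cut = config$cut_absolute)
      masks <- dorsoventral_masks(grid)
      frac <- t(vapply(fmaps, function(fm)
        tryCatch(regional_summary(fm, masks),
                 error = function(e) c(ventral = NA_real_,
                                       dorsal = NA_real_)),
        numeric(2)))
      list(grid = grid, density = dens, functional = fmaps,
           clustering = fc, regional_fractions = frac)
    })
    for (rg in names(res$maps))
      utils::write.csv(
        data.frame(odor_id = panel$odor_id,
                   cluster = unname(res$maps[[rg]]$clustering$clusters),
                   res$maps[[rg]]$regional_fractions),
        file.path(out_dir, paste0("functional_clusters_", rg, ".csv")),
        row.names = FALSE)
  } else res$skipped <- c(res$skipped, "maps")

  if ("temporal" %in% stages) {
    logf("temporal stage")
    tensor <- psth(pn_trains, bin_width = config$psth_bin)
    res$tensor <- tensor
    res$timecourse <- inter_odor_distance_timecourse(tensor)
    utils::write.csv(data.frame(time = res$timecourse$time,
                                distance = res$timecourse$distance),
                     file.path(out_dir, "inter_odor_distance_timecourse.csv"),
                     row.names = FALSE)
  } else res$skipped <- c(res$skipped, "temporal")

  if (length(res$skipped)) logf("skipped stages: %s",
                                paste(res$skipped, collapse = ", "))
  ## manifest with checksums (log excluded: it carries wall-clock timestamps)
  files <- setdiff(list.files(out_dir), c("manifest.csv", "run.log"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  logf("run complete: %d files", nrow(manifest))
  invisible(res)
}

#' Summarize a completed run directory
#'
#' Reads the tables written by [run_olfactory_analysis()] and renders a plain
#' markdown summary of the headline statistics (threshold fractions, OSN-PN
#' correlation, odor clusters, functional-map clusters). Stages without
#' output files are reported as absent. Regeneration is deterministic for a
#' fixed run directory.
#'
#' @param run_dir path to a run directory.
#' @param path output file (default \code{report.md} inside the run dir).
#' @return The report lines, invisibly.
#' @export
olf_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  if (!file.exists(file.path(run_dir, "manifest.csv")))
    stop("not a completed run directory: ", run_dir, call. = FALSE)
  say <- function(...) sprintf(...)
  lines <- c("# Olfactory coding analysis report", "")
  f <- function(name) file.path(run_dir, name)
  if (file.exists(f("threshold_fractions.csv"))) {
    tf <- utils::read.csv(f("threshold_fractions.csv"))
    lines <- c(lines, "## Response thresholds",
               apply(tf, 1, function(r)
                 say("- >= %g spikes: %d/%d (%.1f%%)", r["threshold"],
                     r["count"], r["total"], 100 * r["fraction"])), "")
  } else lines <- c(lines, "## Response thresholds", "- absent", "")
  if (file.exists(f("osn_pn_correlation.csv"))) {
    oc <- utils::read.csv(f("osn_pn_correlation.csv"))
    lines <- c(lines, "## OSN-PN correlation",
               say("- mean r = %.3f +/- %.3f (n = %d glomeruli)",
                   mean(oc$r, na.rm = TRUE), stats::sd(oc$r, na.rm = TRUE),
                   sum(!is.na(oc$r))), "")
  } else lines <- c(lines, "## OSN-PN correlation", "- absent", "")
  if (file.exists(f("odor_clusters.csv"))) {
    cl <- utils::read.csv(f("odor_clusters.csv"))
    lines <- c(lines, "## Odor-space clusters",
               vapply(sort(unique(cl$cluster)), function(k)
                 say("- cluster %d: %s", k,
                     paste(cl$odor_id[cl$cluster == k], collapse = ", ")),
                 character(1)), "")
  } else lines <- c(lines, "## Odor-space clusters", "- absent", "")
  for (rg in c("LH", "calyx")) {
    fn <- f(paste0("functional_clusters_", rg, ".csv"))
    if (file.exists(fn)) {
      cl <- utils::read.csv(fn)
      lines <- c(lines, say("## Functional-map clusters (%s)", rg),
                 vapply(sort(unique(cl$cluster)), function(k)
                   say("- cluster %d: %s", k,
                       paste(cl$odor_id[cl$cluster == k], collapse = ", ")),
                   character(1)), "")
    } else lines <- c(lines, say("## Functional-map clusters (%s)", rg),
                      "- absent", "")
  }
  writeLines(lines, path)
  invisible(lines)
}
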