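#' Read a neuron skeleton from an SWC file
#'
#' Parses the 7-column SWC format (node id, type, x, y, z, radius, parent id;
#' comment lines start with \code{#}). The tree is validated: exactly one
#' root (parent \code{-1}), every other parent must name an existing node,
#' and no cycles.
#'
#' @param path file path.
#' @return A \code{neuron_skeleton}: a data.frame with columns \code{id},
#'   \code{type}, \code{x}, \code{y}, \code{z}, \code{radius}, \code{parent},
#'   plus attributes \code{class_id} and \code{region} when present as
#'   \code{# class_id:} / \code{# region:} header comments.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^\\s*(#|$)", lines, value = TRUE, invert = TRUE)
  if (!length(body)) stop("SWC file has no data lines: ", path, call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("SWC parse error at data line %d: expected 7 fields", bad[1]),
         call. = FALSE)
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  nonnum <- which(apply(is.na(m), 1, any))
  if (length(nonnum))
    stop(sprintf("SWC parse error at data line %d: non-numeric field",
                 nonnum[1]), call. = FALSE)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  sk <- new_skeleton(nodes,
                     class_id = swc_meta(meta, "class_id"),
                     region = swc_meta(meta, "region"))
  sk
}

swc_meta <- function(meta, key) {
  hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
}

new_skeleton <- function(nodes, class_id = NULL, region = NULL) {
  validate_skeleton(nodes)
  attr(nodes, "class_id") <- class_id
  attr(nodes, "region") <- region
  class(nodes) <- c("neuron_skeleton", "data.frame")
  nodes
}

validate_skeleton <- function(nodes) {
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids in skeleton", call. = FALSE)
  roots <- sum(nodes$parent == -1L)
  if (roots != 1L)
    stop(sprintf("skeleton must have exactly one root, found %d", roots),
         call. = FALSE)
  known <- nodes$parent == -1L | nodes$parent %in% nodes$id
  if (!all(known))
    stop("orphan parent id at node ", nodes$id[which(!known)[1]],
         call. = FALSE)
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite coordinates in skeleton", call. = FALSE)
  # every non-root has one parent, so n-1 edges: a cycle would leave part of
  # the graph unreachable from the root. BFS from the root over children.
  idx <- match(nodes$parent, nodes$id)        # parent row per node, NA at root
  reached <- logical(nrow(nodes))
  frontier <- which(nodes$parent == -1L)
  reached[frontier] <- TRUE
  while (length(frontier)) {
    frontier <- which(!reached & idx %in% frontier)
    reached[frontier] <- TRUE
  }
  if (!all(reached))
    stop("cycle detected in skeleton (nodes unreachable from root)",
         call. = FALSE)
  invisible(nodes)
}

#' Write a neuron skeleton to an SWC file
#'
#' Coordinates and radii are printed with four decimals, which makes the
#' output byte-stable for a fixed skeleton and lossless at that precision.
#'
#' @param skeleton a \code{neuron_skeleton}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "neuron_skeleton"))
  hdr <- c("# SWC skeleton",
           if (!is.null(attr(skeleton, "class_id")))
             paste0("# class_id: ", attr(skeleton, "class_id")),
           if (!is.null(attr(skeleton, "region")))
             paste0("# region: ", attr(skeleton, "region")))
  rows <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                  skeleton$id, skeleton$type, skeleton$x, skeleton$y,
                  skeleton$z, skeleton$radius, skeleton$parent)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Bounding boxes of the higher-brain-center regions in template space
#'
#' Axis-aligned boxes for the mushroom-body calyx (55 x 46 x 32 um) and the
#' lateral horn (52 x 53 x 43 um), centered in the default 135 x 135 x 105 um
#' template grid.
#'
#' @param region \code{"calyx"} or \code{"LH"}.
#' @return 3 x 2 matrix with columns \code{min}, \code{max} (micrometres).
#' @export
region_box <- function(region = c("calyx", "LH")) {
  region <- match.arg(region)
  size <- switch(region, calyx = c(55, 46, 32), LH = c(52, 53, 43))
  template <- c(135, 135, 105)
  lo <- (template - size) / 2
  cbind(min = lo, max = lo + size)
}

#' Generate synthetic axonal arbors as SWC-style skeletons
#'
#' For each neuron class two arbors are grown (one per region): a random walk
#' tree whose segments are pulled toward the class's target locus, with
#' isotropic noise controlled by \code{spread_sd}. Target loci in the LH are
#' structured by planted group (attractive-group classes dorsal, aversive
#' ventral); calyx loci are drawn near-uniformly in the calyx box, making the
#' calyx targeting more distributed than the LH targeting.
#'
#' @param model a \code{ground_truth_model}.
#' @param seed integer seed.
#' @param n_nodes nodes per arbor.
#' @param segment_length mean segment length, micrometres.
#' @param spread_sd s.d. of the directional noise, micrometres.
#' @param regions regions to grow (default both).
#' @return Named list (class id) of lists (region) of
#'   \code{neuron_skeleton} objects.
#' @export
generate_skeletons <- function(model, seed = 1, n_nodes = 120,
                               segment_length = 1.5, spread_sd = 4,
                               regions = c("calyx", "LH")) {
  stopifnot(inherits(model, "ground_truth_model"), spread_sd >= 0)
  loci <- arbor_loci(model, seed)
  with_seed(stage_seed(seed, "skeletons"), {
    out <- lapply(model$class_ids, function(cl) {
      per_region <- lapply(regions, function(rg) {
        grow_arbor(locus = loci[[rg]][cl, ],
                   box = region_box(rg),
                   n_nodes = n_nodes,
                   segment_length = segment_length,
                   spread_sd = spread_sd,
                   class_id = cl, region = rg)
      })
      names(per_region) <- regions
      per_region
    })
    names(out) <- model$class_ids
    out
  })
}

## Target loci per class: LH structured by group along the z (ventral-dorsal)
## axis -- attractive-valence groups dorsal, aversive ventral; calyx loci
## spread across the box.
arbor_loci <- function(model, seed) {
  groups <- model$group_of_glomerulus[model$glomerulus_of_class]
  n_groups <- max(groups)
  # a group is "attractive" if its odors are attractive
  val_of_group <- vapply(seq_len(n_groups), function(g) {
    odors <- names(model$group_of_odor)[model$group_of_odor == g]
    v <- model$panel$valence[match(odors, model$panel$odor_id)]
    names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))
  with_seed(stage_seed(seed, "arbor_loci"), {
    lh <- region_box("LH")
    lh_span <- lh[, "max"] - lh[, "min"]
    centers <- t(vapply(seq_len(n_groups), function(g) {
      zfrac <- if (val_of_group[g] == "attractive") 0.8 else 0.2
      c(lh[1, "min"] + lh_span[1] * stats::runif(1, 0.3, 0.7),
        lh[2, "min"] + lh_span[2] * stats::runif(1, 0.3, 0.7),
        lh[3, "min"] + lh_span[3] * zfrac)
    }, numeric(3)))
    lh_loci <- centers[groups, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(groups), 0, 0.04 * min(lh_span)),
             ncol = 3)
    lh_loci <- clamp_box(lh_loci, lh)
    cx <- region_box("calyx")
    cx_span <- cx[, "max"] - cx[, "min"]
    cx_loci <- sweep(sweep(matrix(stats::runif(3 * length(groups), 0.15, 0.85),
                                  ncol = 3), 2, cx_span, `*`),
                     2, cx[, "min"], `+`)
    rownames(lh_loci) <- rownames(cx_loci) <- model$class_ids
    list(LH = lh_loci, calyx = cx_loci)
  })
}

clamp_box <- function(p, box) {
  for (j in 1:3) p[, j] <- pmin(pmax(p[, j], box[j, "min"]), box[j, "max"])
  p
}

## Random-walk tree: root at a box face near the locus; each step extends a
## random recent tip one segment toward the locus plus isotropic noise.
grow_arbor <- function(locus, box, n_nodes, segment_length, spread_sd,
                       class_id, region) {
  root <- locus
  root[1] <- box[1, "min"]                      # entry from one face
  pos <- matrix(NA_real_, n_nodes, 3)
  parent <- integer(n_nodes)
  pos[1, ] <- root
  parent[1] <- -1L
  for (i in 2:n_nodes) {
    # bias toward recent nodes so the arbor elongates, with side branches
    pi_ <- if (i <= 3) i - 1L else
      sample(seq_len(i - 1L), 1L, prob = seq_len(i - 1L))
    dir <- locus - pos[pi_, ]
    nd <- sqrt(sum(dir^2))
    if (nd > 1e-9) dir <- dir / nd else dir <- c(0, 0, 0)
    step <- dir * segment_length + stats::rnorm(3, 0, spread_sd / 3)
    ns <- sqrt(sum(step^2))
    if (ns < 1e-9) { step <- dir; ns <- 1 }
    p <- pos[pi_, ] + step / ns * segment_length
    pos[i, ] <- pmin(pmax(p, box[, "min"]), box[, "max"])
    parent[i] <- pi_
  }
  new_skeleton(data.frame(id = seq_len(n_nodes), type = 2L,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          radius = 0.5, parent = parent),
               class_id = class_id, region = region)
}
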