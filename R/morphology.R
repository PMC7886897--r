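#' @useDynLib stellate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif approx coef lm nls sd setNames
#' @importFrom utils head read.csv tail write.csv
NULL

# SWC type codes: 1 = soma, 2 = axon, 3 = (basal) dendrite.  The axon
# initial segment has no SWC code; it is identified as the first
# `ais_length` um of axonal path from the soma.
.swc_code <- c(soma = 1L, axon = 2L, dendrite = 3L)

#' Morphology object
#'
#' A neuronal morphology is stored SWC-style as a table of 3D sample points
#' with per-point diameters and parent links, plus metadata. Section labels
#' are `soma`, `dendrite`, `axon` (the AIS is carved out of the proximal
#' axonal path at classification time).
#'
#' @param nodes data frame with columns `id`, `type` (SWC integer code),
#'   `x`, `y`, `z` (um), `radius` (um), `parent` (id or -1 for the root).
#' @param cell_id identifier stored in the metadata.
#' @return An object of class `sc_morphology`.
#' @export
morphology <- function(nodes, cell_id = "cell") {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes))) stop("missing SWC columns")
  if (any(nodes$radius <= 0)) stop("all radii must be positive")
  roots <- sum(nodes$parent == -1)
  if (roots != 1) stop("topology error: expected 1 root, found ", roots)
  if (!all(nodes$parent %in% c(-1, nodes$id)))
    stop("topology error: dangling parent reference")
  structure(list(nodes = nodes, meta = list(cell_id = cell_id, units = "um")),
            class = "sc_morphology")
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments
#' allowed. Exactly one root (parent -1) is required.
#'
#' @param path file path.
#' @return An [morphology()] object.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop("malformed SWC record at line ", idx[bad[1]])
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (any(!is.finite(m)))
    stop("malformed SWC record at line ",
         idx[which(rowSums(!is.finite(m)) > 0)[1]])
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  morphology(nodes, cell_id = sub("\\.swc$", "", basename(path)))
}

#' Write a morphology to an SWC file
#'
#' @param morph an [morphology()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "sc_morphology"))
  n <- morph$nodes
  if (!all(n$type %in% .swc_code))
    stop("unmappable section type code: ", setdiff(n$type, .swc_code)[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC export, cell %s", morph$meta$cell_id), con)
  writeLines(sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                     n$id, n$type, n$x, n$y, n$z, n$radius, n$parent), con)
  invisible(path)
}

# per-node distance to parent (um); root contributes 0
.edge_lengths <- function(nodes) {
  pidx <- match(nodes$parent, nodes$id)
  len <- sqrt((nodes$x - nodes$x[pidx])^2 +
              (nodes$y - nodes$y[pidx])^2 +
              (nodes$z - nodes$z[pidx])^2)
  len[is.na(len)] <- 0
  len
}

# path distance of each node from the root along the tree (um)
.path_dist <- function(nodes) {
  len <- .edge_lengths(nodes)
  pidx <- match(nodes$parent, nodes$id)
  d <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {           # nodes are in topological order
    d[i] <- if (is.na(pidx[i])) 0 else d[pidx[i]] + len[i]
  }
  d
}

#' Default morphometric targets for the stellate-cell generator
#'
#' Summary statistics of the reconstructed stellate cells: soma surface
#' 42.4 +/- 9.3 um2, total dendritic length 845.2 +/- 121.2 um, 11 +/- 3
#' proximal and 63.5 +/- 14 distal dendritic segments separated at the
#' 0.6 um diameter cut-off, AIS 28.0 +/- 6.7 um and axon 577.9 +/- 225 um.
#'
#' @return Named list of `c(mean, sd)` pairs plus `cutoff_um`.
#' @export
morphometric_targets <- function() {
  list(soma_surface = c(mean = 42.4, sd = 9.3),
       dendritic_length = c(mean = 845.2, sd = 121.2),
       proximal_count = c(mean = 11.0, sd = 3.0),
       distal_count = c(mean = 63.5, sd = 14.0),
       ais_length = c(mean = 28.0, sd = 6.7),
       axon_length = c(mean = 577.9, sd = 225.0),
       cutoff_um = 0.6)
}

# grow a random subtree of `n_seg` segments from tip rows, returning nodes
.grow_segments <- function(start_xyz, start_dir, n_seg, seg_len, diam_range,
                           first_id, parent_id, type = 3L, branch_p = 0.35) {
  nodes <- NULL
  # open tips: list of (x,y,z, dir, parent id, depth)
  tips <- list(list(xyz = start_xyz, dir = start_dir, parent = parent_id,
                    depth = 0))
  id <- first_id
  diams <- sort(runif(n_seg, diam_range[1], diam_range[2]), decreasing = TRUE)
  for (k in seq_len(n_seg)) {
    ti <- sample.int(length(tips), 1)
    tip <- tips[[ti]]
    dir <- tip$dir + rnorm(3, 0, 0.4)
    dir <- dir / sqrt(sum(dir^2))
    L <- seg_len * runif(1, 0.7, 1.3)
    xyz <- tip$xyz + dir * L
    nodes <- rbind(nodes, data.frame(
      id = id, type = type, x = xyz[1], y = xyz[2], z = xyz[3],
      radius = diams[k] / 2, parent = tip$parent))
    newtip <- list(xyz = xyz, dir = dir, parent = id, depth = tip$depth + 1)
    if (runif(1) < branch_p) tips <- c(tips, list(newtip))  # branch: keep old tip too
    else tips[[ti]] <- newtip
    id <- id + 1
  }
  nodes
}

#' Generate a synthetic stellate-cell morphology
#'
#' Draws a random morphology matching the printed stellate-cell
#' morphometrics: a soma (single cylinder matched to the target surface
#' area) emitting 3-4 branched dendritic trees whose segment counts and
#' total length are sampled from the target distributions, with proximal
#' segments at or above the 0.6 um diameter cut-off and distal segments
#' below it (diameters taper from about 1.0 um at the trunk to about 0.3 um
#' at the tips), followed by an axon initial segment and a branched axon.
#'
#' @param targets a [morphometric_targets()] list.
#' @param seed integer random seed.
#' @param max_attempts attempts before giving up on unreachable targets.
#' @return An [morphology()] object.
#' @export
generate_sc_morphology <- function(targets = morphometric_targets(), seed = 1,
                                   max_attempts = 20) {
  stopifnot(all(vapply(targets[1:6], function(t) t[["mean"]] > 0, TRUE)))
  cutoff <- targets$cutoff_um
  if (cutoff <= 0.3 || cutoff >= 1.0)
    stop("generation error: cut-off diameter excludes a dendrite class")
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    draw <- function(t) max(t[["mean"]] + t[["sd"]] * rnorm(1), 0.2 * t[["mean"]])
    soma_s <- draw(targets$soma_surface)
    dend_len <- draw(targets$dendritic_length)
    n_prox <- max(3L, as.integer(round(draw(targets$proximal_count))))
    n_dist <- max(4L, as.integer(round(draw(targets$distal_count))))
    ais_len <- draw(targets$ais_length)
    axon_len <- draw(targets$axon_length)
    n_trunk <- sample(3:4, 1)
    if (n_prox < n_trunk) n_prox <- n_trunk

    # soma: cylinder with L = d, lateral surface pi*d*L = soma_s
    d_soma <- sqrt(soma_s / pi)
    nodes <- data.frame(id = 1:2, type = 1L,
                        x = c(0, 0), y = c(0, d_soma), z = c(0, 0),
                        radius = d_soma / 2, parent = c(-1L, 1L))
    id <- 3L
    # mean segment length so that total dendritic length matches the draw
    seg_len <- dend_len / (n_prox + n_dist)
    prox_per_trunk <- diff(round(seq(0, n_prox, length.out = n_trunk + 1)))
    dist_per_trunk <- diff(round(seq(0, n_dist, length.out = n_trunk + 1)))
    for (tr in seq_len(n_trunk)) {
      ang <- 2 * pi * tr / n_trunk + runif(1, -0.3, 0.3)
      dir <- c(cos(ang), sin(ang), rnorm(1, 0, 0.1))
      dir <- dir / sqrt(sum(dir^2))
      np <- prox_per_trunk[tr]
      if (np < 1) np <- 1
      prox <- .grow_segments(c(0, 0, 0), dir, np, seg_len,
                             c(cutoff + 0.05, 1.0), id, 1L)
      id <- id + np
      # distal subtree continues from the most distal proximal node
      tip_row <- prox[nrow(prox), ]
      nd <- dist_per_trunk[tr]
      if (nd < 1) nd <- 1
      dist <- .grow_segments(c(tip_row$x, tip_row$y, tip_row$z), dir, nd,
                             seg_len, c(0.3, cutoff - 0.02), id, tip_row$id)
      id <- id + nd
      nodes <- rbind(nodes, prox, dist)
    }
    # AIS + axon from the soma, type 2
    n_ais <- 4L
    ais <- data.frame(id = id:(id + n_ais - 1), type = 2L,
                      x = 0, y = -(seq_len(n_ais)) * ais_len / n_ais,
                      z = 0, radius = 0.35, parent = c(1L, id:(id + n_ais - 2)))
    id <- id + n_ais
    n_ax <- 20L
    axon <- .grow_segments(c(0, -ais_len, 0), c(0, -1, 0), n_ax,
                           axon_len / n_ax, c(0.25, 0.45), id,
                           ais$id[n_ais], type = 2L, branch_p = 0.25)
    nodes <- rbind(nodes, ais, axon)
    m <- morphology(nodes, cell_id = sprintf("sc_synthetic_%d", seed))
    mm <- morphometrics(m)
    ok <- abs(mm$dendritic_length - targets$dendritic_length[["mean"]]) <=
      max(targets$dendritic_length[["sd"]], 1e-6) + 1e-6
    if (ok) return(m)
  }
  stop("generation error: targets unreachable after ", max_attempts,
       " attempts")
}

#' Classify morphology nodes into the five electrotonic compartment classes
#'
#' Nodes are mapped to `soma`, `prox_dend`, `dist_dend` (split at the local
#' diameter cut-off), `ais` (axonal path within `ais_length` um of the
#' soma) and `axon`.
#'
#' @param morph an [morphology()] object.
#' @param cutoff_um dendritic diameter cut-off (um, default 0.6).
#' @param ais_length AIS path length (um, default 28).
#' @return Character vector of class labels, one per node.
#' @export
classify_compartments <- function(morph, cutoff_um = 0.6, ais_length = 28) {
  stopifnot(inherits(morph, "sc_morphology"))
  n <- morph$nodes
  if (!any(n$type == 1L)) stop("missing soma")
  cls <- character(nrow(n))
  cls[n$type == 1L] <- "soma"
  dend <- n$type == 3L
  cls[dend & 2 * n$radius >= cutoff_um] <- "prox_dend"
  cls[dend & 2 * n$radius < cutoff_um] <- "dist_dend"
  ax <- n$type == 2L
  if (any(ax)) {
    d <- .path_dist(n)
    cls[ax & d <= ais_length] <- "ais"
    cls[ax & d > ais_length] <- "axon"
  }
  cls
}

#' Morphometric summary of a morphology
#'
#' Computes soma surface (lateral cylinder surface of the soma section),
#' total dendritic length (summed inter-point distances), proximal/distal
#' segment counts at the diameter cut-off, and AIS/axon lengths.
#'
#' @param morph an [morphology()] object.
#' @param cutoff_um dendritic diameter cut-off (um).
#' @param ais_length AIS path length (um).
#' @return List of summary values.
#' @export
morphometrics <- function(morph, cutoff_um = 0.6, ais_length = 28) {
  stopifnot(inherits(morph, "sc_morphology"))
  n <- morph$nodes
  len <- .edge_lengths(n)
  cls <- classify_compartments(morph, cutoff_um, ais_length)
  soma_len <- sum(len[n$type == 1L])
  soma_diam <- mean(2 * n$radius[n$type == 1L])
  list(soma_surface = pi * soma_diam * soma_len,
       dendritic_length = sum(len[n$type == 3L]),
       proximal_count = sum(cls == "prox_dend"),
       distal_count = sum(cls == "dist_dend"),
       ais_length = sum(len[cls == "ais"]),
       axon_length = sum(len[cls == "axon"]),
       n_nodes = nrow(n))
}
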