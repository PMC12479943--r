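#' Read a neuron reconstruction from an SWC file
#'
#' Standard 7-column SWC: id, type, x, y, z, radius, parent (um
#' coordinates; parent -1 marks the root; type codes 1 soma, 2 axon,
#' 3 basal dendrite, 4 apical dendrite).
#'
#' @param path SWC file path.
#' @return a `neuron_morphology` data.frame with columns `id`, `type`,
#'   `x`, `y`, `z`, `radius`, `parent`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 7) stop("SWC must have 7 columns")
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                   parent = as.integer(m[, 7]))
  validate_morphology(df)
}

#' Write a neuron reconstruction to an SWC file
#'
#' @param morph a `neuron_morphology` data.frame.
#' @param path output path.
#' @export
write_swc <- function(morph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  utils::write.table(morph[, c("id", "type", "x", "y", "z", "radius",
                               "parent")],
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Validate a reconstruction table as a rooted tree
#'
#' Exactly one root (parent -1), every parent precedes its child, and the
#' parent links form a tree (acyclic by construction once ordering holds).
#'
#' @param morph data.frame with SWC columns.
#' @return the validated `neuron_morphology`.
#' @export
validate_morphology <- function(morph) {
  needed <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(all(needed %in% names(morph)))
  roots <- sum(morph$parent == -1)
  if (roots != 1) stop("reconstruction must have exactly one root, found ",
                       roots)
  if (anyDuplicated(morph$id)) stop("duplicate node ids")
  pos <- match(morph$parent, morph$id)
  nonroot <- morph$parent != -1
  if (any(is.na(pos[nonroot]))) stop("parent id not present in the table")
  if (any(pos[nonroot] >= seq_len(nrow(morph))[nonroot])) {
    stop("every parent must precede its children (cycle or bad ordering)")
  }
  class(morph) <- c("neuron_morphology", "data.frame")
  morph
}

#' Correct reconstruction coordinates for tissue shrinkage
#'
#' Histological processing shrinks the tissue; coordinates are rescaled by
#' multiplicative factors, by default 1.1x in the imaging plane (x-y) and
#' 2.1x along the optical axis (z). Topology and type labels are
#' untouched.
#'
#' @param morph a `neuron_morphology`.
#' @param f_xy in-plane correction factor, > 0 (default 1.1).
#' @param f_z axial correction factor, > 0 (default 2.1).
#' @return the corrected `neuron_morphology`.
#' @export
apply_shrinkage_correction <- function(morph, f_xy = 1.1, f_z = 2.1) {
  if (f_xy <= 0 || f_z <= 0) stop("shrinkage factors must be positive")
  morph <- validate_morphology(morph)
  morph$x <- morph$x * f_xy
  morph$y <- morph$y * f_xy
  morph$z <- morph$z * f_z
  morph
}

# SWC type codes treated as dendrite (basal + apical)
.dendrite_types <- c(3L, 4L)

#' Dendritic morphometric summary
#'
#' Total dendritic length is the sum of Euclidean parent-child distances
#' over dendrite-labelled nodes; primary dendrites are dendrite children
#' of the soma; bifurcation nodes are dendrite nodes with two or more
#' dendrite children (trifurcations count once); terminal endings are
#' dendrite leaves. Axon-labelled nodes never contribute.
#'
#' For strictly binary dendritic trees the Euler identity
#' endings = bifurcations + primary dendrites holds.
#'
#' @param morph a `neuron_morphology`.
#' @return list with `total_dendritic_length` (um),
#'   `n_primary_dendrites`, `n_bifurcation_nodes`, `n_terminal_endings`.
#' @export
morphometric_summary <- function(morph) {
  morph <- validate_morphology(morph)
  dend <- morph$type %in% .dendrite_types
  if (!any(dend)) stop("no dendrite-labelled nodes present")
  pos <- match(morph$parent, morph$id)

  seg_len <- rep(0, nrow(morph))
  has_parent <- morph$parent != -1
  idx <- which(dend & has_parent)
  p <- pos[idx]
  seg_len[idx] <- sqrt((morph$x[idx] - morph$x[p])^2 +
                       (morph$y[idx] - morph$y[p])^2 +
                       (morph$z[idx] - morph$z[p])^2)

  parent_type <- morph$type[pos]
  n_primary <- sum(dend & has_parent & parent_type == 1L, na.rm = TRUE)

  # dendrite children per node
  child_cnt <- integer(nrow(morph))
  tab <- table(factor(pos[which(dend & has_parent)],
                      levels = seq_len(nrow(morph))))
  child_cnt <- as.integer(tab)
  n_bif <- sum(dend & child_cnt >= 2)
  n_term <- sum(dend & child_cnt == 0)

  list(total_dendritic_length = sum(seg_len),
       n_primary_dendrites = n_primary,
       n_bifurcation_nodes = n_bif,
       n_terminal_endings = n_term)
}

#' Generate a toy dendritic tree with known metrics
#'
#' A soma node plus one primary dendrite that bifurcates
#' `n_bifurcations` times; every branch point is strictly binary, so the
#' Euler identity (endings = bifurcations + primaries) holds by
#' construction. With `balanced = TRUE` bifurcations fill the tree level
#' by level; otherwise each new bifurcation is attached to a uniformly
#' random terminal (seeded), generating varied topologies for property
#' tests.
#'
#' @param n_bifurcations number of binary branch points, >= 0.
#' @param segment_length length of every parent-child segment, um.
#' @param segments_per_branch straight run of segments between branch
#'   points (and on terminal branches).
#' @param balanced balanced vs random topology.
#' @param seed seed for the random topology.
#' @return a `neuron_morphology`.
#' @export
generate_toy_morphology <- function(n_bifurcations = 3, segment_length = 10,
                                    segments_per_branch = 1,
                                    balanced = TRUE, seed = 1L) {
  stopifnot(n_bifurcations >= 0, segment_length > 0,
            segments_per_branch >= 1)
  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = 5, parent = -1L))
  nid <- 1L
  add_node <- function(parent, type, x, y, z) {
    nid <<- nid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      id = nid, type = type, x = x, y = y, z = z, radius = 0.5,
      parent = parent)
    nid
  }
  # grow a straight run of `segments_per_branch` segments in direction dir
  grow_branch <- function(parent, origin, dir) {
    p <- parent; o <- origin
    for (s in seq_len(segments_per_branch)) {
      o <- o + segment_length * dir
      p <- add_node(p, 3L, o[1], o[2], o[3])
    }
    list(id = p, pos = o, dir = dir)
  }
  rot <- function(dir, ang) {
    c(cos(ang) * dir[1] - sin(ang) * dir[2],
      sin(ang) * dir[1] + cos(ang) * dir[2], dir[3])
  }

  # primary dendrite starts at the soma position
  tips <- list(grow_branch(1L, c(0, 0, 0), c(0, 1, 0)))
  if (n_bifurcations > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    for (bif in seq_len(n_bifurcations)) {
      pick <- if (balanced) 1L else sample.int(length(tips), 1L)
      tip <- tips[[pick]]
      tips[[pick]] <- NULL
      left <- grow_branch(tip$id, tip$pos, rot(tip$dir, pi / 7))
      right <- grow_branch(tip$id, tip$pos, rot(tip$dir, -pi / 7))
      tips <- c(tips, list(left, right))
    }
  }
  validate_morphology(do.call(rbind, rows))
}
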