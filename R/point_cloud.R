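#' Construct a point cloud
#'
#' A `point_cloud` holds gravity-aligned 3D points (z-up: the zenith is
#' `(0, 0, 1)`), in metres once rescaled (arbitrary units before), with
#' optional per-point colour, organ-label and surface-normal channels.
#'
#' @param points numeric matrix with one row per point and columns x, y, z.
#' @param colors optional integer matrix (n x 3) of RGB values in 0--255.
#' @param labels optional integer vector of per-point organ label ids.
#' @param normals optional numeric matrix (n x 3) of unit surface normals
#'   (written by the synthetic generator; required by [degrade()]).
#' @return an object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
#' n_points(pc)
#' @export
point_cloud <- function(points, colors = NULL, labels = NULL, normals = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 3)
    stop("'points' must be an n x 3 matrix")
  if (nrow(points) < 1) stop("empty cloud: at least one point is required")
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("non-finite coordinates in 'points'")
  colnames(points) <- c("x", "y", "z")
  n <- nrow(points)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (nrow(colors) != n || ncol(colors) != 3)
      stop("'colors' must have exactly one RGB row per point")
    storage.mode(colors) <- "integer"
    if (any(colors < 0L | colors > 255L)) stop("'colors' must lie in 0-255")
    colnames(colors) <- c("red", "green", "blue")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n)
      stop("'labels' must have exactly one entry per point")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (nrow(normals) != n || ncol(normals) != 3)
      stop("'normals' must have exactly one row per point")
    storage.mode(normals) <- "double"
  }
  structure(list(points = points, colors = colors, labels = labels,
                 normals = normals),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s%s%s>\n", nrow(x$points),
              if (!is.null(x$colors)) ", rgb" else "",
              if (!is.null(x$labels)) ", labels" else "",
              if (!is.null(x$normals)) ", normals" else ""))
  rng <- apply(x$points, 2, range)
  cat(sprintf("  x: [%.4g, %.4g]  y: [%.4g, %.4g]  z: [%.4g, %.4g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

## Subset a cloud to row indices, preserving all channels.
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              colors = if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx],
              normals = if (!is.null(cloud$normals)) cloud$normals[idx, , drop = FALSE])
}

#' Reference markers for metric rescaling
#'
#' Markers are physical references of known size placed in the scene (the
#' platform uses four 10 mm disc markers on each pot). Rescaling needs one
#' designated pair with a known metric separation; further pairs with known
#' distances may be supplied and are checked for scale consistency.
#'
#' @param positions numeric matrix (m x 3) of marker centres, in cloud units.
#' @param known_distance_m true metric distance (metres, > 0) between the
#'   designated pair.
#' @param pair integer length-2: row indices of the designated marker pair.
#' @param extra_pairs optional data.frame with columns `i`, `j`, `dist_m`
#'   giving additional pairs of known metric distance, used only for the
#'   consistency check in [rescale_with_markers()].
#' @return an object of class `marker_set`.
#' @export
marker_set <- function(positions, known_distance_m, pair = c(1L, 2L),
                       extra_pairs = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 2)
    stop("'positions' must be an m x 3 matrix with m >= 2")
  storage.mode(positions) <- "double"
  pair <- as.integer(pair)
  if (length(pair) != 2 || pair[1] == pair[2] ||
      any(pair < 1L) || any(pair > nrow(positions)))
    stop("designated 'pair' indices must be two distinct in-range rows")
  if (!is.numeric(known_distance_m) || length(known_distance_m) != 1 ||
      known_distance_m <= 0)
    stop("'known_distance_m' must be a single positive number")
  if (!is.null(extra_pairs)) {
    stopifnot(is.data.frame(extra_pairs),
              all(c("i", "j", "dist_m") %in% names(extra_pairs)))
  }
  structure(list(positions = positions, known_distance_m = known_distance_m,
                 pair = pair, extra_pairs = extra_pairs),
            class = "marker_set")
}

#' Organ-segmented plant cloud
#'
#' Partition of a cloud into a principal stem, indexed petioles/branches and
#' indexed single leaves. Index sets are 1-based row indices into the cloud,
#' must be disjoint, and the stem set must be non-empty. Invalid partitions
#' raise errors; they are never silently repaired.
#'
#' @param cloud a [point_cloud()].
#' @param stem integer vector of stem point indices (non-empty).
#' @param branches list of integer vectors, one per petiole/branch, in order.
#' @param leaves list of integer vectors, one per single leaf, in order.
#' @return an object of class `segmented_plant`.
#' @export
segmented_plant <- function(cloud, stem, branches = list(), leaves = list()) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  stem <- as.integer(stem)
  branches <- lapply(branches, as.integer)
  leaves <- lapply(leaves, as.integer)
  if (length(stem) == 0) stop("missing stem: the stem index set is empty")
  all_sets <- c(list(stem = stem),
                stats::setNames(branches, if (length(branches))
                  paste0("branch_", seq_along(branches)) else NULL),
                stats::setNames(leaves, if (length(leaves))
                  paste0("leaf_", seq_along(leaves)) else NULL))
  for (nm in names(all_sets)) {
    s <- all_sets[[nm]]
    if (any(s < 1L | s > n))
      stop("index out of range in organ '", nm, "': cloud has ", n, " points")
  }
  all_idx <- unlist(all_sets, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    dup <- all_idx[duplicated(all_idx)][1]
    owners <- names(all_sets)[vapply(all_sets, function(s) dup %in% s, logical(1))]
    stop("overlapping segmentation: point index ", dup,
         " assigned to more than one organ (", paste(owners, collapse = ", "), ")")
  }
  structure(list(cloud = cloud, stem = stem, branches = branches,
                 leaves = leaves),
            class = "segmented_plant")
}

#' @export
print.segmented_plant <- function(x, ...) {
  cat(sprintf("<segmented_plant: %d points; stem %d, %d branch(es), %d leaf(s)>\n",
              n_points(x$cloud), length(x$stem), length(x$branches),
              length(x$leaves)))
  invisible(x)
}
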