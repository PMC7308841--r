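#' Locate the height key points of a segmented plant
#'
#' `p1` is the lowest point of the whole dense cloud, `p3` the highest point
#' of the main stem, `p2` the stem point nearest (in z) to the mid-height
#' `(p1.z + p3.z) / 2`, and `p4[[j]]` the lowest point of petiole/branch `j`.
#' Ties are broken by lowest point index.
#'
#' @param plant a [segmented_plant()].
#' @return list with components `p1`, `p2`, `p3` (length-3 xyz, metres) and
#'   `p4` (list of xyz per branch).
#' @export
locate_keypoints <- function(plant) {
  stopifnot(inherits(plant, "segmented_plant"))
  pts <- plant$cloud$points
  p1 <- pts[which.min(pts[, 3]), ]
  stem_pts <- pts[plant$stem, , drop = FALSE]
  p3 <- stem_pts[which.max(stem_pts[, 3]), ]
  mid_z <- (p1[3] + p3[3]) / 2
  p2 <- stem_pts[which.min(abs(stem_pts[, 3] - mid_z)), ]
  p4 <- lapply(plant$branches, function(idx) {
    if (length(idx) == 0) return(c(NA_real_, NA_real_, NA_real_))
    b <- pts[idx, , drop = FALSE]
    b[which.min(b[, 3]), ]
  })
  list(p1 = unname(p1), p2 = unname(p2), p3 = unname(p3),
       p4 = lapply(p4, unname))
}

#' Straight-line Euclidean distance between two points
#'
#' Heights are defined as straight-line distances in Euclidean space, not
#' vertical drops, so a tilted stem reports its axis length.
#'
#' @param a,b length-3 xyz coordinates (metres).
#' @return distance in metres.
#' @export
euclidean_height <- function(a, b) sqrt(sum((b - a)^2))

#' Plant height from key points
#' @param kp key points from [locate_keypoints()].
#' @return plant height `PH` in cm (distance p1 to p3, x 100).
#' @export
plant_height <- function(kp) 100 * euclidean_height(kp$p1, kp$p3)

#' Branch insertion heights from key points
#' @param kp key points from [locate_keypoints()].
#' @return numeric vector `BH` in cm (distance p1 to each p4), empty if the
#'   plant has no branches.
#' @export
branch_heights <- function(kp) {
  vapply(kp$p4, function(p) 100 * euclidean_height(kp$p1, p), numeric(1))
}

#' Select stem points within a ring around a centroid
#'
#' The default `"slab"` geometry keeps stem points with
#' `|z - centroid.z| <= radius` (preserving the horizontal cross-section
#' whose x/y ranges define the diameter); `"ball"` keeps points within
#' Euclidean distance `radius` of the centroid.
#'
#' @param stem_points n x 3 matrix of stem coordinates (metres).
#' @param centroid length-3 xyz ring centre.
#' @param radius ring radius in metres (> 0).
#' @param geometry `"slab"` (default) or `"ball"`.
#' @return list with `centroid`, `radius`, `selected` (indices into
#'   `stem_points`), `rangeX`, `rangeY` (metres; `NA` when the selection is
#'   empty).
#' @export
ring_select <- function(stem_points, centroid, radius,
                        geometry = c("slab", "ball")) {
  geometry <- match.arg(geometry)
  if (radius <= 0) stop("'radius' must be > 0")
  stem_points <- as.matrix(stem_points)
  sel <- if (geometry == "slab") {
    which(abs(stem_points[, 3] - centroid[3]) <= radius)
  } else {
    d2 <- (stem_points[, 1] - centroid[1])^2 +
      (stem_points[, 2] - centroid[2])^2 +
      (stem_points[, 3] - centroid[3])^2
    which(d2 <= radius^2)
  }
  rX <- if (length(sel)) diff(range(stem_points[sel, 1])) else NA_real_
  rY <- if (length(sel)) diff(range(stem_points[sel, 2])) else NA_real_
  list(centroid = centroid, radius = radius, selected = sel,
       rangeX = rX, rangeY = rY)
}

#' Stem diameter from a ring selection
#'
#' The default `"range"` mode returns `min(rangeX, rangeY)`: on a fully
#' sampled circular cross-section this is the diameter. The `"half_range"`
#' mode returns `min(rangeX / 2, rangeY / 2)` (which on a full circle is the
#' radius); it is retained as the literal reading of the published formula.
#'
#' @param sel a ring selection from [ring_select()].
#' @param mode `"range"` (default) or `"half_range"`.
#' @return diameter estimate in mm, or `NA` (with a `"reason"` attribute)
#'   when the selection has fewer than 3 points.
#' @export
ring_diameter <- function(sel, mode = c("range", "half_range")) {
  mode <- match.arg(mode)
  if (length(sel$selected) < 3)
    return(structure(NA_real_, reason = "insufficient points in ring"))
  d <- min(sel$rangeX, sel$rangeY)
  if (mode == "half_range") d <- d / 2
  1000 * d
}

#' Basal, half-plant and apical stem diameters
#'
#' Applies [ring_select()] + [ring_diameter()] with `p1`, `p2` and `p3` as
#' ring centroids. Per-ring failures yield `NA` for that diameter only.
#'
#' @param plant a [segmented_plant()].
#' @param kp key points from [locate_keypoints()].
#' @param radius ring radius in metres (default 5 mm; species-dependent).
#' @param geometry,mode passed to [ring_select()] and [ring_diameter()].
#' @return named numeric vector `c(BD, HD, AD)` in mm.
#' @export
stem_diameters <- function(plant, kp, radius = 0.005,
                           geometry = c("slab", "ball"),
                           mode = c("range", "half_range")) {
  geometry <- match.arg(geometry)
  mode <- match.arg(mode)
  stem_pts <- plant$cloud$points[plant$stem, , drop = FALSE]
  one <- function(centroid)
    ring_diameter(ring_select(stem_pts, centroid, radius, geometry), mode)
  c(BD = one(kp$p1), HD = one(kp$p2), AD = one(kp$p3))
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal distances: the
#' centroid is the mean point and the normal is the smallest principal
#' direction of the centred coordinates. The normal sign is fixed for
#' reproducibility: non-negative z, then (if z = 0) non-negative x, then y.
#'
#' @param points n x 3 matrix (n >= 3, non-collinear).
#' @return list with `normal` (unit length-3), `centroid`, `rms_residual`
#'   (metres).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("degenerate fit: need at least 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x, nu = 0)
  if (sv$d[2] <= max(sv$d[1], .Machine$double.eps) * 1e-8)
    stop("degenerate fit: points are collinear or coincident")
  normal <- sv$v[, 3]
  tol <- 1e-12
  if (normal[3] < -tol) normal <- -normal
  else if (abs(normal[3]) <= tol) {
    if (normal[1] < -tol) normal <- -normal
    else if (abs(normal[1]) <= tol && normal[2] < 0) normal <- -normal
  }
  normal <- normal / vec_norm(normal)
  list(normal = unname(normal), centroid = unname(ctr),
       rms_residual = sv$d[3] / sqrt(nrow(points)))
}

#' Leaf inclination angle
#'
#' The angle between the normal of the best-fitting plane through the leaf
#' points and the zenith `(0, 0, 1)`, folded into `[0, 90]` degrees (so the
#' result does not depend on the normal's sign): 0 for a horizontal leaf,
#' 90 for a vertical one.
#'
#' @param leaf_points n x 3 matrix of leaf coordinates.
#' @return `LI` in degrees, or `NA` (with `"reason"`) on a degenerate fit.
#' @export
leaf_inclination <- function(leaf_points) {
  fit <- tryCatch(fit_plane(leaf_points), error = function(e) NULL)
  if (is.null(fit)) return(structure(NA_real_, reason = "degenerate plane fit"))
  rad2deg(acos(clamp(abs(fit$normal[3]), 0, 1)))
}

#' Petiole/branch inclination angle
#'
#' Default `"axis"` mode: the principal (largest-variance) direction of the
#' centred branch points, oriented from the branch end nearest `origin`
#' (normally the stem centroid) toward the far end; `BI` is the angle
#' between that vector and the zenith, in `[0, 180]` degrees (0 = pointing
#' straight up). When `origin` is `NULL` the axis is oriented to
#' non-negative z (then x, then y), confining the angle to `[0, 90]`.
#' `"plane"` mode is the literal plane-based reading:
#' `90 - ` the plane-normal zenith angle, in `[0, 90]`.
#'
#' @param branch_points n x 3 matrix (n >= 3, non-degenerate spread).
#' @param mode `"axis"` (default) or `"plane"`.
#' @param origin optional length-3 reference point fixing the axis direction.
#' @return `BI` in degrees, or `NA` (with `"reason"`) on degenerate spread.
#' @export
branch_inclination <- function(branch_points, mode = c("axis", "plane"),
                               origin = NULL) {
  mode <- match.arg(mode)
  branch_points <- as.matrix(branch_points)
  if (mode == "plane") {
    li <- leaf_inclination(branch_points)
    if (is.na(li)) return(li)
    return(90 - li)
  }
  if (nrow(branch_points) < 3)
    return(structure(NA_real_, reason = "fewer than 3 points"))
  ctr <- colMeans(branch_points)
  x <- sweep(branch_points, 2, ctr)
  sv <- svd(x, nu = 0)
  if (sv$d[1] <= .Machine$double.eps)
    return(structure(NA_real_, reason = "degenerate spread"))
  axis <- sv$v[, 1]
  t_proj <- x %*% axis
  if (!is.null(origin)) {
    lo <- branch_points[which.min(t_proj), ]
    hi <- branch_points[which.max(t_proj), ]
    near_is_lo <- vec_norm(lo - origin) <= vec_norm(hi - origin)
    if (!near_is_lo) axis <- -axis
  } else {
    tol <- 1e-12
    if (axis[3] < -tol) axis <- -axis
    else if (abs(axis[3]) <= tol) {
      if (axis[1] < -tol) axis <- -axis
      else if (abs(axis[1]) <= tol && axis[2] < 0) axis <- -axis
    }
  }
  rad2deg(acos(clamp(axis[3] / vec_norm(axis), -1, 1)))
}

#' Convex-hull leaf area
#'
#' Projects the leaf points onto their total-least-squares plane and returns
#' the area of the 2D convex hull of the projection; interior voids are
#' included by construction.
#'
#' @param leaf_points n x 3 matrix (n >= 3, non-collinear).
#' @return `LA` in cm^2, or `NA` (with `"reason"`) on a degenerate fit.
#' @export
leaf_area <- function(leaf_points) {
  leaf_points <- as.matrix(leaf_points)
  fit <- tryCatch(fit_plane(leaf_points), error = function(e) NULL)
  if (is.null(fit)) return(structure(NA_real_, reason = "degenerate plane fit"))
  ## orthonormal in-plane basis
  ref <- if (abs(fit$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(ref - sum(ref * fit$normal) * fit$normal)
  e2 <- c(fit$normal[2] * e1[3] - fit$normal[3] * e1[2],
          fit$normal[3] * e1[1] - fit$normal[1] * e1[3],
          fit$normal[1] * e1[2] - fit$normal[2] * e1[1])
  x <- sweep(leaf_points, 2, fit$centroid)
  u <- x %*% e1
  v <- x %*% e2
  h <- chull(u, v)
  if (length(h) < 3)
    return(structure(NA_real_, reason = "degenerate hull"))
  1e4 * polygon_area(u[h], v[h])
}

#' Extraction parameters
#'
#' @param ring_radius_mm ring radius for stem diameters, mm (default 5;
#'   intended to be set per species).
#' @param ring_geometry `"slab"` or `"ball"` (see [ring_select()]).
#' @param diameter_mode `"range"` or `"half_range"` (see [ring_diameter()]).
#' @param bi_mode `"axis"` or `"plane"` (see [branch_inclination()]).
#' @return list of class `extract_config`.
#' @export
extract_config <- function(ring_radius_mm = 5, ring_geometry = "slab",
                           diameter_mode = "range", bi_mode = "axis") {
  stopifnot(ring_radius_mm > 0)
  structure(list(ring_radius_mm = ring_radius_mm,
                 ring_geometry = match.arg(ring_geometry, c("slab", "ball")),
                 diameter_mode = match.arg(diameter_mode, c("range", "half_range")),
                 bi_mode = match.arg(bi_mode, c("axis", "plane"))),
            class = "extract_config")
}

#' Extract the full trait set from a segmented plant
#'
#' Composes [locate_keypoints()], [plant_height()], [branch_heights()],
#' [stem_diameters()], [branch_inclination()] per branch and
#' [leaf_inclination()] / [leaf_area()] per leaf. Per-organ failures become
#' explicit missing values (logged with organ id and reason, and counted for
#' the Sw weighting adjustment downstream); they never abort the record.
#' An empty stem is the only fatal error.
#'
#' @param plant a [segmented_plant()].
#' @param config an [extract_config()].
#' @param plant_id id recorded in the output.
#' @return a [trait_record()] with a `missing_log` attribute; the extraction
#'   configuration is stored in the `"config"` attribute.
#' @examples
#' spec <- synthetic_plant_spec("tomato_like", seed = 1)
#' gp <- generate_plant(spec, density = 40)
#' extract_traits(gp$plant)
#' @export
extract_traits <- function(plant, config = extract_config(),
                           plant_id = "plant") {
  stopifnot(inherits(plant, "segmented_plant"),
            inherits(config, "extract_config"))
  log <- list()
  note <- function(trait, organ, reason)
    log[[length(log) + 1L]] <<- data.frame(trait = trait,
                                           organ_index = as.integer(organ),
                                           reason = reason)
  kp <- locate_keypoints(plant)
  PH <- plant_height(kp)
  BH <- branch_heights(kp)
  for (j in seq_along(BH))
    if (is.na(BH[j])) note("BH", j, "empty branch cloud")
  D <- stem_diameters(plant, kp, radius = config$ring_radius_mm / 1000,
                      geometry = config$ring_geometry,
                      mode = config$diameter_mode)
  for (nm in names(D))
    if (is.na(D[[nm]])) note(nm, 0L, attr(D[[nm]], "reason") %||% "ring failure")
  pts <- plant$cloud$points
  stem_centroid <- colMeans(pts[plant$stem, , drop = FALSE])
  BI <- vapply(seq_along(plant$branches), function(j) {
    v <- branch_inclination(pts[plant$branches[[j]], , drop = FALSE],
                            mode = config$bi_mode, origin = stem_centroid)
    if (is.na(v)) note("BI", j, attr(v, "reason") %||% "degenerate")
    as.numeric(v)
  }, numeric(1))
  LI <- vapply(seq_along(plant$leaves), function(j) {
    v <- leaf_inclination(pts[plant$leaves[[j]], , drop = FALSE])
    if (is.na(v)) note("LI", j, attr(v, "reason") %||% "degenerate")
    as.numeric(v)
  }, numeric(1))
  LA <- vapply(seq_along(plant$leaves), function(j) {
    v <- leaf_area(pts[plant$leaves[[j]], , drop = FALSE])
    if (is.na(v)) note("LA", j, attr(v, "reason") %||% "degenerate")
    as.numeric(v)
  }, numeric(1))
  ml <- if (length(log)) do.call(rbind, log) else NULL
  rec <- trait_record(plant_id = plant_id, PH = PH, BH = BH,
                      BD = D[["BD"]], HD = D[["HD"]], AD = D[["AD"]],
                      BI = BI, LI = LI, LA = LA, missing_log = ml)
  attr(rec, "config") <- config
  rec
}
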