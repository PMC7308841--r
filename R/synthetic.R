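## Synthetic plant generator: three canopy archetypes with exact ground truth.
## Stands in for the camera + SfM front end so every downstream stage can be
## tested at desk scale against known trait values.

#' Specification of a synthetic plant
#'
#' Draws a randomised but reproducible plant of one of three canopy
#' archetypes, sized within the ranges typical of the crops they emulate:
#' `"maize_like"` (erect monocot: single stem, sessile curled ribbon leaves),
#' `"tomato_like"` (petiolate herb: petioles each bearing one ribbon leaf)
#' and `"olive_like"` (woody evergreen: branches bearing flat elliptical
#' leaves; curl is always 0). All dimensions can be overridden after
#' construction, subject to basal >= half >= apical diameter.
#'
#' @param archetype one of `"maize_like"`, `"tomato_like"`, `"olive_like"`.
#' @param seed RNG seed; the spec (and every cloud generated from it) is a
#'   pure function of `(archetype, seed)`.
#' @return object of class `synthetic_plant_spec`: list with `archetype`,
#'   `seed`, `stem` (height_m, tilt_deg, basal_mm, half_mm, apical_mm),
#'   `branches` (data.frame: insertion_frac, inclination_deg, length_m,
#'   diameter_mm, azimuth_deg) and `leaves` (data.frame: shape, attach_organ,
#'   attach_index, attach_frac, azimuth_deg, tilt_deg, curl, dim1_m, dim2_m;
#'   for ellipses dim1/dim2 are the semi-axes, for ribbons length/width).
#' @export
synthetic_plant_spec <- function(archetype = c("maize_like", "tomato_like",
                                               "olive_like"),
                                 seed = 1L) {
  archetype <- match.arg(archetype)
  with_seed(derive_seed(seed, 101L), {
    if (archetype == "maize_like") {
      h <- runif(1, 0.35, 0.55)
      bd <- runif(1, 12, 16); hd <- bd * runif(1, 0.68, 0.78)
      ad <- hd * runif(1, 0.55, 0.70)
      stem <- list(height_m = h, tilt_deg = runif(1, 0, 4),
                   basal_mm = bd, half_mm = hd, apical_mm = ad)
      branches <- empty_branches()
      nl <- sample(5:7, 1)
      leaves <- data.frame(
        shape = "ribbon", attach_organ = "stem", attach_index = 0L,
        attach_frac = seq(0.3, 0.9, length.out = nl) +
          runif(nl, -0.02, 0.02),
        azimuth_deg = (seq_len(nl) %% 2) * 180 + runif(nl, -25, 25),
        tilt_deg = runif(nl, 25, 55), curl = runif(nl, 0.2, 0.5),
        dim1_m = runif(nl, 0.18, 0.28), dim2_m = runif(nl, 0.02, 0.035))
    } else if (archetype == "tomato_like") {
      h <- runif(1, 0.25, 0.40)
      bd <- runif(1, 7, 10); hd <- bd * runif(1, 0.70, 0.80)
      ad <- hd * runif(1, 0.55, 0.70)
      stem <- list(height_m = h, tilt_deg = runif(1, 0, 4),
                   basal_mm = bd, half_mm = hd, apical_mm = ad)
      nb <- sample(4:6, 1)
      branches <- data.frame(
        insertion_frac = sort(runif(nb, 0.35, 0.95)),
        inclination_deg = runif(nb, 40, 70),
        length_m = runif(nb, 0.08, 0.15),
        diameter_mm = runif(nb, 2.5, 4),
        azimuth_deg = (seq_len(nb) * 137.5 + runif(nb, -15, 15)) %% 360)
      leaves <- data.frame(
        shape = "ribbon", attach_organ = "branch",
        attach_index = seq_len(nb), attach_frac = 1,
        azimuth_deg = branches$azimuth_deg,
        tilt_deg = runif(nb, 15, 45), curl = runif(nb, 0.1, 0.4),
        dim1_m = runif(nb, 0.07, 0.12), dim2_m = runif(nb, 0.03, 0.05))
    } else {
      h <- runif(1, 0.70, 1.00)
      bd <- runif(1, 15, 20); hd <- bd * runif(1, 0.70, 0.80)
      ad <- hd * runif(1, 0.60, 0.75)
      stem <- list(height_m = h, tilt_deg = runif(1, 0, 3),
                   basal_mm = bd, half_mm = hd, apical_mm = ad)
      nb <- sample(5:7, 1)
      branches <- data.frame(
        insertion_frac = sort(runif(nb, 0.40, 0.95)),
        inclination_deg = runif(nb, 30, 65),
        length_m = runif(nb, 0.20, 0.35),
        diameter_mm = runif(nb, 3, 5),
        azimuth_deg = (seq_len(nb) * 137.5 + runif(nb, -15, 15)) %% 360)
      per_branch <- lapply(seq_len(nb), function(j) data.frame(
        shape = "ellipse", attach_organ = "branch", attach_index = j,
        attach_frac = c(0.65, 1), azimuth_deg =
          (branches$azimuth_deg[j] + runif(2, -30, 30)) %% 360,
        tilt_deg = runif(2, 10, 60), curl = 0,
        dim1_m = {a <- runif(2, 0.025, 0.035); a},
        dim2_m = NA_real_))
      leaves <- do.call(rbind, per_branch)
      leaves$dim2_m <- leaves$dim1_m * runif(nrow(leaves), 0.35, 0.50)
    }
    validate_spec(structure(
      list(archetype = archetype, seed = as.integer(seed), stem = stem,
           branches = branches, leaves = leaves),
      class = "synthetic_plant_spec"))
  })
}

empty_branches <- function() {
  data.frame(insertion_frac = numeric(0), inclination_deg = numeric(0),
             length_m = numeric(0), diameter_mm = numeric(0),
             azimuth_deg = numeric(0))
}

validate_spec <- function(spec) {
  s <- spec$stem
  if (s$height_m <= 0 || s$basal_mm <= 0 || s$apical_mm <= 0)
    stop("invalid spec: stem dimensions must be positive")
  if (!(s$basal_mm >= s$half_mm && s$half_mm >= s$apical_mm))
    stop("invalid spec: need basal >= half >= apical stem diameter")
  if (nrow(spec$branches) &&
      any(spec$branches$length_m <= 0 | spec$branches$diameter_mm <= 0))
    stop("invalid spec: branch dimensions must be positive")
  if (nrow(spec$leaves)) {
    if (any(spec$leaves$dim1_m <= 0 | spec$leaves$dim2_m <= 0))
      stop("invalid spec: leaf dimensions must be positive")
    if (spec$archetype == "olive_like" && any(spec$leaves$curl != 0))
      stop("invalid spec: olive_like leaves must have curl = 0")
    bad <- spec$leaves$attach_organ == "branch" &
      (spec$leaves$attach_index < 1 |
         spec$leaves$attach_index > nrow(spec$branches))
    if (any(bad)) stop("invalid spec: leaf attached to missing branch")
  }
  spec
}

#' @export
print.synthetic_plant_spec <- function(x, ...) {
  cat(sprintf("<synthetic_plant_spec: %s, seed %d; stem %.2f m, %d branch(es), %d leaf(s)>\n",
              x$archetype, x$seed, x$stem$height_m, nrow(x$branches),
              nrow(x$leaves)))
  invisible(x)
}

## stem radius (m) at axis position t, piecewise linear through the three
## control diameters (mm) at 0, h/2, h.
stem_radius_fun <- function(stem) {
  r <- c(stem$basal_mm, stem$half_mm, stem$apical_mm) / 2000
  h <- stem$height_m
  function(t) {
    t <- clamp(t, 0, h)
    ifelse(t <= h / 2,
           r[1] + (r[2] - r[1]) * t / (h / 2),
           r[2] + (r[3] - r[2]) * (t - h / 2) / (h / 2))
  }
}

## orthonormal frame perpendicular to unit axis u
perp_frame <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- unit_vec(ref - sum(ref * u) * u)
  n2 <- c(u[2] * n1[3] - u[3] * n1[2],
          u[3] * n1[1] - u[1] * n1[3],
          u[1] * n1[2] - u[2] * n1[1])
  list(n1 = n1, n2 = n2)
}

## sample N points on a (possibly tapered) cylinder surface; returns points
## and outward radial normals
sample_cylinder <- function(base, u, length, radius_fun, n) {
  fr <- perp_frame(u)
  rmax <- max(radius_fun(seq(0, length, length.out = 64)))
  t <- numeric(0)
  while (length(t) < n) {
    cand <- runif(2 * (n - length(t)) + 16, 0, length)
    acc <- runif(length(cand)) < radius_fun(cand) / rmax
    t <- c(t, cand[acc])
  }
  t <- t[seq_len(n)]
  th <- runif(n, 0, 2 * pi)
  radial <- outer(cos(th), fr$n1) + outer(sin(th), fr$n2)
  pts <- matrix(base, n, 3, byrow = TRUE) + outer(t, u) +
    radial * radius_fun(t)
  list(points = pts, normals = radial)
}

## ribbon leaf midrib: arc-length parametrised curve whose tangent zenith
## angle grows linearly from (90 - tilt) deg by curl * 90 deg over the blade
ribbon_midrib <- function(attach, azimuth_deg, tilt_deg, curl, len, n_grid = 256) {
  psi <- deg2rad(azimuth_deg)
  tg <- seq(0, len, length.out = n_grid)
  theta <- deg2rad(90 - tilt_deg + curl * 90 * tg / len)
  tang <- cbind(sin(theta) * cos(psi), sin(theta) * sin(psi), cos(theta))
  dt <- len / (n_grid - 1)
  pos <- apply(tang, 2, function(c1) cumsum(c(0, (head(c1, -1) + tail(c1, -1)) / 2 * dt)))
  pos <- sweep(pos, 2, -attach)  # add attach
  list(t = tg, pos = pos, tangent = tang,
       w = c(-sin(psi), cos(psi), 0))
}

ribbon_surface <- function(mr, t, v) {
  px <- stats::approx(mr$t, mr$pos[, 1], t)$y
  py <- stats::approx(mr$t, mr$pos[, 2], t)$y
  pz <- stats::approx(mr$t, mr$pos[, 3], t)$y
  tx <- stats::approx(mr$t, mr$tangent[, 1], t)$y
  ty <- stats::approx(mr$t, mr$tangent[, 2], t)$y
  tz <- stats::approx(mr$t, mr$tangent[, 3], t)$y
  w <- mr$w
  pts <- cbind(px + v * w[1], py + v * w[2], pz + v * w[3])
  normals <- cbind(ty * w[3] - tz * w[2],
                   tz * w[1] - tx * w[3],
                   tx * w[2] - ty * w[1])
  list(points = pts, normals = normals / sqrt(rowSums(normals^2)))
}

## perpendicular-to-d unit vector with the most negative z component
## (NULL when d is vertical)
down_perp <- function(d) {
  v <- c(0, 0, 1) - d[3] * d
  n <- vec_norm(v)
  if (n < 1e-9) NULL else -v / n
}

#' Generate a labelled plant cloud with exact ground truth
#'
#' Samples the parametric organ surfaces of a [synthetic_plant_spec()]
#' uniformly at `density` points per cm^2: a tapered stem cylinder,
#' cylindrical petioles/branches, flat elliptical leaves (olive archetype)
#' and curl-parametrised ribbon leaves (maize/tomato archetypes). Per-point
#' organ labels, colours and outward surface normals are emitted (the
#' normals drive [degrade()]'s visibility culling). Ground truth follows the
#' trait definitions of the extraction pipeline: `PH`/`BH` are straight-line
#' distances between the ideal extreme surface points, diameters come from
#' the construction cross-sections, `BI` from the construction inclination,
#' and `LI`/`LA` analytically for flat leaves or from a fine regular-mesh
#' oracle at `oracle_factor` times the sampling density for curled ones.
#' Output is a pure function of `(spec, density)`.
#'
#' @param spec a [synthetic_plant_spec()].
#' @param density surface sampling density, points per cm^2.
#' @param oracle_factor density multiplier of the curled-leaf oracle mesh.
#' @return list with `plant` (a [segmented_plant()] whose cloud carries
#'   labels, colours and normals; generation density in attribute
#'   `"density"`), `truth` (a [trait_record()]), and `truth_provenance`
#'   (named character vector, `"analytic"` or `"oracle"` per trait; the
#'   oracle mesh density is in attribute `"oracle_density"`).
#' @export
generate_plant <- function(spec, density = 150, oracle_factor = 10) {
  stopifnot(inherits(spec, "synthetic_plant_spec"), density > 0)
  with_seed(derive_seed(spec$seed, 202L), {
    st <- spec$stem
    h <- st$height_m
    tilt <- deg2rad(st$tilt_deg)
    u <- c(sin(tilt), 0, cos(tilt))
    base <- c(0, 0, 0)
    rfun <- stem_radius_fun(st)
    area_cm2 <- function(a) a * 1e4
    grid_t <- seq(0, h, length.out = 256)
    stem_area <- sum(2 * pi * rfun(grid_t)) * (h / 255)
    n_stem <- max(200L, round(area_cm2(stem_area) * density))
    stem_s <- sample_cylinder(base, u, h, rfun, n_stem)

    pts_list <- list(stem_s$points)
    nrm_list <- list(stem_s$normals)
    lab_list <- list(rep(0L, n_stem))

    nb <- nrow(spec$branches)
    branch_start <- matrix(NA_real_, nb, 3)
    branch_dir <- matrix(NA_real_, nb, 3)
    for (j in seq_len(nb)) {
      br <- spec$branches[j, ]
      s_j <- br$insertion_frac * h
      phi <- deg2rad(br$azimuth_deg)
      beta <- deg2rad(br$inclination_deg)
      fr <- perp_frame(u)
      radial <- cos(phi) * fr$n1 + sin(phi) * fr$n2
      q <- base + s_j * u + rfun(s_j) * radial
      d <- c(sin(beta) * cos(phi), sin(beta) * sin(phi), cos(beta))
      branch_start[j, ] <- q
      branch_dir[j, ] <- d
      rb <- br$diameter_mm / 2000
      n_b <- max(60L, round(area_cm2(2 * pi * rb * br$length_m) * density))
      bs <- sample_cylinder(q, d, br$length_m, function(t) rep(rb, length(t)), n_b)
      pts_list <- c(pts_list, list(bs$points))
      nrm_list <- c(nrm_list, list(bs$normals))
      lab_list <- c(lab_list, list(rep(j, n_b)))
    }

    nl <- nrow(spec$leaves)
    LI_truth <- LA_truth <- numeric(nl)
    li_flag <- character(nl)
    for (k in seq_len(nl)) {
      lf <- spec$leaves[k, ]
      attach <- if (lf$attach_organ == "stem") {
        s_k <- lf$attach_frac * h
        phi <- deg2rad(lf$azimuth_deg)
        fr <- perp_frame(u)
        base + s_k * u + rfun(s_k) * (cos(phi) * fr$n1 + sin(phi) * fr$n2)
      } else {
        j <- lf$attach_index
        branch_start[j, ] + lf$attach_frac *
          spec$branches$length_m[j] * branch_dir[j, ]
      }
      if (lf$shape == "ellipse") {
        a <- lf$dim1_m; b <- lf$dim2_m
        tau <- deg2rad(lf$tilt_deg); psi <- deg2rad(lf$azimuth_deg)
        nrm <- c(sin(tau) * cos(psi), sin(tau) * sin(psi), cos(tau))
        horiz <- c(cos(psi), sin(psi), 0)
        e1 <- unit_vec(horiz - sum(horiz * nrm) * nrm)
        e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
                nrm[3] * e1[1] - nrm[1] * e1[3],
                nrm[1] * e1[2] - nrm[2] * e1[1])
        n_k <- max(60L, round(area_cm2(pi * a * b) * density))
        rho <- sqrt(runif(n_k)); om <- runif(n_k, 0, 2 * pi)
        ## rim points at matching linear density (the lamina silhouette is a
        ## sampled surface edge, not an open set)
        per_m <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
        n_e <- max(16L, round(per_m * 100 * sqrt(density)))
        om_e <- runif(n_e, 0, 2 * pi)
        rho <- c(rho, rep(1, n_e)); om <- c(om, om_e)
        n_k <- n_k + n_e
        uu <- a * rho * cos(om); vv <- b * rho * sin(om)
        ctr <- attach + a * e1
        pts <- matrix(ctr, n_k, 3, byrow = TRUE) + outer(uu, e1) + outer(vv, e2)
        pts_list <- c(pts_list, list(pts))
        nrm_list <- c(nrm_list, list(matrix(nrm, n_k, 3, byrow = TRUE)))
        LI_truth[k] <- lf$tilt_deg
        LA_truth[k] <- 1e4 * pi * a * b
        li_flag[k] <- "analytic"
      } else {
        len <- lf$dim1_m; wid <- lf$dim2_m
        mr <- ribbon_midrib(attach, lf$azimuth_deg, lf$tilt_deg, lf$curl, len)
        n_k <- max(60L, round(area_cm2(len * wid) * density))
        tt <- runif(n_k, 0, len); vv <- runif(n_k, -wid / 2, wid / 2)
        ## blade margin points at matching linear density
        n_el <- max(8L, round(len * 100 * sqrt(density)))
        n_ew <- max(4L, round(wid * 100 * sqrt(density)))
        tt <- c(tt, runif(n_el, 0, len), runif(n_el, 0, len),
                rep(c(0, len), each = n_ew))
        vv <- c(vv, rep(c(-wid / 2, wid / 2), each = n_el),
                runif(2 * n_ew, -wid / 2, wid / 2))
        rs <- ribbon_surface(mr, tt, vv)
        pts_list <- c(pts_list, list(rs$points))
        nrm_list <- c(nrm_list, list(rs$normals))
        ## fine regular-mesh oracle for the curled lamina
        n_o <- max(600L, round(area_cm2(len * wid) * density * oracle_factor))
        nt_o <- ceiling(sqrt(n_o * len / wid))
        nv_o <- max(4L, ceiling(n_o / nt_o))
        og <- ribbon_surface(mr,
                             rep(seq(0, len, length.out = nt_o), each = nv_o),
                             rep(seq(-wid / 2, wid / 2, length.out = nv_o),
                                 times = nt_o))
        LI_truth[k] <- leaf_inclination(og$points)
        LA_truth[k] <- leaf_area(og$points)
        li_flag[k] <- "oracle"
      }
      lab_list <- c(lab_list, list(rep(nb + k, nrow(pts_list[[length(pts_list)]]))))
    }

    pts <- do.call(rbind, pts_list)
    nrm <- do.call(rbind, nrm_list)
    lab <- unlist(lab_list)
    n_tot <- nrow(pts)
    ## organ-coded colours (green hues for laminae, brownish for woody parts)
    colors <- matrix(0L, n_tot, 3)
    colors[lab == 0L, ] <- matrix(rep(c(110L, 110L, 50L), each = sum(lab == 0L)),
                                  ncol = 3)
    is_branch <- lab >= 1L & lab <= nb
    colors[is_branch, ] <- matrix(rep(c(100L, 130L, 55L), each = sum(is_branch)),
                                  ncol = 3)
    is_leaf <- lab > nb
    colors[is_leaf, ] <- cbind(30L + (which(is_leaf) %% 30L),
                               140L + (which(is_leaf) %% 70L),
                               40L + (which(is_leaf) %% 25L))
    cloud <- point_cloud(pts, colors = colors, labels = lab, normals = nrm)
    plant <- segmented_plant(
      cloud, stem = which(lab == 0L),
      branches = lapply(seq_len(nb), function(j) which(lab == j)),
      leaves = lapply(seq_len(nl), function(k) which(lab == nb + k)))
    attr(plant, "density") <- density
    attr(plant, "spec") <- spec

    ## ---- analytic ground truth -------------------------------------------
    e_dn <- down_perp(u)
    p1_true <- if (is.null(e_dn)) base else base + rfun(0) * e_dn
    e_up <- if (is.null(e_dn)) NULL else -e_dn
    p3_true <- if (is.null(e_up)) base + h * u else base + h * u + rfun(h) * e_up
    PH <- 100 * vec_norm(p3_true - p1_true)
    BH <- vapply(seq_len(nb), function(j) {
      rb <- spec$branches$diameter_mm[j] / 2000
      e_j <- down_perp(branch_dir[j, ])
      low <- if (is.null(e_j)) branch_start[j, ] else branch_start[j, ] + rb * e_j
      100 * vec_norm(low - p1_true)
    }, numeric(1))
    truth <- trait_record(
      plant_id = sprintf("%s_seed%d", spec$archetype, spec$seed),
      PH = PH, BH = BH, BD = st$basal_mm, HD = st$half_mm, AD = st$apical_mm,
      BI = spec$branches$inclination_deg, LI = LI_truth, LA = LA_truth)
    prov <- c(PH = "analytic", BH = "analytic", BD = "analytic",
              HD = "analytic", AD = "analytic", BI = "analytic",
              LI = if (all(li_flag == "analytic") || nl == 0) "analytic" else "oracle",
              LA = if (all(li_flag == "analytic") || nl == 0) "analytic" else "oracle")
    attr(prov, "oracle_density") <- density * oracle_factor
    list(plant = plant, truth = truth, truth_provenance = prov)
  })
}

#' Degradation parameters
#'
#' Emulates the acquisition factors of the imaging platform: image quality
#' maps to surface sampling density and measurement noise, image quantity to
#' azimuthal visibility culling.
#'
#' @param density target sampling density, points/cm^2 (must not exceed the
#'   generation density: points cannot be upsampled).
#' @param n_views number of equally spaced camera azimuths (>= 1), placed at
#'   a 15-degree depression angle.
#' @param noise_sigma isotropic Gaussian noise standard deviation, metres.
#' @param seed RNG seed for subsampling and noise.
#' @return list of class `degradation`.
#' @export
degradation <- function(density, n_views = 90L, noise_sigma = 0,
                        seed = 1L) {
  stopifnot(density > 0, n_views >= 1, noise_sigma >= 0)
  structure(list(density = density, n_views = as.integer(n_views),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "degradation")
}

#' Image-quality presets
#'
#' Named presets standing in for the platform's three image resolutions
#' (H = 4.88, M = 6.52, L = 9.77 um/pixel). Poorer resolution is emulated as
#' jointly lower sampling density and larger point noise; the levels are
#' ordinal stand-ins, not a photogrammetric calibration.
#'
#' @param quality `"H"`, `"M"` or `"L"`.
#' @return list with `density` (points/cm^2) and `noise_sigma` (metres).
#' @export
quality_preset <- function(quality = c("H", "M", "L")) {
  quality <- match.arg(quality)
  switch(quality,
         H = list(density = 160, noise_sigma = 0.0003),
         M = list(density = 80, noise_sigma = 0.0006),
         L = list(density = 40, noise_sigma = 0.0010))
}

#' Degrade a synthetic plant cloud
#'
#' Applies, in order: (i) uniform subsampling to the target density,
#' (ii) visibility culling -- a point survives iff its outward normal has a
#' positive dot product with the direction to at least one of `n_views`
#' equally spaced azimuthal viewpoints (placed on a circle at a 15-degree
#' depression angle), (iii) isotropic Gaussian coordinate noise. Labels,
#' colours and normals of survivors are preserved. Deterministic given the
#' degradation seed, and the subsampling/noise streams do not depend on
#' `n_views`, so view-count comparisons are paired.
#'
#' @param plant a [segmented_plant()] from [generate_plant()] (its cloud
#'   must carry surface normals).
#' @param d a [degradation()].
#' @return the degraded [segmented_plant()]; attribute `"density"` is
#'   updated to the target density.
#' @export
degrade <- function(plant, d) {
  stopifnot(inherits(plant, "segmented_plant"), inherits(d, "degradation"))
  cloud <- plant$cloud
  if (is.null(cloud$normals))
    stop("degrade() needs per-point surface normals from generation")
  gen_density <- attr(plant, "density")
  if (is.null(gen_density))
    stop("plant carries no generation density attribute")
  if (d$density > gen_density * (1 + 1e-9))
    stop("cannot upsample: target density ", d$density,
         " exceeds generation density ", gen_density)
  n <- n_points(cloud)
  keep <- with_seed(derive_seed(d$seed, 310L), {
    ratio <- d$density / gen_density
    if (ratio < 1) sort(sample.int(n, round(n * ratio))) else seq_len(n)
  })
  pts <- cloud$points[keep, , drop = FALSE]
  nrm <- cloud$normals[keep, , drop = FALSE]
  ## visibility culling
  ctr <- colMeans(pts)
  rad <- sqrt(max(rowSums(sweep(pts, 2, ctr)^2)))
  R <- 2.5 * max(rad, 1e-6)
  az <- 2 * pi * (seq_len(d$n_views) - 1) / d$n_views
  zv <- R * tan(deg2rad(15))
  visible <- rep(FALSE, nrow(pts))
  for (a in az) {
    vp <- ctr + c(R * cos(a), R * sin(a), zv)
    dir <- sweep(-pts, 2, -vp)   # vp - pts
    visible <- visible | rowSums(dir * nrm) > 0
  }
  keep <- keep[visible]
  pts <- pts[visible, , drop = FALSE]
  if (length(keep) == 0) stop("degradation removed every point")
  if (d$noise_sigma > 0) {
    noise <- with_seed(derive_seed(d$seed, 311L),
                       matrix(rnorm(3 * length(keep), 0, d$noise_sigma),
                              ncol = 3))
    pts <- pts + noise
  }
  new_cloud <- point_cloud(
    pts,
    colors = if (!is.null(cloud$colors)) cloud$colors[keep, , drop = FALSE],
    labels = if (!is.null(cloud$labels)) cloud$labels[keep],
    normals = cloud$normals[keep, , drop = FALSE])
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  reindex <- function(idx) {
    v <- remap[idx]
    v[v > 0L]
  }
  out <- segmented_plant(new_cloud, stem = reindex(plant$stem),
                         branches = lapply(plant$branches, reindex),
                         leaves = lapply(plant$leaves, reindex))
  attr(out, "density") <- d$density
  attr(out, "spec") <- attr(plant, "spec")
  out
}

#' Render a plant scene over a coloured background
#'
#' Orthographic point splatting of the cloud (viewed along -y, x right,
#' z up) in green hues over a uniform background panel, together with the
#' exact foreground silhouette mask, for testing [background_mask()].
#'
#' @param plant a [segmented_plant()].
#' @param bg_color background RGB, 0--255 (default a red panel).
#' @param image_size `c(height, width)` in pixels.
#' @return list with `image` (h x w x 3 array, 0--255) and `mask`
#'   (h x w 0/1 matrix, 1 where a point was splatted).
#' @export
render_scene <- function(plant, bg_color = c(200, 35, 35),
                         image_size = c(240, 240)) {
  stopifnot(inherits(plant, "segmented_plant"), length(image_size) == 2)
  pts <- plant$cloud$points
  H <- image_size[1]; W <- image_size[2]
  xr <- range(pts[, 1]); zr <- range(pts[, 3])
  span <- max(diff(xr), diff(zr), 1e-9)
  margin <- 0.05 * span
  x0 <- mean(xr) - span / 2 - margin; x1 <- mean(xr) + span / 2 + margin
  z0 <- mean(zr) - span / 2 - margin; z1 <- mean(zr) + span / 2 + margin
  col <- 1L + as.integer(floor((pts[, 1] - x0) / (x1 - x0) * (W - 1) + 0.5))
  row <- H - as.integer(floor((pts[, 3] - z0) / (z1 - z0) * (H - 1) + 0.5))
  ok <- col >= 1L & col <= W & row >= 1L & row <= H
  img <- array(0, c(H, W, 3))
  img[, , 1] <- bg_color[1]; img[, , 2] <- bg_color[2]; img[, , 3] <- bg_color[3]
  mask <- matrix(0L, H, W)
  if (any(ok)) {
    idx <- which(ok)
    lin <- cbind(row[idx], col[idx])
    mask[lin] <- 1L
    g <- 120 + (idx %% 80)
    img[cbind(lin, 1L)] <- 35
    img[cbind(lin, 2L)] <- g
    img[cbind(lin, 3L)] <- 40
  }
  list(image = img, mask = mask)
}
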