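test_that("key points follow the lowest/highest/mid-z definitions", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 1))
  pl <- segmented_plant(point_cloud(pts), stem = 1:2)
  kp <- locate_keypoints(pl)
  expect_equal(kp$p1, c(0, 0, 0))
  expect_equal(kp$p3, c(0, 0, 1))
  expect_equal(kp$p2, c(0, 0, 0))  # tie on |z - 0.5| broken by lowest index

  ## a leaf tip below the stem base becomes p1 (whole-cloud minimum)
  pts <- rbind(c(0, 0, 0.1), c(0, 0, 0.5), c(0.2, 0, -0.05), c(0.2, 0, 0.0),
               c(0.2, 0, 0.02))
  pl <- segmented_plant(point_cloud(pts), stem = 1:2, leaves = list(3:5))
  kp <- locate_keypoints(pl)
  expect_equal(kp$p1, c(0.2, 0, -0.05))
})

test_that("branch key points match generator insertion geometry", {
  gp <- generate_plant(synthetic_plant_spec("tomato_like", seed = 4),
                       density = 60)
  kp <- locate_keypoints(gp$plant)
  spec <- attr(gp$plant, "spec")
  ins_z <- spec$branches$insertion_frac * spec$stem$height_m
  p4_z <- vapply(kp$p4, function(p) p[3], numeric(1))
  expect_equal(p4_z, ins_z, tolerance = 0.02)
})

test_that("euclidean height is the straight-line metric", {
  expect_equal(euclidean_height(c(0, 0, 0), c(0, 0, 0.10)), 0.10)
  expect_equal(euclidean_height(c(0.01, 0.02, 0.03), c(0.04, 0.06, 0.03)),
               0.05)  # 3-4-5 triangle
  withr::local_seed(17)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    expect_equal(euclidean_height(a, b), sqrt(sum((a - b)^2)))
    expect_equal(euclidean_height(a, b), euclidean_height(b, a))
    expect_gte(euclidean_height(a, b) + euclidean_height(b, c) + 1e-12,
               euclidean_height(a, c))
  }
  expect_equal(euclidean_height(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("plant and branch heights are straight-line distances in cm", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 0.45))
  pl <- segmented_plant(point_cloud(pts), stem = 1:2)
  expect_equal(plant_height(locate_keypoints(pl)), 45)
  expect_length(branch_heights(locate_keypoints(pl)), 0)

  ## a branch whose lowest point coincides with p1 has BH = 0
  pts <- rbind(c(0, 0, 0), c(0, 0, 0.3), c(0, 0, 0), c(0.1, 0, 0.1),
               c(0.05, 0, 0.05))
  pl <- segmented_plant(point_cloud(pts), stem = 1:2, branches = list(3:5))
  expect_equal(branch_heights(locate_keypoints(pl)), 0)

  ## tilt does not shorten the reported height: a 0.45 m axis reads 45 cm
  t10 <- 10 * pi / 180
  ax <- c(sin(t10), 0, cos(t10))
  tpts <- rbind(c(0, 0, 0), outer(seq(0, 0.45, length.out = 50), ax))
  pl <- segmented_plant(point_cloud(tpts), stem = seq_len(nrow(tpts)))
  expect_equal(plant_height(locate_keypoints(pl)), 45, tolerance = 1e-6)
})

test_that("ring selection respects slab and ball geometries", {
  pts <- rbind(c(0, 0, 0), c(0.001, 0, 0.004), c(0, 0.001, 0.02))
  sel <- ring_select(pts, centroid = c(0, 0, 0), radius = 0.005)
  expect_identical(sel$selected, 1:2)
  expect_equal(sel$rangeX, 0.001)

  th <- seq(0, 2 * pi, length.out = 200)
  cyl <- cbind(0.005 * cos(th), 0.005 * sin(th), runif(200, 0, 0.1))
  ball <- ring_select(cyl, centroid = c(0, 0, 0.05), radius = 0.02,
                      geometry = "ball")
  expect_gt(length(ball$selected), 0)
  empty <- ring_select(cyl, centroid = c(0, 0, 10), radius = 0.001)
  expect_length(empty$selected, 0)
  expect_true(is.na(ring_diameter(empty)))
})

test_that("ring diameter modes agree with hand-computed ranges", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(0.005 * cos(th), 0.005 * sin(th), 0)
  sel <- ring_select(circ, c(0, 0, 0), radius = 0.001)
  expect_equal(ring_diameter(sel, mode = "range"), 10, tolerance = 1e-3)
  expect_equal(ring_diameter(sel, mode = "half_range"), 5, tolerance = 1e-3)

  ## three collinear points along x: min picks the zero y-range
  lin <- rbind(c(0, 0, 0), c(0.002, 0, 0), c(0.004, 0, 0))
  expect_equal(ring_diameter(ring_select(lin, c(0, 0, 0), 0.01)), 0)

  ## fewer than 3 points is a missing value, not an error
  expect_true(is.na(ring_diameter(ring_select(lin[1:2, ], c(0, 0, 0), 0.01))))
})

test_that("stem diameters recover synthetic cylinder cross-sections", {
  withr::local_seed(9)
  ## uniform cylinder: BD = HD = AD
  n <- 4000
  th <- runif(n, 0, 2 * pi)
  cyl <- cbind(0.006 * cos(th), 0.006 * sin(th), runif(n, 0, 0.4))
  pl <- segmented_plant(point_cloud(cyl), stem = seq_len(n))
  d <- stem_diameters(pl, locate_keypoints(pl))
  expect_equal(unname(d), rep(12, 3), tolerance = 0.02)

  ## tapered synthetic maize stem: three distinct diameters within 5%
  spec <- synthetic_plant_spec("maize_like", seed = 1)
  gp <- generate_plant(spec, density = 150)
  stem_only <- stem_only_plant(gp$plant)
  d <- stem_diameters(stem_only, locate_keypoints(stem_only))
  expect_equal(unname(d[["BD"]]), spec$stem$basal_mm, tolerance = 0.05)
  expect_equal(unname(d[["HD"]]), spec$stem$half_mm, tolerance = 0.05)
  expect_equal(unname(d[["AD"]]), spec$stem$apical_mm, tolerance = 0.05)

  ## a 2-point stem yields three missing diameters
  two <- segmented_plant(point_cloud(rbind(c(0, 0, 0), c(0, 0, 1))), stem = 1:2)
  expect_true(all(is.na(stem_diameters(two, locate_keypoints(two)))))
})

test_that("total-least-squares plane fits recover exact and noisy planes", {
  withr::local_seed(10)
  pts <- cbind(runif(50), runif(50), 0.3)
  f <- fit_plane(pts)
  expect_equal(f$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_lt(f$rms_residual, 1e-12)

  ## axis plane x = 0: z-sign rule defers to positive x
  pts <- cbind(0, runif(50), runif(50))
  f <- fit_plane(pts)
  expect_equal(f$normal, c(1, 0, 0), tolerance = 1e-9)

  ## noisy random plane: normal recovered within 1 degree
  for (i in 1:5) {
    nrm <- rand_unit()
    e1 <- unit_vec_perp(nrm)
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2], nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    u <- runif(1000, -0.05, 0.05); v <- runif(1000, -0.05, 0.05)
    pts <- outer(u, e1) + outer(v, e2) +
      outer(rnorm(1000, sd = 0.001), nrm)
    f <- fit_plane(pts)
    expect_lt(min(angle_deg(f$normal, nrm), angle_deg(f$normal, -nrm)), 1)
  }

  expect_error(fit_plane(cbind(1:5, 1:5, 1:5)), "degenerate")
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "degenerate")
})

test_that("leaf inclination is the plane-normal zenith angle folded to [0, 90]", {
  horiz <- cbind(runif(100), runif(100), 0.2)
  expect_equal(leaf_inclination(horiz), 0, tolerance = 1e-9)
  vert <- cbind(runif(100), 0.1, runif(100))
  expect_equal(leaf_inclination(vert), 90, tolerance = 1e-9)

  ## tilted flat ellipse with sub-mm noise: 30 deg within 0.5 deg
  withr::local_seed(12)
  tau <- 30 * pi / 180
  nrm <- c(sin(tau), 0, cos(tau))
  e1 <- c(cos(tau), 0, -sin(tau)); e2 <- c(0, 1, 0)
  om <- runif(2000, 0, 2 * pi); rho <- sqrt(runif(2000))
  pts <- outer(0.04 * rho * cos(om), e1) + outer(0.02 * rho * sin(om), e2) +
    outer(rnorm(2000, sd = 5e-4), nrm)
  expect_equal(leaf_inclination(pts), 30, tolerance = 0.5)
  ## flipping the surface (normal sign) leaves LI unchanged
  flipped <- pts %*% diag(c(1, 1, -1))
  expect_equal(leaf_inclination(flipped), leaf_inclination(pts),
               tolerance = 1e-6)
})

test_that("branch inclination follows the oriented principal axis", {
  withr::local_seed(13)
  t <- runif(500, 0, 0.1)
  jitter <- matrix(rnorm(1500, sd = 1e-4), ncol = 3)
  vert <- cbind(0, 0, t) + jitter
  expect_equal(branch_inclination(vert, origin = c(0, 0, 0)), 0,
               tolerance = 0.5)
  horiz <- cbind(t, 0, 0) + jitter
  expect_equal(branch_inclination(horiz, origin = c(0, 0, 0)), 90,
               tolerance = 0.5)

  ## 40 deg from vertical, oriented upward-outward
  beta <- 40 * pi / 180
  d <- c(sin(beta), 0, cos(beta))
  pts <- outer(t, d) + jitter
  expect_equal(branch_inclination(pts, origin = c(0, 0, 0)), 40,
               tolerance = 0.5)
  ## seen from the far end the same branch points down: supplementary angle
  expect_equal(branch_inclination(pts, origin = 0.1 * d), 140,
               tolerance = 0.5)
  ## plane mode is the complement of the plane-normal zenith angle
  flat <- cbind(runif(100), runif(100), 0.1)
  expect_equal(branch_inclination(flat, mode = "plane"), 90)
  expect_true(is.na(branch_inclination(rbind(c(0, 0, 0), c(1, 0, 0)))))
})

test_that("convex-hull leaf area matches analytic shapes and includes voids", {
  rect <- rbind(c(0, 0, 0.2), c(0.10, 0, 0.2), c(0.10, 0.05, 0.2),
                c(0, 0.05, 0.2))
  expect_equal(leaf_area(rect), 50)

  ## dense flat ellipse: pi * a * b within 2%
  withr::local_seed(14)
  om <- runif(5000, 0, 2 * pi); rho <- sqrt(runif(5000))
  ell <- cbind(0.04 * rho * cos(om), 0.02 * rho * sin(om), 0.1)
  expect_equal(leaf_area(ell), pi * 4 * 2, tolerance = 0.02)

  ## annulus: the hull spans the outer boundary, interior void included
  th <- runif(2000, 0, 2 * pi); r <- runif(2000, 0.03, 0.04)
  ann <- cbind(r * cos(th), r * sin(th), 0)
  hull_o <- bf_hull_area(ann[, 1], ann[, 2])
  expect_equal(leaf_area(ann), 1e4 * hull_o, tolerance = 1e-6)
  expect_true(is.na(leaf_area(cbind(1:5, 1:5, 1:5))))
})

test_that("hull area is monotone under added coplanar points", {
  withr::local_seed(15)
  base <- cbind(runif(30, 0, 0.05), runif(30, 0, 0.05), 0.3)
  a0 <- leaf_area(base)
  for (i in 1:5) {
    extra <- cbind(runif(10, -0.02, 0.07), runif(10, -0.02, 0.07), 0.3)
    a1 <- leaf_area(rbind(base, extra))
    expect_gte(a1 + 1e-9, a0)
    base <- rbind(base, extra); a0 <- a1
  }
})

test_that("extract_traits composes all operations and tolerates organ failures", {
  gp <- generate_plant(synthetic_plant_spec("olive_like", seed = 3),
                       density = 60)
  rec <- extract_traits(gp$plant)
  tr <- gp$truth
  expect_equal(rec$PH, tr$PH, tolerance = 0.01)
  expect_equal(rec$BH, tr$BH, tolerance = 0.05)
  expect_equal(rec$BI, tr$BI, tolerance = 0.03)
  expect_equal(rec$LI, tr$LI, tolerance = 0.02)
  expect_equal(rec$LA, tr$LA, tolerance = 0.02)

  ## a leafless plant still yields heights and diameters
  pts <- gp$plant$cloud$points[gp$plant$stem, ]
  bare <- segmented_plant(point_cloud(pts), stem = seq_len(nrow(pts)))
  rec2 <- extract_traits(bare)
  expect_length(rec2$LI, 0)
  expect_length(rec2$LA, 0)
  expect_false(is.na(rec2$PH))

  ## a 2-point branch gets missing BI, everything else intact
  pts3 <- rbind(pts[1:500, ], c(1, 1, 1), c(1, 1, 1.001))
  crippled <- segmented_plant(point_cloud(pts3), stem = 1:500,
                              branches = list(501:502))
  rec3 <- extract_traits(crippled)
  expect_true(is.na(rec3$BI[1]))
  expect_false(is.na(rec3$PH))
  ml <- attr(rec3, "missing_log")
  expect_true("BI" %in% ml$trait)
})

test_that("traits are covariant under rigid motion and scaling", {
  ## flat-leaf archetype: all plane fits are well conditioned, so the
  ## equivariance holds to numerical precision (curled narrow ribbons can
  ## have near-tied minor principal axes whose fitted normal is genuinely
  ## unstable under rotation)
  gp <- generate_plant(synthetic_plant_spec("olive_like", seed = 6),
                       density = 60)
  pl <- gp$plant
  base <- extract_traits(pl)

  move_plant <- function(pl, f) {
    segmented_plant(point_cloud(f(pl$cloud$points)), stem = pl$stem,
                    branches = pl$branches, leaves = pl$leaves)
  }
  ## translation
  shifted <- move_plant(pl, function(p)
    p + matrix(c(1, -2, 3), nrow(p), 3, byrow = TRUE))
  rec_t <- extract_traits(shifted)
  ## rotation about z
  a <- 70 * pi / 180
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  rotated <- move_plant(pl, function(p) p %*% rz)
  rec_r <- extract_traits(rotated)
  for (nm in c("PH", "BH", "BD", "HD", "AD", "BI", "LI", "LA"))
    expect_equal(rec_t[[nm]], base[[nm]], tolerance = 1e-6)
  ## the x/y-range diameter estimator is axis-aligned by definition, so only
  ## the remaining traits are invariant under z-rotation
  for (nm in c("PH", "BH", "BI", "LI", "LA"))
    expect_equal(rec_r[[nm]], base[[nm]], tolerance = 1e-6)
  ## uniform scaling (ring radius scaled alongside the geometry)
  c_s <- 2.5
  scaled <- move_plant(pl, function(p) p * c_s)
  rec_s <- extract_traits(scaled, config = extract_config(ring_radius_mm = 5 * c_s))
  expect_equal(rec_s$PH, base$PH * c_s, tolerance = 1e-6)
  expect_equal(rec_s$BH, base$BH * c_s, tolerance = 1e-6)
  expect_equal(c(rec_s$BD, rec_s$HD, rec_s$AD),
               c(base$BD, base$HD, base$AD) * c_s, tolerance = 1e-6)
  expect_equal(rec_s$BI, base$BI, tolerance = 1e-6)
  expect_equal(rec_s$LI, base$LI, tolerance = 1e-6)
  expect_equal(rec_s$LA, base$LA * c_s^2, tolerance = 1e-6)
})
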