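## Independent brute-force oracles used to cross-check the geometric and
## statistical routines. Deliberately naive implementations: O(n^2) loops,
## gift-wrapping hulls, numerical optimisation for plane fits.

## mean distance to the k nearest neighbours, exhaustive
bf_knn_mean_dist <- function(pts, k) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(pts) - pts[i, ])^2))
    d[i] <- Inf
    out[i] <- mean(sort(d)[seq_len(k)])
  }
  out
}

## outlier removal decision replicated from first principles
bf_outlier_removed <- function(pts, k, alpha) {
  md <- bf_knn_mean_dist(pts, k)
  which(md > mean(md) + alpha * stats::sd(md))
}

## 2D convex hull area via Jarvis gift wrapping + triangle fan
bf_hull_area <- function(u, v) {
  n <- length(u)
  if (n < 3) return(0)
  start <- order(u, v)[1]
  h <- start
  cur <- start
  repeat {
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (u[nxt] - u[cur]) * (v[j] - v[cur]) -
        (v[nxt] - v[cur]) * (u[j] - u[cur])
      d_nxt <- (u[nxt] - u[cur])^2 + (v[nxt] - v[cur])^2
      d_j <- (u[j] - u[cur])^2 + (v[j] - v[cur])^2
      if (cr < 0 || (cr == 0 && d_j > d_nxt)) nxt <- j
    }
    if (nxt == start) break
    h <- c(h, nxt)
    cur <- nxt
    if (length(h) > n + 1) stop("gift wrapping failed")
  }
  area <- 0
  for (i in 2:(length(h) - 1)) {
    x1 <- u[h[i]] - u[h[1]]; y1 <- v[h[i]] - v[h[1]]
    x2 <- u[h[i + 1]] - u[h[1]]; y2 <- v[h[i + 1]] - v[h[1]]
    area <- area + (x1 * y2 - x2 * y1) / 2
  }
  abs(area)
}

## orthogonal-distance plane fit by direct numerical minimisation over the
## normal's spherical angles (multi-start Nelder-Mead)
bf_plane_ss <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  obj <- function(par) {
    nrm <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]),
             cos(par[1]))
    sum((x %*% nrm)^2)
  }
  best <- Inf
  for (th0 in seq(0.2, pi - 0.2, length.out = 4))
    for (ph0 in seq(0, 1.5 * pi, length.out = 4)) {
      o <- stats::optim(c(th0, ph0), obj,
                        control = list(reltol = 1e-14, maxit = 2000))
      if (o$value < best) best <- o$value
    }
  best
}

## uniformly random unit vector
rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

## random 3D rotation matrix (QR of a Gaussian matrix, det +1)
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## plain cylinder cloud with radial normals, as a segmented one-stem plant
cylinder_plant <- function(n_theta = 60, n_z = 40, radius = 0.01,
                           height = 0.4, density_attr = 100) {
  th <- rep(seq(0, 2 * pi, length.out = n_theta + 1)[-1], times = n_z)
  z <- rep(seq(0, height, length.out = n_z), each = n_theta)
  pts <- cbind(radius * cos(th), radius * sin(th), z)
  nrm <- cbind(cos(th), sin(th), 0)
  pl <- segmented_plant(point_cloud(pts, normals = nrm),
                        stem = seq_len(nrow(pts)))
  attr(pl, "density") <- density_attr
  pl
}

## internal spec validator, re-exposed for contract tests
validate_spec_for_test <- phenocloud:::validate_spec

## any unit vector perpendicular to v
unit_vec_perp <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- ref - sum(ref * v) * v
  w / sqrt(sum(w^2))
}

## reduce a segmented plant to its stem points only
stem_only_plant <- function(plant) {
  pts <- plant$cloud$points[plant$stem, , drop = FALSE]
  segmented_plant(point_cloud(pts), stem = seq_len(nrow(pts)))
}

## angle between two vectors, degrees
angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}
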