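#' Background removal by supervised colour thresholding
#'
#' The platform photographs plants against a uniformly coloured panel (red,
#' maximally separable from foliage in RGB). A pixel is foreground iff its
#' Euclidean distance to `bg_color` in RGB space exceeds `tolerance`;
#' foreground connected components smaller than `min_component_px` pixels
#' (8-connectivity) are then erased as speckle. The reference colour and
#' tolerance are the "supervision".
#'
#' @param image RGB raster: an h x w x 3 array, either in 0--255 or 0--1
#'   (as returned by [png::readPNG()]; scaled to 0--255 internally).
#' @param bg_color length-3 RGB reference colour of the background, 0--255.
#' @param tolerance colour-distance threshold (>= 0) in 0--255 RGB units.
#' @param min_component_px minimum connected-component size (pixels) kept as
#'   foreground; 0 disables the cleanup.
#' @return binary mask matrix (h x w) of 0/1 integers, 1 = foreground.
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 1] <- 200  # all-red image
#' sum(background_mask(img, bg_color = c(200, 0, 0), tolerance = 10))
#' @export
background_mask <- function(image, bg_color, tolerance, min_component_px = 0L) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("channel error: 'image' must be an h x w x 3 RGB array")
  if (length(bg_color) != 3) stop("'bg_color' must have three components")
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  if (min_component_px < 0) stop("'min_component_px' must be >= 0")
  img <- image[, , 1:3, drop = FALSE]
  if (max(img) <= 1) img <- img * 255
  d2 <- (img[, , 1] - bg_color[1])^2 + (img[, , 2] - bg_color[2])^2 +
    (img[, , 3] - bg_color[3])^2
  mask <- d2 > tolerance^2
  if (min_component_px > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask)          # 8-connected components
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= min_component_px)
    mask <- matrix(lab %in% keep, nrow = nrow(mask))
  }
  matrix(as.integer(mask), nrow = dim(image)[1])
}

#' Write a binary mask as a black/white PNG
#'
#' Foreground is written white, background black (the convention mask-aware
#' photogrammetry suites expect).
#'
#' @param mask 0/1 matrix from [background_mask()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  write_atomic(path, function(tmp)
    png::writePNG(matrix(as.numeric(mask > 0), nrow = nrow(mask)), tmp))
  invisible(path)
}

#' Statistical outlier removal for point clouds
#'
#' The standard k-nearest-neighbour statistical filter of photogrammetry
#' suites: for each point compute the mean distance to its `k_neighbors`
#' nearest neighbours; a point is removed when its mean distance exceeds
#' `mu + alpha * sigma`, where `mu` and `sigma` are the mean and standard
#' deviation of those per-point means over the whole cloud. Ties in
#' neighbour distances are broken by point index order, so the result is
#' deterministic and invariant under rigid motion of the cloud.
#'
#' @param cloud a [point_cloud()].
#' @param k_neighbors number of nearest neighbours (>= 1, < point count).
#' @param alpha standard-deviation multiplier (> 0).
#' @return list with `cloud` (survivors, channels preserved), `removed`
#'   (integer indices into the input cloud, increasing), and `mean_knn_dist`
#'   (the per-point statistic, in input order).
#' @export
statistical_outlier_filter <- function(cloud, k_neighbors = 8L, alpha = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  k <- as.integer(k_neighbors)
  if (k < 1) stop("configuration error: 'k_neighbors' must be >= 1")
  if (k >= n)
    stop("configuration error: 'k_neighbors' (", k,
         ") must be smaller than the point count (", n, ")")
  if (alpha <= 0) stop("'alpha' must be > 0")
  md <- knn_mean_dist(cloud$points, k)
  thr <- mean(md) + alpha * sd(md)
  removed <- which(md > thr)
  keep <- setdiff(seq_len(n), removed)
  list(cloud = subset_cloud(cloud, keep), removed = removed,
       mean_knn_dist = md)
}

## Mean distance to the k nearest neighbours, computed in row blocks so the
## full n x n distance matrix is never materialised.
knn_mean_dist <- function(pts, k) {
  n <- nrow(pts)
  sq <- rowSums(pts^2)
  block <- max(1L, min(n, as.integer(2e7 / n)))
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    ## squared cross-distances block x n
    d2 <- outer(sq[idx], sq, "+") - 2 * pts[idx, , drop = FALSE] %*% t(pts)
    d2[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1, function(r) mean(sqrt(sort(r, partial = k)[seq_len(k)])))
  }
  out
}
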