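#' Plane model \eqn{ax + by + cz + d = 0}
#'
#' @param normal length-3 normal vector (need not be unit; it is
#'   normalized).
#' @param offset scalar `d`, on the same scale as the supplied normal.
#' @return object of class `plane_model` with a unit normal and matching
#'   offset.
#' @export
plane_model <- function(normal, offset) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L) stop("normal must have 3 components")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("zero normal vector")
  structure(list(normal = normal / nn, offset = offset / nn),
            class = "plane_model")
}

#' Point-to-plane distance
#'
#' `|a x + b y + c z + d| / sqrt(a^2 + b^2 + c^2)`, vectorized over points.
#'
#' @param points numeric `N x 3` matrix (or length-3 vector).
#' @param plane a [plane_model()].
#' @return numeric vector of distances.
#' @export
point_plane_distance <- function(points, plane) {
  stopifnot(inherits(plane, "plane_model"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  abs(points %*% plane$normal + plane$offset)[, 1]
}

#' RANSAC parameters for ground-plane fitting
#'
#' Defaults follow the standard field-cloud setting: inlier distance
#' threshold 0.2, minimal sample of 3 points, 500 iterations.
#'
#' @param distance_threshold inlier distance (same units as the cloud).
#' @param sample_size points drawn per hypothesis (>= 3; > 3 fits by least
#'   squares).
#' @param n_iterations number of hypotheses.
#' @param seed optional integer seed.
#' @return object of class `ransac_params`.
#' @export
ransac_params <- function(distance_threshold = 0.2, sample_size = 3L,
                          n_iterations = 500L, seed = NULL) {
  if (distance_threshold <= 0) stop("distance_threshold must be > 0")
  if (sample_size < 3L) stop("sample_size must be >= 3")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(list(distance_threshold = distance_threshold,
                 sample_size = as.integer(sample_size),
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "ransac_params")
}

# Exact plane through 3 points (NULL if collinear); least squares (total,
# via SVD) for larger samples.
fit_plane_points <- function(pts) {
  if (nrow(pts) == 3L) {
    n <- crossprod3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
    if (sqrt(sum(n^2)) < 1e-12) return(NULL)
    plane_model(n, -sum(n * pts[1, ]))
  } else {
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    n <- sv$v[, 3]
    if (sv$d[2] < 1e-12) return(NULL)  # collinear sample
    plane_model(n, -sum(n * ctr))
  }
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fit the ground plane by RANSAC
#'
#' Repeatedly draws `sample_size` points, fits the exact plane through 3 of
#' them (least squares for larger samples), and counts points closer to the
#' plane than `distance_threshold` (strictly). Degenerate (collinear) draws
#' are rejected and count against the iteration budget. The plane with the
#' most inliers wins.
#'
#' @param cloud a [labeled_cloud()] with at least 3 points.
#' @param params a [ransac_params()].
#' @return list with `plane` ([plane_model()]), `inlier_mask` (logical per
#'   point) and `n_inliers`; reproducible under `params$seed`.
#' @export
fit_ground_ransac <- function(cloud, params = ransac_params()) {
  stopifnot(inherits(params, "ransac_params"))
  m <- cloud$coords
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 points to fit a plane")
  if (!is.null(params$seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(params$seed)
  }
  best <- NULL
  best_count <- -1L
  for (it in seq_len(params$n_iterations)) {
    pts <- m[sample.int(n, params$sample_size), , drop = FALSE]
    plane <- fit_plane_points(pts)
    if (is.null(plane)) next
    cnt <- sum(point_plane_distance(m, plane) < params$distance_threshold)
    if (cnt > best_count) { best_count <- cnt; best <- plane }
  }
  if (is.null(best))
    stop("RANSAC failed: every sampled point set was collinear")
  mask <- point_plane_distance(m, best) < params$distance_threshold
  list(plane = best, inlier_mask = mask, n_inliers = sum(mask))
}

#' Remove ground points given a fitted plane
#'
#' Keeps points at distance >= `threshold` from the plane (the complement
#' of the RANSAC inlier rule, which classifies distance < threshold as
#' ground).
#'
#' @param cloud a [labeled_cloud()].
#' @param plane a [plane_model()].
#' @param threshold distance threshold (default 0.2).
#' @return the above-ground sub-cloud; labels carried along.
#' @export
remove_ground <- function(cloud, plane, threshold = 0.2) {
  keep <- point_plane_distance(cloud$coords, plane) >= threshold
  if (!any(keep)) stop("ground removal left an empty cloud")
  subset_cloud(cloud, keep)
}

#' Statistical outlier filter
#'
#' For each point, the mean distance to its `n_neighbors` nearest
#' neighbours is computed; points whose mean distance exceeds
#' (global mean + `std_ratio` x global standard deviation) of those
#' per-point means are removed.
#'
#' @param cloud a [labeled_cloud()] with more than `n_neighbors` points.
#' @param n_neighbors neighbourhood size (default 50).
#' @param std_ratio standard-deviation multiplier (default 1.0).
#' @return the filtered [labeled_cloud()].
#' @export
statistical_outlier_filter <- function(cloud, n_neighbors = 50L,
                                       std_ratio = 1.0) {
  n <- n_points(cloud)
  if (n <= n_neighbors)
    stop(sprintf("need more than n_neighbors = %d points, got %d",
                 n_neighbors, n))
  md <- cpp_mean_knn_dist(cloud$coords, as.integer(n_neighbors))
  cutoff <- mean(md) + std_ratio * stats::sd(md)
  subset_cloud(cloud, md <= cutoff)
}

#' Uniform downsampling by index stride
#'
#' Keeps every `rate`-th point in index order (rate 2 halves the cloud,
#' keeping `ceiling(N / rate)` points), the stride-based uniform subsample
#' used by common point-cloud editors.
#'
#' @param cloud a [labeled_cloud()].
#' @param rate integer sampling rate >= 1 (default 2).
#' @return the decimated [labeled_cloud()].
#' @export
uniform_downsample <- function(cloud, rate = 2L) {
  rate <- as.integer(rate)
  if (is.na(rate) || rate < 1L) stop("rate must be an integer >= 1")
  if (rate == 1L) return(cloud)
  subset_cloud(cloud, seq.int(1L, n_points(cloud), by = rate))
}

#' Full preprocessing chain
#'
#' Ground removal (RANSAC) then statistical outlier filtering then uniform
#' downsampling, in that order, with the standard defaults.
#'
#' @param cloud a [labeled_cloud()].
#' @param ransac a [ransac_params()].
#' @param n_neighbors,std_ratio statistical filter settings.
#' @param rate downsampling rate.
#' @param skip_ground skip the RANSAC stage (for clouds without ground).
#' @return list with `cloud` and `stage_counts` (named point counts after
#'   each stage).
#' @export
preprocess_cloud <- function(cloud, ransac = ransac_params(),
                             n_neighbors = 50L, std_ratio = 1.0,
                             rate = 2L, skip_ground = FALSE) {
  counts <- c(input = n_points(cloud))
  if (!skip_ground) {
    fit <- fit_ground_ransac(cloud, ransac)
    cloud <- remove_ground(cloud, fit$plane, ransac$distance_threshold)
  }
  counts <- c(counts, ground_removed = n_points(cloud))
  cloud <- statistical_outlier_filter(cloud, n_neighbors, std_ratio)
  counts <- c(counts, filtered = n_points(cloud))
  cloud <- uniform_downsample(cloud, rate)
  counts <- c(counts, downsampled = n_points(cloud))
  list(cloud = cloud, stage_counts = counts)
}
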