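#' Labeled point cloud
#'
#' The universal currency of the pipeline: an `N x 3` matrix of metric
#' coordinates with optional per-point semantic labels, instance ids and
#' feature columns. Semantic label convention throughout the package:
#' 0 = stem, 1 = leaf, 2 = ground, 3 = outlier.
#'
#' @param coords numeric `N x 3` matrix (columns x, y, z), finite values.
#' @param semantic optional integer vector of length `N`.
#' @param instance optional integer vector of length `N` (0 = stem,
#'   1..n for leaves).
#' @param features optional numeric `N x d` matrix of extra per-point
#'   features.
#' @return an object of class `labeled_cloud`.
#' @examples
#' cl <- labeled_cloud(matrix(rnorm(30), 10, 3), semantic = rep(0:1, 5))
#' n_points(cl)
#' @export
labeled_cloud <- function(coords, semantic = NULL, instance = NULL,
                          features = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have exactly 3 columns")
  if (nrow(coords) < 1L) stop("coords must contain at least one point")
  if (!all(is.finite(coords))) stop("coords must be finite")
  colnames(coords) <- c("x", "y", "z")
  n <- nrow(coords)
  chk_vec <- function(v, name) {
    if (is.null(v)) return(NULL)
    if (length(v) != n) {
      stop(sprintf("%s must have length %d (one per point), got %d",
                   name, n, length(v)))
    }
    as.integer(v)
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != n) stop("features must have one row per point")
  }
  structure(
    list(coords = coords,
         semantic = chk_vec(semantic, "semantic"),
         instance = chk_vec(instance, "instance"),
         features = features),
    class = "labeled_cloud")
}

#' Number of points in a cloud
#' @param cloud a [labeled_cloud()].
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud> %d points", n_points(x)))
  if (!is.null(x$semantic)) {
    tab <- table(x$semantic)
    cat(" | labels:", paste(names(tab), as.integer(tab), sep = ":",
                            collapse = " "))
  }
  if (!is.null(x$instance)) cat(" | instances:", length(unique(x$instance)))
  cat("\n")
  invisible(x)
}

# Subset points, keeping label/instance/feature alignment.
#' Subset a cloud by point index or logical mask
#' @param cloud a [labeled_cloud()].
#' @param i integer indices or logical mask over points.
#' @return the sub-cloud; labels and features travel with their points.
#' @export
subset_cloud <- function(cloud, i) {
  if (is.logical(i)) i <- which(i)
  if (length(i) == 0L) stop("subset would produce an empty cloud")
  labeled_cloud(cloud$coords[i, , drop = FALSE],
                semantic = cloud$semantic[i],
                instance = cloud$instance[i],
                features = if (!is.null(cloud$features))
                  cloud$features[i, , drop = FALSE])
}

# rbind-style concatenation of two clouds (labels must be present in both or
# neither).
bind_clouds <- function(a, b) {
  bind_vec <- function(u, v) {
    if (is.null(u) && is.null(v)) return(NULL)
    if (is.null(u) || is.null(v)) stop("cannot bind labeled and unlabeled clouds")
    c(u, v)
  }
  labeled_cloud(rbind(a$coords, b$coords),
                semantic = bind_vec(a$semantic, b$semantic),
                instance = bind_vec(a$instance, b$instance))
}

#' Resample a cloud to a fixed number of points
#'
#' Networks with fixed-size inputs need every cloud at the same point count
#' (default 8192). Clouds with at least `num_points` points are subsampled
#' uniformly without replacement; smaller clouds are sampled with
#' replacement up to the target size. Labels travel with their points.
#'
#' @param cloud a [labeled_cloud()].
#' @param num_points target size (default 8192).
#' @param seed optional integer seed for reproducibility.
#' @return a [labeled_cloud()] with exactly `num_points` points.
#' @export
resample_to_count <- function(cloud, num_points = 8192L, seed = NULL) {
  num_points <- as.integer(num_points)
  if (num_points < 1L) stop("num_points must be >= 1")
  n <- n_points(cloud)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  i <- if (n >= num_points) sample.int(n, num_points, replace = FALSE)
       else sample.int(n, num_points, replace = TRUE)
  subset_cloud(cloud, i)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
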