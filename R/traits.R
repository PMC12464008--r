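#' Plant height from a segmented cloud
#'
#' The difference between the highest and lowest z coordinates over all
#' plant points (stem and leaf), in centimetres. The cloud must already be
#' de-normalized to metric units (metres).
#'
#' @param cloud a [labeled_cloud()] in metric space.
#' @return height in cm.
#' @export
plant_height <- function(cloud) {
  z <- cloud$coords[, 3]
  if (length(z) == 0L) stop("empty cloud")
  (max(z) - min(z)) * 100
}

#' Extract per-leaf instances from a semantically segmented cloud
#'
#' Leaf-labeled points (semantic == 1) are clustered by Euclidean
#' connectivity (two points connected iff their distance is at most
#' `cluster_eps`); clusters below `min_cluster_size` points are discarded.
#' Each surviving cluster becomes one leaf, numbered by increasing base
#' height. The base point is the cluster point closest (horizontally) to
#' the vertical stem axis, the vertical line through the centroid of the
#' stem-labeled points (cloud centroid if no stem points survive).
#'
#' @param cloud a [labeled_cloud()] in metric space with semantic labels.
#' @param cluster_eps connectivity radius in metres (default 0.03).
#' @param min_cluster_size minimum points per leaf (default 50).
#' @return list of `leaf_instance` objects (`point_indices`, `base_point`,
#'   `length`, `width` in cm), ordered by base height; empty list when no
#'   leaf points exist.
#' @export
extract_leaf_instances <- function(cloud, cluster_eps = 0.03,
                                   min_cluster_size = 50L) {
  if (is.null(cloud$semantic)) stop("cloud must carry semantic labels")
  leaf_idx <- which(cloud$semantic == 1L)
  if (length(leaf_idx) == 0L) return(list())
  stem_idx <- which(cloud$semantic == 0L)
  axis_xy <- if (length(stem_idx) > 0L)
    colMeans(cloud$coords[stem_idx, 1:2, drop = FALSE])
  else colMeans(cloud$coords[, 1:2, drop = FALSE])
  lab <- cpp_euclidean_cluster(cloud$coords[leaf_idx, , drop = FALSE],
                               cluster_eps)
  out <- list()
  for (cl in unique(lab)) {
    members <- leaf_idx[lab == cl]
    if (length(members) < min_cluster_size) next
    pts <- cloud$coords[members, , drop = FALSE]
    d_axis <- sqrt((pts[, 1] - axis_xy[1])^2 + (pts[, 2] - axis_xy[2])^2)
    base <- pts[which.min(d_axis), ]
    dims <- leaf_dimensions(pts)
    out[[length(out) + 1L]] <- structure(
      list(point_indices = members, base_point = base,
           length = dims[1], width = dims[2]),
      class = "leaf_instance")
  }
  if (length(out) > 1L) {
    ord <- order(vapply(out, function(x) x$base_point[3], numeric(1)))
    out <- out[ord]
  }
  out
}

#' Leaf length and width via PCA and the minimum-area bounding rectangle
#'
#' The 3D leaf points are projected onto the plane of their first two
#' principal components; the minimum-area bounding rectangle of the
#' projection is found by rotating calipers over the convex hull, and its
#' longer and shorter sides are returned as leaf length and width.
#'
#' @param instance_points `n x 3` matrix of leaf points (n >= 3, not all
#'   collinear).
#' @return `c(length, width)` in cm (input metres); a collinear cluster
#'   yields width 0 with a warning.
#' @export
leaf_dimensions <- function(instance_points) {
  pts <- as.matrix(instance_points)
  if (nrow(pts) < 3L) stop("need at least 3 points")
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  proj <- pc$x[, 1:2, drop = FALSE]
  if (pc$sdev[2] < 1e-12) {
    warning("degenerate (collinear) leaf cluster: width is 0")
    return(c((max(proj[, 1]) - min(proj[, 1])) * 100, 0))
  }
  rect <- min_bounding_rectangle(proj)
  c(rect$sides[1] * 100, rect$sides[2] * 100)
}

#' Minimum-area bounding rectangle of a planar point set
#'
#' Rotating calipers: the minimum-area enclosing rectangle has a side
#' collinear with an edge of the convex hull, so each hull edge is tried as
#' the rectangle orientation and the smallest-area axis-aligned box in that
#' rotated frame wins.
#'
#' @param xy `n x 2` matrix.
#' @return list: `sides` (longer, shorter), `angle` (radians of the long
#'   side), `area`.
#' @export
min_bounding_rectangle <- function(xy) {
  xy <- as.matrix(xy)
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 2L) stop("degenerate point set")
  best <- NULL
  for (i in seq_len(nh)) {
    e <- hull[(i %% nh) + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-15) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    s1 <- max(pu) - min(pu)
    s2 <- max(pv) - min(pv)
    area <- s1 * s2
    if (is.null(best) || area < best$area) {
      ang <- if (s1 >= s2) atan2(u[2], u[1]) else atan2(v[2], v[1])
      best <- list(sides = c(max(s1, s2), min(s1, s2)), angle = ang,
                   area = area)
    }
  }
  if (is.null(best)) stop("degenerate point set")
  best
}

#' Internode length
#'
#' Vertical distance between the bases of the upper leaf (highest base)
#' and the middle leaf (median rank, `ceiling(n/2)` in ascending base
#' height order), in cm.
#'
#' @param instances list of leaf instances from [extract_leaf_instances()].
#' @return internode length in cm.
#' @export
internode_length <- function(instances) {
  if (length(instances) < 2L)
    stop("internode length needs at least 2 leaf instances")
  base_z <- vapply(instances, function(x) x$base_point[3], numeric(1))
  internode_from_base_heights(base_z) * 100
}

#' Extract all five phenotypic traits from a segmented cloud
#'
#' Assembles plant height, leaf number (number of leaf instances), per-leaf
#' lengths and widths, and internode length into one [trait_record()]. The
#' cloud must be de-normalized (metric) and semantically segmented.
#'
#' @param cloud a [labeled_cloud()] in metric space with semantic labels.
#' @param cluster_eps,min_cluster_size leaf instancing parameters, see
#'   [extract_leaf_instances()].
#' @return a [trait_record()]; with no recoverable leaves, a degenerate
#'   record with `leaf_number = 0` and `NA` dimensions is returned.
#' @export
extract_traits <- function(cloud, cluster_eps = 0.03, min_cluster_size = 50L) {
  height <- plant_height(cloud)
  inst <- extract_leaf_instances(cloud, cluster_eps, min_cluster_size)
  if (length(inst) == 0L) {
    return(structure(list(plant_height = height, leaf_lengths = numeric(),
                          leaf_widths = numeric(), leaf_number = 0L,
                          internode_length = NA_real_),
                     class = "trait_record"))
  }
  trait_record(
    plant_height = height,
    leaf_lengths = vapply(inst, `[[`, numeric(1), "length"),
    leaf_widths = vapply(inst, `[[`, numeric(1), "width"),
    internode_length = if (length(inst) >= 2L) internode_length(inst)
                       else NA_real_)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` between measured and predicted values.
#'
#' @param measured numeric vector (not constant, n >= 2).
#' @param predicted numeric vector of the same length.
#' @return dimensionless value (at most 1).
#' @export
r_squared <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal length")
  if (length(measured) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("R-squared undefined for constant measured values")
  1 - sum((measured - predicted)^2) / ss_tot
}

#' Root mean square error
#'
#' @param measured,predicted numeric vectors of equal length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal length")
  if (length(measured) < 1L) stop("need at least 1 observation")
  sqrt(mean((measured - predicted)^2))
}

#' Flat trait table from a list of records
#'
#' @param records list of [trait_record()]s.
#' @param ids optional plant identifiers.
#' @return data.frame with one row per plant: height, leaf count, mean leaf
#'   length/width and internode length (cm).
#' @export
trait_table <- function(records, ids = seq_along(records)) {
  data.frame(
    plant = ids,
    plant_height = vapply(records, `[[`, numeric(1), "plant_height"),
    leaf_number = vapply(records, function(r) as.numeric(r$leaf_number),
                         numeric(1)),
    mean_leaf_length = vapply(records, function(r)
      if (length(r$leaf_lengths)) mean(r$leaf_lengths) else NA_real_,
      numeric(1)),
    mean_leaf_width = vapply(records, function(r)
      if (length(r$leaf_widths)) mean(r$leaf_widths) else NA_real_,
      numeric(1)),
    internode_length = vapply(records, `[[`, numeric(1), "internode_length"))
}

#' Per-trait agreement between measured and predicted records
#'
#' Computes R-squared and RMSE for plant height, leaf number, mean leaf
#' length, mean leaf width and internode length over paired plants.
#'
#' @param measured,predicted lists of [trait_record()]s, paired by
#'   position.
#' @return data.frame with columns trait, r_squared, rmse.
#' @export
evaluate_traits <- function(measured, predicted) {
  mt <- trait_table(measured)
  pt <- trait_table(predicted)
  traits <- c("plant_height", "leaf_number", "mean_leaf_length",
              "mean_leaf_width", "internode_length")
  rows <- lapply(traits, function(tr) {
    m <- mt[[tr]]; p <- pt[[tr]]
    ok <- is.finite(m) & is.finite(p)
    data.frame(trait = tr,
               r_squared = if (sum(ok) >= 2 && stats::var(m[ok]) > 0)
                 r_squared(m[ok], p[ok]) else NA_real_,
               rmse = if (any(ok)) rmse(m[ok], p[ok]) else NA_real_,
               n = sum(ok))
  })
  do.call(rbind, rows)
}
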