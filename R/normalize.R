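#' Min-max normalization of a point cloud to the unit cube
#'
#' Each axis is mapped independently to `[0, 1]` by
#' `x_norm = (x - min_x) / R_x`, where `min_x` is the axis minimum and `R_x`
#' the axis range. The returned state stores `min_x` and `R_x` so that
#' [denormalize_cloud()] restores the original metric coordinates exactly
#' (`x_orig = x_norm * R_x + min_x`). A degenerate axis (zero extent) is
#' stored with `R_x = 1` and maps to 0, keeping the inversion exact.
#'
#' @param cloud a [labeled_cloud()] with at least 2 points and non-zero
#'   extent on at least one axis.
#' @return list with elements `cloud` (normalized) and `state`
#'   (class `normalization_state`: `min_per_axis`, `range_per_axis`).
#' @seealso [denormalize_cloud()]
#' @export
normalize_cloud <- function(cloud) {
  m <- cloud$coords
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  rng <- maxs - mins
  if (all(rng == 0)) stop("degenerate cloud: zero extent on every axis")
  rng[rng == 0] <- 1  # degenerate axis sentinel: maps to 0, inverts exactly
  normed <- sweep(sweep(m, 2, mins, "-"), 2, rng, "/")
  out <- cloud
  out$coords <- normed
  state <- structure(list(min_per_axis = mins, range_per_axis = rng),
                     class = "normalization_state")
  list(cloud = out, state = state)
}

#' Restore metric coordinates from a normalized cloud
#'
#' Applies `x_orig = x_norm * R_x + min_x` per axis, the exact inverse of
#' [normalize_cloud()]. Trait measurements are taken in this restored
#' metric space.
#'
#' @param cloud a normalized [labeled_cloud()].
#' @param state a `normalization_state` produced by [normalize_cloud()].
#' @return the de-normalized [labeled_cloud()].
#' @export
denormalize_cloud <- function(cloud, state) {
  if (!inherits(state, "normalization_state"))
    stop("state must be produced by normalize_cloud()")
  if (length(state$min_per_axis) != 3L || length(state$range_per_axis) != 3L)
    stop("state axis count mismatch: expected 3 axes")
  out <- cloud
  out$coords <- sweep(sweep(cloud$coords, 2, state$range_per_axis, "*"),
                      2, state$min_per_axis, "+")
  out
}
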