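# Brute-force oracles and shared fixtures. Every oracle here is a direct,
# independent implementation (plain loops over definitions), used to verify
# the package's vectorized / compiled counterparts.

# exact k nearest neighbours by full sort, ties by lower index
bf_knn <- function(query, ref, k) {
  t(apply(query, 1, function(q) {
    d <- sqrt(colSums((t(ref) - q)^2))
    order(d, seq_len(nrow(ref)))[seq_len(k)]
  }))
}

# greedy farthest point sampling by definition
bf_fps <- function(coords, m, start) {
  n <- nrow(coords)
  sel <- integer(m)
  sel[1] <- start
  mind <- sqrt(colSums((t(coords) - coords[start, ])^2))
  for (s in seq_len(m - 1L)) {
    nxt <- which.max(mind)  # which.max takes the lowest index on ties
    sel[s + 1L] <- nxt
    d <- sqrt(colSums((t(coords) - coords[nxt, ])^2))
    mind <- pmin(mind, d)
  }
  sel
}

# per-point mean distance to the k nearest neighbours (self excluded)
bf_mean_knn_dist <- function(coords, k) {
  n <- nrow(coords)
  sapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    mean(sort(d[-i])[seq_len(k)])
  })
}

# neighbourhood density by definition (Eq-style mean of inverse distances)
bf_density <- function(dist_rows, eps) {
  apply(dist_rows, 1, function(d) mean(1 / (d + eps)))
}

# mask-based OA / IoU, independent of the confusion-matrix path
bf_metrics <- function(pred, true, n_classes) {
  oa <- 100 * mean(pred == true)
  iou <- sapply(0:(n_classes - 1L), function(c) {
    inter <- sum(pred == c & true == c)
    uni <- sum(pred == c | true == c)
    if (uni == 0) NA_real_ else 100 * inter / uni
  })
  list(oa = oa, iou = iou, miou = mean(iou, na.rm = TRUE))
}

# minimum-area bounding rectangle by dense rotation grid
bf_min_rect <- function(xy, n_angles = 7200L) {
  best <- Inf; sides <- c(NA, NA)
  for (a in seq(0, pi / 2, length.out = n_angles)) {
    u <- c(cos(a), sin(a)); v <- c(-u[2], u[1])
    s1 <- diff(range(xy %*% u)); s2 <- diff(range(xy %*% v))
    if (s1 * s2 < best) { best <- s1 * s2; sides <- c(max(s1, s2), min(s1, s2)) }
  }
  sides
}

# a small plant raised above a dominant ground patch, emulating a field
# crop: the single-plant crops the pipeline consumes sit on, not in, the
# ground, and the ground plane carries more points than any plane through
# the canopy
elevated_plant_with_ground <- function(noise = 0.01, seed = 21,
                                       ground_extent = 3, lift = 0.3) {
  spec <- plant_spec(stem_height = 1.2, n_leaves = 5, noise_sigma = noise,
                     ground_extent = ground_extent, seed = seed)
  p <- make_plant(spec)
  p$cloud$coords[, 3] <- p$cloud$coords[, 3] + lift
  list(cloud = add_ground_and_outliers(p$cloud, spec), spec = spec,
       traits = p$traits)
}

# tiny network configuration that keeps test-time training cheap
tiny_config <- function(num_points = 64L, use_lse = TRUE, use_dap = TRUE,
                        dropout = 0) {
  segnet_config(num_points = num_points, k = 4L,
                lift_channels = list(c(8L), c(12L)),
                fp_channels = c(12L, 8L), head_hidden = 8L,
                dropout = dropout, use_lse = use_lse, use_dap = use_dap)
}

# build a normalized fixed-size training sample from a plant cloud
plant_sample <- function(cloud, num_points, seed) {
  rs <- resample_to_count(cloud, num_points, seed = seed)
  nm <- normalize_cloud(rs)
  list(coords = nm$cloud$coords, labels = rs$semantic)
}
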