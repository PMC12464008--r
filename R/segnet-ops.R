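# Building blocks of the segmentation encoder. All neighbour-feature
# matrices are stored "center-major": an (M*K) x d matrix whose row
# (i-1)*K + k is neighbour k of center i. Group helpers below loop over k
# (K is small) so every elementwise operation stays a vectorized matrix op.

expand_centers <- function(X, K) cpp_expand_centers(X, as.integer(K))

# channelwise max over the K neighbours; argk records which neighbour won
# (first winner on ties), needed to route gradients.
group_max <- function(X, M, K) cpp_group_max(X, as.integer(M), as.integer(K))

group_max_backward <- function(dVal, argk, M, K)
  cpp_group_max_backward(dVal, argk, as.integer(M), as.integer(K))

# per-channel softmax over the K neighbours of each center
group_softmax <- function(S, M, K)
  cpp_group_softmax(S, as.integer(M), as.integer(K))

group_sum <- function(X, M, K) cpp_group_sum(X, as.integer(M), as.integer(K))

#' Farthest point sampling
#'
#' Greedy subsampling: starting from a (seeded) random point, repeatedly
#' selects the point maximizing the minimum distance to the points already
#' selected. Ties break toward the lower index.
#'
#' @param coords numeric `N x 3` matrix.
#' @param m number of points to select, `1 <= m <= N`.
#' @param seed optional integer seed for the random start.
#' @param start optional explicit 1-based start index (overrides `seed`).
#' @return integer vector of `m` selected indices, start first.
#' @export
farthest_point_sample <- function(coords, m, seed = NULL, start = NULL) {
  n <- nrow(coords)
  if (m < 1L || m > n) stop("m must lie in [1, N]")
  if (is.null(start)) {
    if (!is.null(seed)) {
      old <- get_rng_state(); on.exit(set_rng_state(old))
      set.seed(seed)
    }
    start <- sample.int(n, 1L)
  }
  cpp_fps(coords, as.integer(m), as.integer(start))
}

#' K-nearest-neighbour grouping around center points
#'
#' For each center, the exact K nearest cloud points by Euclidean distance
#' (ties toward the lower index). A center is always its own first
#' neighbour.
#'
#' @param coords numeric `N x 3` matrix.
#' @param center_indices 1-based indices of the centers.
#' @param k neighbourhood size, `k <= N` (default 16).
#' @return object of class `neighborhood`: `centers`, `idx` (`M x k`,
#'   1-based into `coords`), `dist` (`M x k`), `k`.
#' @export
knn_group <- function(coords, center_indices, k = 16L) {
  if (k > nrow(coords)) stop("k exceeds the number of points")
  if (k < 1L) stop("k must be >= 1")
  res <- cpp_knn_group(coords, as.integer(center_indices), as.integer(k))
  structure(list(centers = as.integer(center_indices), idx = res$idx,
                 dist = res$dist, k = as.integer(k)),
            class = "neighborhood")
}

# Gather order turning a neighborhood into center-major row indices.
nbhd_gather <- function(nbhd) as.vector(t(nbhd$idx))

# Geometric encoding input: [p_i, p_ik, p_i - p_ik, d(p_i, p_ik)], 10 wide.
lse_geometry <- function(coords, nbhd) {
  K <- nbhd$k
  gi <- nbhd_gather(nbhd)
  Pc <- expand_centers(coords[nbhd$centers, , drop = FALSE], K)
  Pn <- coords[gi, , drop = FALSE]
  cbind(Pc, Pn, Pc - Pn, as.vector(t(nbhd$dist)))
}

#' Local spatial encoding of a neighbourhood
#'
#' For every center `i` and neighbour `k`, concatenates the absolute
#' coordinates of both points, their relative coordinates and their
#' Euclidean distance into a 10-vector, maps it through a shared MLP to the
#' feature width `d`, and concatenates the result with the neighbour's
#' current feature, yielding the position-enhanced feature `t_ik` of width
#' `2 d`.
#'
#' @param coords numeric `N x 3` matrix (model-space coordinates).
#' @param features numeric `N x d` per-point features; column count must
#'   equal the MLP output width.
#' @param nbhd a [knn_group()] neighbourhood.
#' @param mlp an [mlp_network()] mapping 10 inputs to `d` outputs.
#' @return list: `t` (`(M*K) x 2d` position-enhanced features,
#'   center-major rows), `r` (encoded geometry, `(M*K) x d`), `geometry`
#'   (the raw 10-column encoding), `M`, `K`.
#' @export
lse_encode <- function(coords, features, nbhd, mlp) {
  stopifnot(inherits(nbhd, "neighborhood"), inherits(mlp, "mlp_network"))
  d_out <- mlp$dims[length(mlp$dims)]
  if (mlp$dims[1] != 10L)
    stop("LSE MLP must accept the 10-wide geometric encoding")
  if (ncol(features) != d_out)
    stop(sprintf("feature width (%d) must match MLP output width (%d)",
                 ncol(features), d_out))
  G <- lse_geometry(coords, nbhd)
  r <- mlp_forward(mlp, G)$out
  q <- features[nbhd_gather(nbhd), , drop = FALSE]
  list(t = cbind(r, q), r = r, geometry = G,
       M = length(nbhd$centers), K = nbhd$k)
}

#' Neighbourhood density of center points
#'
#' `D_i = (1/K) * sum_k 1 / (d(p_i, p_ik) + epsilon)`. The center's
#' self-distance contributes `1/epsilon`, which is finite and cancels in
#' the subsequent min-max normalization.
#'
#' @param coords numeric `N x 3` matrix (unused beyond validation; the
#'   distances are taken from `nbhd`).
#' @param nbhd a [knn_group()] neighbourhood.
#' @param epsilon small positive guard against division by zero.
#' @return numeric vector of raw densities, one per center.
#' @export
neighborhood_density <- function(coords, nbhd, epsilon = 1e-8) {
  stopifnot(inherits(nbhd, "neighborhood"))
  if (epsilon <= 0) stop("epsilon must be > 0")
  rowMeans(1 / (nbhd$dist + epsilon))
}

#' Min-max normalization of a density field
#'
#' Maps raw densities to `[0, 1]` by
#' `(D - D_min) / (D_max - D_min)`; a constant field maps to all zeros.
#'
#' @param raw numeric vector of raw densities.
#' @return object of class `density_field`: `raw`, `normalized`, `d_min`,
#'   `d_max`.
#' @export
normalize_density <- function(raw) {
  if (length(raw) < 1L) stop("empty density field")
  d_min <- min(raw); d_max <- max(raw)
  normalized <- if (d_max > d_min) (raw - d_min) / (d_max - d_min)
                else rep(0, length(raw))
  structure(list(raw = raw, normalized = normalized,
                 d_min = d_min, d_max = d_max),
            class = "density_field")
}

#' Partition centers into high- and low-density regions
#'
#' A center is high-density iff its normalized density strictly exceeds the
#' mean normalized density of its K neighbours; otherwise low. The two
#' masks are complementary by construction.
#'
#' @param field a [normalize_density()] field defined over all points the
#'   neighbourhood indexes (centers and neighbours).
#' @param nbhd a [knn_group()] neighbourhood.
#' @return logical vector `high_mask`, one entry per center.
#' @export
partition_by_density <- function(field, nbhd) {
  stopifnot(inherits(field, "density_field"), inherits(nbhd, "neighborhood"))
  dn <- field$normalized
  if (max(nbhd$idx) > length(dn) || max(nbhd$centers) > length(dn))
    stop("density field does not cover all neighbourhood indices")
  nbr_mean <- rowMeans(matrix(dn[nbhd$idx], nrow = nrow(nbhd$idx)))
  dn[nbhd$centers] > nbr_mean
}

#' Attention pooling over neighbourhoods
#'
#' Neighbour features are scored by a shared function `g` (an MLP mapping
#' d-vectors to d-vectors), the scores are softmax-normalized per channel
#' over the K neighbours, and the features are aggregated as the weighted
#' elementwise sum.
#'
#' @param nbr_features `(M*K) x d` neighbour features, center-major rows
#'   (e.g. `$t` from [lse_encode()]).
#' @param nbhd the [knn_group()] neighbourhood (supplies M and K).
#' @param scorer an [mlp_network()] with matching input and output width.
#' @return `M x d` matrix of attention-pooled features.
#' @export
attention_pool <- function(nbr_features, nbhd, scorer) {
  stopifnot(inherits(nbhd, "neighborhood"), inherits(scorer, "mlp_network"))
  M <- length(nbhd$centers); K <- nbhd$k
  if (nrow(nbr_features) != M * K)
    stop("nbr_features rows must equal M * K")
  d <- ncol(nbr_features)
  if (scorer$dims[1] != d || scorer$dims[length(scorer$dims)] != d)
    stop("scorer must map d-vectors to d-vectors")
  S <- mlp_forward(scorer, nbr_features)$out
  W <- group_softmax(S, M, K)
  cpp_group_wsum(W, nbr_features, M, K)
}

#' Max pooling over neighbourhoods
#'
#' Channelwise maximum of the K neighbour features of each center.
#'
#' @inheritParams attention_pool
#' @return `M x d` matrix of max-pooled features.
#' @export
max_pool <- function(nbr_features, nbhd) {
  stopifnot(inherits(nbhd, "neighborhood"))
  M <- length(nbhd$centers); K <- nbhd$k
  if (nrow(nbr_features) != M * K)
    stop("nbr_features rows must equal M * K")
  group_max(nbr_features, M, K)$val
}

#' Density-aware pooling
#'
#' Computes both the attention-pooled and the max-pooled aggregate of every
#' neighbourhood, then concatenates them channelwise with the
#' density-selected branch first: high-density centers lead with the max
#' aggregate (attention as the complementary slot), low-density centers
#' lead with the attention aggregate. A fusion MLP reduces the
#' concatenation to the output width.
#'
#' @param nbr_features `(M*K) x d` position-enhanced neighbour features.
#' @param field a [normalize_density()] field over all cloud points.
#' @param nbhd the [knn_group()] neighbourhood.
#' @param scorer attention scorer (d to d [mlp_network()]).
#' @param fusion fusion [mlp_network()] mapping `2 d` to the output width.
#' @return `M x d_out` matrix of fused features.
#' @export
dap_pool <- function(nbr_features, field, nbhd, scorer, fusion) {
  stopifnot(inherits(fusion, "mlp_network"))
  d <- ncol(nbr_features)
  if (fusion$dims[1] != 2L * d)
    stop("fusion MLP input width must be twice the feature width")
  high <- partition_by_density(field, nbhd)
  f_att <- attention_pool(nbr_features, nbhd, scorer)
  f_max <- max_pool(nbr_features, nbhd)
  sel <- f_att; sel[high, ] <- f_max[high, ]
  comp <- f_max; comp[high, ] <- f_att[high, ]
  mlp_forward(fusion, cbind(sel, comp))$out
}

#' Inverse-distance feature interpolation (feature propagation)
#'
#' For every fine point, the features of its 3 nearest coarse points are
#' averaged with weights `1/(d + epsilon)` normalized to sum to one; used
#' by the decoder to upsample coarse features back onto finer point sets.
#'
#' @param coords_fine `Nf x 3` fine coordinates.
#' @param coords_coarse `Nc x 3` coarse coordinates (non-empty).
#' @param feats_coarse `Nc x d` coarse features.
#' @param epsilon weight guard (default 1e-8).
#' @return list: `feats` (`Nf x d` interpolated features), `idx`, `w`
#'   (`Nf x 3` neighbour indices and normalized weights).
#' @export
interpolate_features <- function(coords_fine, coords_coarse, feats_coarse,
                                 epsilon = 1e-8) {
  if (nrow(coords_coarse) < 1L) stop("coarse level must be non-empty")
  k <- min(3L, nrow(coords_coarse))
  kn <- cpp_knn(coords_fine, coords_coarse, k)
  w <- 1 / (kn$dist + epsilon)
  w <- w / rowSums(w)
  out <- matrix(0, nrow(coords_fine), ncol(feats_coarse))
  for (j in seq_len(k))
    out <- out + w[, j] * feats_coarse[kn$idx[, j], , drop = FALSE]
  list(feats = out, idx = kn$idx, w = w)
}
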