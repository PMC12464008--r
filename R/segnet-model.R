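# A density-aware PointNet++-style encoder-decoder. Encoder: stacked set
# abstraction (SA) layers, each halving the center count (FPS), grouping by
# KNN, lifting features with a shared MLP, enhancing neighbour features with
# local spatial encoding (LSE) and aggregating with density-aware pooling
# (DAP). Decoder: feature propagation (FP) by inverse-distance interpolation
# with skip connections, then a per-point classifier head. Both improvement
# modules can be disabled, which reproduces a plain SA layer (grouped MLP on
# [relative coords, features] + max pooling) for ablation studies.

#' Segmentation network configuration
#'
#' @param num_points fixed input size (default 8192).
#' @param k neighbourhood size for grouping (default 16).
#' @param lift_channels list of per-layer MLP widths for the feature lift;
#'   one element per SA layer (defaults give three layers of widths
#'   64-128, 128-256, 256-512).
#' @param use_lse enable the local spatial encoding module.
#' @param use_dap enable the density-aware pooling module.
#' @param fp_channels decoder unit-MLP widths, top-down, one per FP layer.
#' @param head_hidden classifier hidden width.
#' @param dropout classifier dropout probability during training.
#' @param n_classes number of semantic classes (2: stem, leaf).
#' @param density_epsilon guard in the density estimate.
#' @param fp_epsilon guard in the interpolation weights.
#' @return object of class `segnet_config`.
#' @export
segnet_config <- function(num_points = 8192L, k = 16L,
                          lift_channels = list(c(64L, 128L), c(128L, 256L),
                                               c(256L, 512L)),
                          use_lse = TRUE, use_dap = TRUE,
                          fp_channels = c(256L, 256L, 128L),
                          head_hidden = 128L, dropout = 0.5,
                          n_classes = 2L, density_epsilon = 1e-8,
                          fp_epsilon = 1e-8) {
  n_sa <- length(lift_channels)
  if (n_sa < 1L) stop("need at least one SA layer")
  if (length(fp_channels) != n_sa)
    stop("fp_channels must supply one width per SA layer")
  if (num_points < 2^n_sa) stop("num_points too small for the layer count")
  if (k < 1L) stop("k must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(num_points = as.integer(num_points), k = as.integer(k),
                 lift_channels = lapply(lift_channels, as.integer),
                 use_lse = isTRUE(use_lse), use_dap = isTRUE(use_dap),
                 fp_channels = as.integer(fp_channels),
                 head_hidden = as.integer(head_hidden), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 density_epsilon = density_epsilon, fp_epsilon = fp_epsilon),
            class = "segnet_config")
}

#' Initialize the segmentation network
#'
#' Builds all shared MLPs with He-initialized weights. Feature widths per
#' level follow the lift widths; with LSE the position-enhanced features
#' are twice the lift width, and with DAP a fusion MLP reduces the
#' two concatenated pooling branches back to the lift width.
#'
#' @param config a [segnet_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `segnet_model` (`config`, `params`, per-level
#'   feature widths).
#' @export
segnet_init <- function(config = segnet_config(), seed = 1L) {
  stopifnot(inherits(config, "segnet_config"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  n_sa <- length(config$lift_channels)
  d <- 3L  # level-0 features: the normalized coordinates
  dims <- integer(n_sa + 1L); dims[1] <- d
  sa <- vector("list", n_sa)
  for (l in seq_len(n_sa)) {
    widths <- config$lift_channels[[l]]
    cl <- widths[length(widths)]
    layer <- list()
    if (config$use_lse) {
      layer$lift <- mlp_network(c(d, widths), norm = TRUE)
      layer$lse <- mlp_network(c(10L, widths), norm = TRUE)
      td <- 2L * cl
    } else {
      layer$lift <- mlp_network(c(3L + d, widths), norm = TRUE)
      td <- cl
    }
    if (config$use_dap) {
      layer$scorer <- mlp_network(c(td, td), final_activation = FALSE)
      layer$fusion <- mlp_network(c(2L * td, cl), norm = TRUE)
      d_out <- cl
    } else {
      d_out <- td
    }
    sa[[l]] <- layer
    d <- d_out
    dims[l + 1L] <- d
  }
  fp <- vector("list", n_sa)
  d_up <- dims[n_sa + 1L]
  for (l in rev(seq_len(n_sa))) {
    # FP producing level l-1 from coarse level l; skip feats width dims[l]
    fp[[l]] <- mlp_network(c(d_up + dims[l],
                             config$fp_channels[n_sa - l + 1L]), norm = TRUE)
    d_up <- config$fp_channels[n_sa - l + 1L]
  }
  head <- list(hidden = mlp_network(c(d_up, config$head_hidden),
                                    norm = TRUE),
               out = mlp_network(c(config$head_hidden, config$n_classes),
                                 final_activation = FALSE))
  structure(list(config = config,
                 params = list(sa = sa, fp = fp, head = head),
                 level_dims = dims),
            class = "segnet_model")
}

#' @export
print.segnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<segnet_model> %d SA layers | num_points %d | k %d | ",
                     "LSE %s | DAP %s | %d parameters\n"),
              length(cfg$lift_channels), cfg$num_points, cfg$k,
              cfg$use_lse, cfg$use_dap,
              length(flatten_params(x$params))))
  invisible(x)
}

# ---- set abstraction -------------------------------------------------------

sa_forward <- function(layer, config, P, Fin, start) {
  N <- nrow(P)
  M <- N %/% 2L
  K <- min(config$k, N)
  centers <- cpp_fps(P, M, start)
  nbhd <- knn_group(P, centers, K)
  gi <- nbhd_gather(nbhd)
  cc <- list(N = N, M = M, K = K, centers = centers, nbhd = nbhd, gi = gi)

  if (config$use_lse) {
    lift <- mlp_forward(layer$lift, Fin)
    G <- lse_geometry(P, nbhd)
    lse <- mlp_forward(layer$lse, G)
    t <- cbind(lse$out, lift$out[gi, , drop = FALSE])
    cc$lift <- lift; cc$lse <- lse
  } else {
    Pc <- expand_centers(P[centers, , drop = FALSE], K)
    Xg <- cbind(Pc - P[gi, , drop = FALSE], Fin[gi, , drop = FALSE])
    lift <- mlp_forward(layer$lift, Xg)
    t <- lift$out
    cc$lift <- lift
  }
  cc$td <- ncol(t)

  if (config$use_dap) {
    nb_all <- cpp_knn_group(P, seq_len(N), K)
    raw <- rowMeans(1 / (nb_all$dist + config$density_epsilon))
    field <- normalize_density(raw)
    high <- partition_by_density(field, nbhd)
    S <- mlp_forward(layer$scorer, t)
    W <- group_softmax(S$out, M, K)
    f_att <- cpp_group_wsum(W, t, M, K)
    mx <- group_max(t, M, K)
    sel <- f_att; sel[high, ] <- mx$val[high, , drop = FALSE]
    comp <- mx$val; comp[high, ] <- f_att[high, , drop = FALSE]
    fus <- mlp_forward(layer$fusion, cbind(sel, comp))
    out <- fus$out
    cc$t <- t; cc$high <- high; cc$S <- S; cc$W <- W; cc$mx <- mx
    cc$fus <- fus
  } else {
    mx <- group_max(t, M, K)
    out <- mx$val
    cc$mx <- mx
  }
  list(coords = P[centers, , drop = FALSE], feats = out, cache = cc)
}

sa_backward <- function(layer, config, cache, dOut) {
  M <- cache$M; K <- cache$K
  grads <- list()
  if (config$use_dap) {
    td <- cache$td
    fb <- mlp_backward(layer$fusion, cache$fus$cache, dOut)
    grads$fusion <- fb$grads
    dSel <- fb$dX[, seq_len(td), drop = FALSE]
    dComp <- fb$dX[, td + seq_len(td), drop = FALSE]
    high <- cache$high
    dFmax <- dComp; dFmax[high, ] <- dSel[high, , drop = FALSE]
    dFatt <- dSel; dFatt[high, ] <- dComp[high, , drop = FALSE]
    dT <- group_max_backward(dFmax, cache$mx$argk, M, K)
    # attention branch: F_att = sum_k W_k * t_k, W = softmax_k(scores)
    att <- cpp_attention_backward(cache$W, cache$t, dFatt, M, K)
    sb <- mlp_backward(layer$scorer, cache$S$cache, att$dS)
    grads$scorer <- sb$grads
    dT <- dT + att$dX + sb$dX
  } else {
    dT <- group_max_backward(dOut, cache$mx$argk, M, K)
  }

  if (config$use_lse) {
    cl <- cache$td %/% 2L
    dr <- dT[, seq_len(cl), drop = FALSE]
    dq <- dT[, cl + seq_len(cl), drop = FALSE]
    lb <- mlp_backward(layer$lse, cache$lse$cache, dr)
    grads$lse <- lb$grads
    dQ <- matrix(0, cache$N, cl)
    rs <- rowsum(dq, cache$gi)
    dQ[as.integer(rownames(rs)), ] <- rs
    qb <- mlp_backward(layer$lift, cache$lift$cache, dQ)
    grads$lift <- qb$grads
    dFin <- qb$dX
  } else {
    gb <- mlp_backward(layer$lift, cache$lift$cache, dT)
    grads$lift <- gb$grads
    dfeat <- gb$dX[, -(1:3), drop = FALSE]
    dFin <- matrix(0, cache$N, ncol(dfeat))
    rs <- rowsum(dfeat, cache$gi)
    dFin[as.integer(rownames(rs)), ] <- rs
  }
  # align grad components with the layer's parameter order (positional
  # pairing is assumed by the optimizer and the flatteners)
  list(dFin = dFin, grads = grads[names(layer)])
}

# ---- feature propagation ---------------------------------------------------

fp_forward <- function(mlp, config, coords_fine, feats_skip, coords_coarse,
                       feats_coarse) {
  ip <- interpolate_features(coords_fine, coords_coarse, feats_coarse,
                             config$fp_epsilon)
  X <- cbind(ip$feats, feats_skip)
  mf <- mlp_forward(mlp, X)
  list(feats = mf$out,
       cache = list(ip = ip, mf = mf, dc = ncol(feats_coarse),
                    nc = nrow(coords_coarse)))
}

fp_backward <- function(mlp, cache, dOut) {
  mb <- mlp_backward(mlp, cache$mf$cache, dOut)
  dc <- cache$dc
  dInterp <- mb$dX[, seq_len(dc), drop = FALSE]
  dSkip <- mb$dX[, -seq_len(dc), drop = FALSE]
  dCoarse <- matrix(0, cache$nc, dc)
  for (j in seq_len(ncol(cache$ip$idx))) {
    rs <- rowsum(cache$ip$w[, j] * dInterp, cache$ip$idx[, j])
    dCoarse[as.integer(rownames(rs)), ] <-
      dCoarse[as.integer(rownames(rs)), , drop = FALSE] + rs
  }
  list(dCoarse = dCoarse, dSkip = dSkip, grads = mb$grads)
}

# ---- full network ----------------------------------------------------------

#' Forward pass of the segmentation network
#'
#' Input coordinates must be normalized to the unit cube and contain
#' exactly `config$num_points` points. Returns per-point stem/leaf logits
#' aligned with the input row order. The farthest-point-sampling start of
#' the first layer is random (drawn from the current RNG stream, so it is
#' reproducible under a seed) unless `fps_start` pins it; deeper layers
#' start deterministically from the first center of the previous layer.
#'
#' @param model a [segnet_init()] model.
#' @param coords `N x 3` normalized coordinates.
#' @param training apply dropout (uses the current RNG stream).
#' @param fps_start optional 1-based start index for the first FPS.
#' @param keep_cache keep intermediate activations (for backprop).
#' @return list with `logits` (`N x n_classes`) and, if requested, `cache`.
#' @export
segnet_forward <- function(model, coords, training = FALSE, fps_start = NULL,
                           keep_cache = FALSE) {
  stopifnot(inherits(model, "segnet_model"))
  cfg <- model$config
  coords <- as.matrix(coords)
  if (nrow(coords) != cfg$num_points)
    stop(sprintf("expected %d points (config num_points), got %d",
                 cfg$num_points, nrow(coords)))
  n_sa <- length(model$params$sa)
  levels <- vector("list", n_sa + 1L)
  levels[[1]] <- list(coords = coords, feats = coords)
  sa_caches <- vector("list", n_sa)
  start <- if (is.null(fps_start)) sample.int(nrow(coords), 1L)
           else as.integer(fps_start)
  for (l in seq_len(n_sa)) {
    res <- sa_forward(model$params$sa[[l]], cfg, levels[[l]]$coords,
                      levels[[l]]$feats, start)
    levels[[l + 1L]] <- list(coords = res$coords, feats = res$feats)
    sa_caches[[l]] <- res$cache
    start <- 1L  # deeper layers start from the previous start point
  }
  fp_caches <- vector("list", n_sa)
  up <- levels[[n_sa + 1L]]$feats
  for (l in rev(seq_len(n_sa))) {
    res <- fp_forward(model$params$fp[[l]], cfg, levels[[l]]$coords,
                      levels[[l]]$feats, levels[[l + 1L]]$coords, up)
    up <- res$feats
    fp_caches[[l]] <- res$cache
  }
  hid <- mlp_forward(model$params$head$hidden, up)
  H <- hid$out
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                        nrow(H), ncol(H))
    H <- H * drop_mask
  }
  outc <- mlp_forward(model$params$head$out, H)
  out <- list(logits = outc$out)
  if (keep_cache)
    out$cache <- list(levels = levels, sa = sa_caches, fp = fp_caches,
                      hid = hid, drop_mask = drop_mask, outc = outc,
                      fp_up_in = NULL)
  out
}

# Backward pass: gradient of the loss w.r.t. every trainable weight, given
# the gradient at the logits. Returns a grads structure shaped like
# zero_like(model$params).
segnet_backward <- function(model, cache, dLogits) {
  cfg <- model$config
  n_sa <- length(model$params$sa)
  ob <- mlp_backward(model$params$head$out, cache$outc$cache, dLogits)
  dH <- ob$dX
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  hb <- mlp_backward(model$params$head$hidden, cache$hid$cache, dH)
  grads <- list(sa = vector("list", n_sa), fp = vector("list", n_sa),
                head = list(hidden = hb$grads, out = ob$grads))
  # decoder backward: walk FP layers bottom-up (fine to coarse)
  d_up <- hb$dX                         # gradient at the FP output of level 0
  skipg <- vector("list", n_sa + 1L)    # gradient into encoder feats per level
  for (l in seq_len(n_sa)) {
    fb <- fp_backward(model$params$fp[[l]], cache$fp[[l]], d_up)
    grads$fp[[l]] <- fb$grads
    skipg[[l]] <- fb$dSkip              # encoder level l-1 skip gradient
    d_up <- fb$dCoarse                  # gradient at FP input of level l
  }
  # encoder backward, top level first; d_up now sits at encoder top feats
  d_feats <- d_up
  for (l in rev(seq_len(n_sa))) {
    sb <- sa_backward(model$params$sa[[l]], cfg, cache$sa[[l]], d_feats)
    grads$sa[[l]] <- sb$grads
    if (l > 1L) d_feats <- sb$dFin + skipg[[l]]
  }
  grads
}

#' Segment a cloud with a trained model
#'
#' Convenience wrapper: normalizes the cloud, resamples it to the model's
#' input size, runs the forward pass and returns the resampled cloud with
#' predicted semantic labels, de-normalized back to metric space.
#'
#' @param model a trained [segnet_init()] model.
#' @param cloud a metric-space [labeled_cloud()].
#' @param seed integer seed controlling resampling and the FPS start.
#' @return list: `cloud` (metric space, predicted labels), `logits`,
#'   `state` (the [normalize_cloud()] state).
#' @export
segment_cloud <- function(model, cloud, seed = 1L) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  rs <- resample_to_count(cloud, model$config$num_points)
  nm <- normalize_cloud(rs)
  fw <- segnet_forward(model, nm$cloud$coords)
  pred <- max.col(fw$logits, ties.method = "first") - 1L
  out <- denormalize_cloud(nm$cloud, nm$state)
  out$semantic <- pred
  list(cloud = out, logits = fw$logits, state = nm$state,
       true_semantic = rs$semantic)
}
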