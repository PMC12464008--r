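# Minimal shared-MLP machinery with hand-derived backprop.
#
# A "shared MLP" applies the same fully connected stack to every row of its
# input (the per-point / per-neighbour networks of point-cloud models).
# Parameters are plain R matrices so the whole model is a nested list of
# numeric leaves, which makes Adam updates, serialization and
# finite-difference gradient checks straightforward.

#' Shared multilayer perceptron
#'
#' A stack of fully connected layers applied row-wise, with ReLU
#' activations. Used as the building block of the segmentation network;
#' exported so the spatial-encoding and pooling operators can be exercised
#' with caller-supplied (e.g. hand-fixed) weights.
#'
#' @param dims integer vector of layer widths, input first,
#'   e.g. `c(10, 64, 128)`.
#' @param final_activation apply ReLU after the last layer (`FALSE` for
#'   linear output heads / score functions).
#' @param norm normalize each layer's pre-activations per channel over the
#'   rows (points/neighbours) with learned scale and shift, the
#'   batch-normalization convention of point-cloud networks applied per
#'   cloud. Normalized layers learn `W`, `gamma`, `beta`; plain layers
#'   learn `W`, `b`.
#' @return object of class `mlp_network`; weights use He initialization
#'   from the current RNG stream.
#' @export
mlp_network <- function(dims, final_activation = TRUE, norm = FALSE) {
  if (length(dims) < 2L) stop("an MLP needs at least input and output widths")
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- dims[i]
    W <- matrix(stats::rnorm(fan_in * dims[i + 1L], sd = sqrt(2 / fan_in)),
                fan_in, dims[i + 1L])
    layers[[i]] <- if (norm)
      list(W = W, gamma = rep(1, dims[i + 1L]), beta = numeric(dims[i + 1L]))
    else
      list(W = W, b = numeric(dims[i + 1L]))
  }
  structure(list(layers = layers, final_activation = final_activation,
                 dims = dims, norm = norm),
            class = "mlp_network")
}

BN_EPS <- 1e-5

# Forward pass on an n x dims[1] matrix. Returns list(out, cache).
mlp_forward <- function(mlp, X) {
  nl <- length(mlp$layers)
  norm <- isTRUE(mlp$norm)
  cache <- vector("list", nl)
  A <- X
  for (i in seq_len(nl)) {
    ly <- mlp$layers[[i]]
    Z <- A %*% ly$W
    cc <- list(A = A)
    if (norm) {
      n <- nrow(Z)
      mu <- colMeans(Z)
      Zc <- Z - rep(mu, each = n)
      s <- sqrt(colMeans(Zc * Zc) + BN_EPS)
      Zh <- Zc / rep(s, each = n)
      Z <- Zh * rep(ly$gamma, each = n) + rep(ly$beta, each = n)
      cc$Zh <- Zh
      cc$s <- s
    } else {
      Z <- Z + rep(ly$b, each = nrow(Z))
    }
    act <- i < nl || mlp$final_activation
    cc$relu <- act
    if (act) cc$mask <- Z > 0
    cache[[i]] <- cc
    A <- if (act) Z * cc$mask else Z
  }
  list(out = A, cache = cache)
}

# Backward pass; dOut is the gradient at the output. Returns dX and grads
# shaped like mlp$layers.
mlp_backward <- function(mlp, cache, dOut) {
  nl <- length(mlp$layers)
  norm <- isTRUE(mlp$norm)
  grads <- vector("list", nl)
  dA <- dOut
  for (i in rev(seq_len(nl))) {
    cc <- cache[[i]]
    ly <- mlp$layers[[i]]
    dY <- if (cc$relu) dA * cc$mask else dA
    if (norm) {
      n <- nrow(dY)
      dgamma <- colSums(dY * cc$Zh)
      dbeta <- colSums(dY)
      dZh <- dY * rep(ly$gamma, each = n)
      # standard batch-norm backward over the row dimension
      dZ <- (dZh - rep(colMeans(dZh), each = n) -
               cc$Zh * rep(colMeans(dZh * cc$Zh), each = n)) /
        rep(cc$s, each = n)
      grads[[i]] <- list(W = crossprod(cc$A, dZ), gamma = dgamma,
                         beta = dbeta)
    } else {
      dZ <- dY
      grads[[i]] <- list(W = crossprod(cc$A, dZ), b = colSums(dZ))
    }
    dA <- dZ %*% t(ly$W)
  }
  list(dX = dA, grads = grads)
}

# Zero-filled gradient skeleton for a nested parameter list. mlp_network
# objects contribute only their layer weights; non-numeric leaves (flags,
# dims) are dropped so the optimizer never touches configuration.
zero_like <- function(p) {
  if (inherits(p, "mlp_network")) return(zero_like(p$layers))
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

# Elementwise combination of two identically shaped nested lists.
leaf_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- leaf_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

# Flatten every trainable leaf (mlp layer weights) into one numeric vector,
# and write such a vector back into an identically shaped structure; used by
# the finite-difference gradient checks.
flatten_params <- function(p) {
  if (inherits(p, "mlp_network")) return(flatten_params(p$layers))
  if (is.list(p)) return(unlist(lapply(p, flatten_params), use.names = FALSE))
  as.numeric(p)
}

unflatten_params <- function(skeleton, v) {
  pos <- 0L
  fill <- function(p) {
    if (inherits(p, "mlp_network")) {
      p$layers <- fill(p$layers)
      return(p)
    }
    if (is.list(p)) return(lapply(p, fill))
    n <- length(p)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(p)) dim(out) <- dim(p)
    out
  }
  out <- fill(skeleton)
  if (pos != length(v)) stop("parameter vector length mismatch")
  out
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# One Adam step with decoupled-from-nothing classic L2 weight decay folded
# into the gradient (the convention behind a "decay_rate" hyperparameter).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (inherits(p, "mlp_network")) {
      r <- upd(p$layers, g, m, v)
      p$layers <- r$p
      return(list(p = p, m = r$m, v = r$v))
    }
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
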