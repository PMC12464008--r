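test_that("configuration and halving contracts hold through the encoder", {
  expect_error(segnet_config(lift_channels = list(c(8L)),
                             fp_channels = c(8L, 8L)), "one width")
  expect_error(segnet_config(num_points = 4L), "too small")

  model <- segnet_init(tiny_config(num_points = 64L), seed = 1)
  fw <- segnet_forward(model, matrix(runif(64 * 3), 64, 3), fps_start = 1L,
                       keep_cache = TRUE)
  sizes <- sapply(fw$cache$levels, function(l) nrow(l$coords))
  expect_equal(sizes, c(64L, 32L, 16L))
  expect_equal(dim(fw$logits), c(64L, 2L))
  expect_error(segnet_forward(model, matrix(runif(30), 10, 3)),
               "num_points")
})

test_that("three stacked layers halve 1024 to 512, 256, 128 centers", {
  cfg <- segnet_config(num_points = 1024L, k = 8L,
                       lift_channels = list(c(8L), c(8L), c(8L)),
                       fp_channels = c(8L, 8L, 8L), head_hidden = 8L,
                       dropout = 0)
  model <- segnet_init(cfg, seed = 2)
  set.seed(3)
  fw <- segnet_forward(model, matrix(runif(1024 * 3), 1024, 3),
                       fps_start = 1L, keep_cache = TRUE)
  expect_equal(sapply(fw$cache$levels, function(l) nrow(l$coords)),
               c(1024L, 512L, 256L, 128L))
})

test_that("a zero-initialized head yields uniform logits", {
  model <- segnet_init(tiny_config(num_points = 32L), seed = 4)
  model$params$head$out$layers[[1]]$W[] <- 0
  model$params$head$out$layers[[1]]$b[] <- 0
  fw <- segnet_forward(model, matrix(runif(96), 32, 3), fps_start = 1L)
  expect_equal(fw$logits, matrix(0, 32, 2))
})

test_that("permuting the input permutes the logits identically", {
  model <- segnet_init(tiny_config(num_points = 48L), seed = 5)
  set.seed(6)
  x <- matrix(runif(48 * 3), 48, 3)
  fw <- segnet_forward(model, x, fps_start = 7L)
  perm <- sample.int(48)
  # track the pinned FPS start through the permutation
  fw_p <- segnet_forward(model, x[perm, ], fps_start = which(perm == 7L))
  expect_equal(fw_p$logits, fw$logits[perm, ], tolerance = 1e-10)
})

test_that("analytic gradients match finite differences in every variant", {
  for (variant in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                       c(FALSE, FALSE))) {
    set.seed(5)
    cfg <- segnet_config(num_points = 16L, k = 3L,
                         lift_channels = list(c(4L), c(5L)),
                         fp_channels = c(6L, 5L), head_hidden = 4L,
                         dropout = 0, use_lse = variant[1],
                         use_dap = variant[2])
    model <- segnet_init(cfg, seed = 2)
    coords <- matrix(runif(48), 16, 3)
    labels <- sample(0:1, 16, replace = TRUE)
    cw <- c(1.3, 0.8)
    loss_fn <- function(v) {
      m <- model
      m$params <- phenocloud:::unflatten_params(model$params, v)
      fw <- segnet_forward(m, coords, fps_start = 1L)
      phenocloud:::weighted_cross_entropy(fw$logits, labels, cw)$loss
    }
    v0 <- phenocloud:::flatten_params(model$params)
    fw <- segnet_forward(model, coords, fps_start = 1L, keep_cache = TRUE)
    ce <- phenocloud:::weighted_cross_entropy(fw$logits, labels, cw)
    ga <- phenocloud:::flatten_params(
      phenocloud:::segnet_backward(model, fw$cache, ce$dLogits))
    expect_length(ga, length(v0))
    idx <- sample(length(v0), 50)
    num <- sapply(idx, function(i) {
      e <- rep(0, length(v0)); e[i] <- 1e-6
      (loss_fn(v0 + e) - loss_fn(v0 - e)) / 2e-6
    })
    expect_lt(max(abs(num - ga[idx])), 1e-6)
  }
})

test_that("gradients reach both pooling branches on a tiny cloud", {
  # one SA layer over a handful of points: the scorer (attention branch)
  # and the fusion stage must both receive non-zero gradient
  set.seed(8)
  cfg <- segnet_config(num_points = 8L, k = 3L, lift_channels = list(c(6L)),
                       fp_channels = c(6L), head_hidden = 4L, dropout = 0)
  model <- segnet_init(cfg, seed = 2)
  coords <- matrix(runif(24), 8, 3)
  labels <- rep(0:1, 4)
  fw <- segnet_forward(model, coords, fps_start = 1L, keep_cache = TRUE)
  ce <- phenocloud:::weighted_cross_entropy(fw$logits, labels, c(1, 1))
  g <- phenocloud:::segnet_backward(model, fw$cache, ce$dLogits)
  scorer_norm <- sum(abs(unlist(g$sa[[1]]$scorer)))
  fusion_norm <- sum(abs(unlist(g$sa[[1]]$fusion)))
  expect_gt(scorer_norm, 0)
  expect_gt(fusion_norm, 0)
})

test_that("disabling LSE and DAP reproduces a plain SA layer", {
  # independent reference: naive loops implementing sample -> group ->
  # grouped MLP on [relative coords, features] -> max pool
  set.seed(9)
  N <- 20L
  P <- matrix(runif(3 * N), N, 3)
  Fin <- matrix(runif(2 * N), N, 2)
  cfg <- segnet_config(num_points = N, k = 3L, lift_channels = list(c(6L)),
                       fp_channels = c(4L), use_lse = FALSE, use_dap = FALSE,
                       dropout = 0)
  layer <- list(lift = mlp_network(c(5L, 6L)))
  res <- phenocloud:::sa_forward(layer, cfg, P, Fin, 1L)

  centers <- bf_fps(P, N %/% 2L, 1L)
  ref <- matrix(0, length(centers), 6L)
  for (i in seq_along(centers)) {
    d <- sqrt(colSums((t(P) - P[centers[i], ])^2))
    nbr <- order(d, seq_len(N))[1:3]
    acc <- rep(-Inf, 6)
    for (j in nbr) {
      v <- c(P[centers[i], ] - P[j, ], Fin[j, ])
      h <- pmax(v %*% layer$lift$layers[[1]]$W +
                  layer$lift$layers[[1]]$b, 0)
      acc <- pmax(acc, as.vector(h))
    }
    ref[i, ] <- acc
  }
  expect_equal(res$feats, ref, tolerance = 1e-12, ignore_attr = TRUE)

  # and the ablated model has strictly fewer parameters than the full one
  full <- segnet_init(tiny_config(num_points = 64L), seed = 1)
  base <- segnet_init(tiny_config(num_points = 64L, use_lse = FALSE,
                                  use_dap = FALSE), seed = 1)
  expect_lt(length(phenocloud:::flatten_params(base$params)),
            length(phenocloud:::flatten_params(full$params)))
})
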