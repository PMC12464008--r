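test_that("farthest point sampling matches the greedy definition", {
  # unit square: starting at a corner, the second pick is the diagonal
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(farthest_point_sample(sq, 2, start = 1)[2], 4L)
  expect_equal(farthest_point_sample(sq, 1, start = 3), 3L)
  expect_setequal(farthest_point_sample(sq, 4, start = 2), 1:4)

  set.seed(10)
  for (n in c(17, 96, 256)) {
    x <- matrix(rnorm(3 * n), n, 3)
    st <- sample.int(n, 1)
    m <- sample.int(n, 1)
    expect_identical(farthest_point_sample(x, m, start = st),
                     as.integer(bf_fps(x, m, st)))
  }
  expect_error(farthest_point_sample(sq, 5), "\\[1, N\\]")
  # seeded start is reproducible
  expect_identical(farthest_point_sample(sq, 3, seed = 5),
                   farthest_point_sample(sq, 3, seed = 5))
})

test_that("knn grouping is exact, self-first, tie-broken by index", {
  line <- cbind(c(0, 1, 3), 0, 0)
  nb <- knn_group(line, 1L, k = 2L)
  expect_equal(nb$idx[1, ], c(1L, 2L))
  expect_equal(nb$dist[1, ], c(0, 1))

  set.seed(11)
  x <- matrix(runif(3 * 200), 200, 3)
  nb <- knn_group(x, 1:200, k = 7L)
  expect_equal(unname(nb$idx), unname(bf_knn(x, x, 7L)))

  nb1 <- knn_group(x, c(5L, 9L), k = 1L)
  expect_equal(nb1$idx[, 1], c(5L, 9L))
  expect_error(knn_group(line, 1L, k = 9L), "exceeds")
})

test_that("local spatial encoding builds the 10-wide geometric code", {
  set.seed(12)
  x <- matrix(runif(60), 20, 3)
  feats <- matrix(runif(20), 20, 1)
  nb <- knn_group(x, 1:20, k = 4L)
  # MLP wired to pass through the distance coordinate
  mlp <- mlp_network(c(10L, 1L))
  mlp$layers[[1]]$W[] <- 0
  mlp$layers[[1]]$W[10, 1] <- 1
  mlp$layers[[1]]$b[] <- 0
  enc <- lse_encode(x, feats, nb, mlp)
  expect_equal(ncol(enc$geometry), 10L)
  expect_equal(dim(enc$t), c(20L * 4L, 2L))
  # self-neighbour rows encode zero offset and zero distance
  self_rows <- seq(1, 80, by = 4)
  expect_true(all(enc$geometry[self_rows, 7:10] == 0))
  # r reproduces the brute-force distances
  bf_d <- as.vector(sapply(1:20, function(i)
    sqrt(colSums((t(x[nb$idx[i, ], ]) - x[i, ])^2))))
  expect_equal(as.vector(enc$r), bf_d, tolerance = 1e-12)
  # q carries the neighbour's own feature
  expect_equal(enc$t[, 2], feats[as.vector(t(nb$idx)), 1])
  expect_error(lse_encode(x, cbind(feats, feats), nb, mlp), "width")
})

test_that("neighbourhood density follows the inverse-distance mean", {
  nb2 <- structure(list(centers = 1L, idx = matrix(c(2L, 3L), 1),
                        dist = matrix(c(1, 1), 1), k = 2L),
                   class = "neighborhood")
  expect_equal(neighborhood_density(NULL, nb2), 1.0, tolerance = 1e-6)
  nb3 <- structure(list(centers = 1L, idx = matrix(c(2L, 3L), 1),
                        dist = matrix(c(0.5, 1), 1), k = 2L),
                   class = "neighborhood")
  expect_equal(neighborhood_density(NULL, nb3), 1.5, tolerance = 1e-6)
  # self neighbour at distance zero stays finite via the epsilon guard
  nbs <- structure(list(centers = 1L, idx = matrix(c(1L, 2L), 1),
                        dist = matrix(c(0, 1), 1), k = 2L),
                   class = "neighborhood")
  expect_true(is.finite(neighborhood_density(NULL, nbs, epsilon = 1e-8)))
  expect_error(neighborhood_density(NULL, nbs, epsilon = 0), "epsilon")
})

test_that("density normalization and partition behave at the boundaries", {
  f <- normalize_density(c(2, 4, 6))
  expect_equal(f$normalized, c(0, 0.5, 1))
  expect_equal(normalize_density(c(3, 3, 3))$normalized, c(0, 0, 0))
  set.seed(13)
  r <- runif(50)
  fn <- normalize_density(r)$normalized
  expect_equal(range(fn), c(0, 1))

  x <- matrix(runif(90), 30, 3)
  nb <- knn_group(x, 1:30, k = 5L)
  flat <- normalize_density(rep(1, 30))
  expect_false(any(partition_by_density(flat, nb)))  # strict > fails on ties
  dens <- normalize_density(neighborhood_density(x, nb))
  high <- partition_by_density(dens, nb)
  # complementary and exhaustive by construction
  expect_length(high, 30L)
  expect_true(all(high | !high))
  # definition check against a direct loop
  manual <- sapply(1:30, function(i)
    dens$normalized[i] > mean(dens$normalized[nb$idx[i, ]]))
  expect_equal(high, manual)
})

test_that("attention pooling is a softmax-weighted mean with unit weights", {
  set.seed(14)
  x <- matrix(runif(36), 12, 3)
  nb <- knn_group(x, c(1L, 5L, 9L), k = 4L)
  feats <- matrix(runif(3 * 4 * 2), 12, 2)  # (M*K) x d, center-major rows
  # constant scorer -> plain neighbour mean
  scorer0 <- mlp_network(c(2L, 2L), final_activation = FALSE)
  scorer0$layers[[1]]$W[] <- 0; scorer0$layers[[1]]$b[] <- 0
  pooled <- attention_pool(feats, nb, scorer0)
  manual <- rbind(colMeans(feats[1:4, ]), colMeans(feats[5:8, ]),
                  colMeans(feats[9:12, ]))
  expect_equal(pooled, manual, ignore_attr = TRUE)
  # attention weights form a distribution over K per center and channel
  scorer <- mlp_network(c(2L, 2L), final_activation = FALSE)
  S <- phenocloud:::mlp_forward(scorer, feats)$out
  W <- phenocloud:::group_softmax(S, 3L, 4L)
  sums <- phenocloud:::group_sum(W, 3L, 4L)
  expect_equal(sums, matrix(1, 3, 2), tolerance = 1e-6, ignore_attr = TRUE)
  # K = 1: the single neighbour feature passes through
  nb1 <- knn_group(x, c(2L, 6L), k = 1L)
  f1 <- matrix(runif(4), 2, 2)
  expect_equal(attention_pool(f1, nb1, scorer), f1, tolerance = 1e-12)
})

test_that("max pooling equals the channelwise loop maximum", {
  nb <- structure(list(centers = 1L, idx = matrix(1:2, 1),
                       dist = matrix(c(0, 1), 1), k = 2L),
                  class = "neighborhood")
  expect_equal(max_pool(rbind(c(1, 5), c(3, 2)), nb), rbind(c(3, 5)))
  set.seed(15)
  x <- matrix(runif(300), 100, 3)
  nbr <- knn_group(x, seq(1, 100, by = 4), k = 6L)
  f <- matrix(rnorm(length(nbr$centers) * 6 * 5), length(nbr$centers) * 6, 5)
  got <- max_pool(f, nbr)
  manual <- t(sapply(seq_along(nbr$centers), function(i)
    apply(f[(i - 1) * 6 + 1:6, , drop = FALSE], 2, max)))
  expect_equal(got, manual, ignore_attr = TRUE)
})

test_that("density-aware pooling fuses both branches per the gate", {
  set.seed(16)
  x <- matrix(runif(60), 20, 3)
  nb <- knn_group(x, c(1L, 4L, 8L, 15L), k = 5L)
  t_ik <- abs(matrix(rnorm(20 * 3), 20, 3))  # non-negative: ReLU-transparent
  field <- normalize_density(neighborhood_density(x, knn_group(x, 1:20, 5L)))
  scorer <- mlp_network(c(3L, 3L), final_activation = FALSE)
  # identity fusion: output is [selected, complementary]
  fid <- mlp_network(c(6L, 6L))
  fid$layers[[1]]$W <- diag(6); fid$layers[[1]]$b[] <- 0
  out <- dap_pool(t_ik, field, nb, scorer, fid)
  expect_equal(dim(out), c(4L, 6L))
  f_att <- attention_pool(t_ik, nb, scorer)
  f_max <- max_pool(t_ik, nb)
  high <- partition_by_density(field, nb)
  for (i in 1:4) {
    if (high[i]) {
      expect_equal(out[i, 1:3], f_max[i, ])
      expect_equal(out[i, 4:6], f_att[i, ])
    } else {
      expect_equal(out[i, 1:3], f_att[i, ])
      expect_equal(out[i, 4:6], f_max[i, ])
    }
  }
  fusion <- mlp_network(c(6L, 2L))
  expect_equal(dim(dap_pool(t_ik, field, nb, scorer, fusion)), c(4L, 2L))
  expect_error(dap_pool(t_ik, field, nb, scorer, mlp_network(c(5L, 2L))),
               "twice")
})

test_that("feature interpolation weights sum to one and respect geometry", {
  coarse <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  fc <- rbind(c(1, 10), c(2, 20), c(3, 30))
  # coincident fine point inherits the coarse feature
  ip <- interpolate_features(rbind(c(1, 0, 0)), coarse, fc)
  expect_equal(ip$feats[1, ], c(2, 20), tolerance = 1e-6)
  expect_equal(rowSums(ip$w), 1)
  # equidistant fine point averages two coarse features equally
  ip2 <- interpolate_features(rbind(c(0.5, 0, 0)), coarse[1:2, ],
                              fc[1:2, ])
  expect_equal(ip2$feats[1, ], c(1.5, 15), tolerance = 1e-9)
  set.seed(17)
  ip3 <- interpolate_features(matrix(runif(30), 10, 3),
                              matrix(runif(15), 5, 3),
                              matrix(rnorm(20), 5, 4))
  expect_equal(rowSums(ip3$w), rep(1, 10))
})
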