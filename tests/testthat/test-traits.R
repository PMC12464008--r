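test_that("plant height is the z-range in centimetres", {
  cl <- labeled_cloud(rbind(c(0, 0, 0.10), c(1, 1, 1.80)))
  expect_equal(plant_height(cl), 170)
  expect_equal(plant_height(labeled_cloud(matrix(c(1, 2, 3), 1))), 0)
  shifted <- labeled_cloud(cl$coords + matrix(c(5, -2, 11), 2, 3,
                                              byrow = TRUE))
  expect_equal(plant_height(shifted), 170)  # translation invariant
})

test_that("minimum bounding rectangle recovers rotated rectangles", {
  rect <- rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2))
  a <- 30 * pi / 180
  R2 <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  rot <- rect %*% t(R2)
  mbr <- min_bounding_rectangle(rot)
  expect_equal(mbr$sides, c(4, 2), tolerance = 1e-9)
  # matches the dense angle-grid oracle on random hulls
  set.seed(24)
  for (i in 1:5) {
    xy <- matrix(rnorm(40), 20, 2) %*% matrix(c(2, 0.4, 0, 0.7), 2, 2)
    got <- min_bounding_rectangle(xy)
    ref <- bf_min_rect(xy)
    expect_equal(got$sides, ref, tolerance = 1e-3)
  }
})

test_that("leaf dimensions: rectangle corners, unit square, sampled ellipse", {
  # 4 corners of a 4 x 2 m rectangle arbitrarily rotated in 3D
  rect <- cbind(rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2)), 0)
  a <- 0.53; b <- 0.31
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Rz <- rbind(c(cos(b), -sin(b), 0), c(sin(b), cos(b), 0), c(0, 0, 1))
  rot <- rect %*% Rx %*% Rz
  expect_equal(leaf_dimensions(rot), c(400, 200), tolerance = 1e-9)

  sq <- cbind(as.matrix(expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1))), 0)
  expect_equal(leaf_dimensions(sq), c(100, 100), tolerance = 1e-9)

  # dense ellipse with semi-axes 0.25 / 0.1 m -> 50 x 20 cm within 2%
  set.seed(25)
  th <- runif(4000, 0, 2 * pi); rho <- sqrt(runif(4000))
  ell <- cbind(0.25 * rho * cos(th), 0.10 * rho * sin(th), 0)
  ell <- rbind(ell, c(0.25, 0, 0), c(-0.25, 0, 0), c(0, 0.1, 0), c(0, -0.1, 0))
  dims <- leaf_dimensions(ell)
  expect_equal(dims[1], 50, tolerance = 0.02)
  expect_equal(dims[2], 20, tolerance = 0.02)

  # rotation invariance of the recovered dimensions
  rot2 <- ell %*% Rx %*% Rz
  expect_lt(max(abs(leaf_dimensions(rot2) - dims)), 1e-6)
  expect_error(leaf_dimensions(ell[1:2, ]), "3 points")
  expect_warning(leaf_dimensions(cbind(0:9, 0, 0)), "collinear")
})

test_that("leaf instancing separates, numbers and purifies leaves", {
  spec <- plant_spec(stem_height = 1.2, n_leaves = 5, noise_sigma = 0,
                     seed = 26)
  p <- make_plant(spec)
  inst <- extract_leaf_instances(p$cloud)
  expect_length(inst, 5L)
  # instances are numbered by increasing base height
  bz <- sapply(inst, function(x) x$base_point[3])
  expect_equal(bz, sort(bz))
  # purity against the generator's instance ids
  for (li in inst) {
    ids <- p$cloud$instance[li$point_indices]
    expect_gte(max(table(ids)) / length(ids), 0.95)
  }
  # epsilon below the sampling spacing shatters clusters below the size gate
  tiny <- extract_leaf_instances(p$cloud, cluster_eps = 1e-5)
  expect_length(tiny, 0L)
  # no leaf points -> empty list
  stem_only <- subset_cloud(p$cloud, p$cloud$semantic == 0L)
  expect_length(extract_leaf_instances(stem_only), 0L)
})

test_that("internode length uses the upper and median-rank leaf bases", {
  mk <- function(z) structure(list(base_point = c(0, 0, z)),
                              class = "leaf_instance")
  expect_equal(internode_length(list(mk(0.4), mk(0.8), mk(1.2))), 40)
  expect_equal(internode_length(list(mk(0.5), mk(0.9))), 40)
  expect_error(internode_length(list(mk(1))), "2 leaf")

  spec <- plant_spec(stem_height = 1.5, n_leaves = 7, noise_sigma = 0,
                     seed = 27)
  p <- make_plant(spec)
  inst <- extract_leaf_instances(p$cloud)
  expect_lt(abs(internode_length(inst) - p$traits$internode_length), 1)
})

test_that("extract_traits assembles the five parameters in cm", {
  spec <- plant_spec(stem_height = 1.0, n_leaves = 4, noise_sigma = 0,
                     seed = 28)
  p <- make_plant(spec)
  rec <- extract_traits(p$cloud)
  expect_s3_class(rec, "trait_record")
  expect_equal(rec$leaf_number, 4L)
  expect_equal(rec$plant_height, p$traits$plant_height, tolerance = 1e-6)
  expect_equal(sort(rec$leaf_lengths), sort(p$traits$leaf_lengths),
               tolerance = 0.02)
  expect_lt(abs(rec$internode_length - p$traits$internode_length), 1)
  # a cloud with no leaves yields the degenerate record
  stem_only <- subset_cloud(p$cloud, p$cloud$semantic == 0L)
  empty <- extract_traits(stem_only)
  expect_equal(empty$leaf_number, 0L)
  expect_true(is.na(empty$internode_length))
})

test_that("R-squared and RMSE follow their definitions", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("trait tables and agreement reports line up by plant", {
  field <- make_field(4, list(points_per_organ = c(200, 200)), seed = 29)
  truth <- lapply(field, `[[`, "traits")
  rec <- lapply(field, function(p) extract_traits(p$cloud))
  tab <- trait_table(truth)
  expect_equal(nrow(tab), 4L)
  ev <- evaluate_traits(truth, rec)
  expect_setequal(ev$trait, c("plant_height", "leaf_number",
                              "mean_leaf_length", "mean_leaf_width",
                              "internode_length"))
  expect_true(all(ev$rmse >= 0, na.rm = TRUE))
  expect_gt(ev$r_squared[ev$trait == "plant_height"], 0.99)
})
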