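test_that("plant_spec validation names the offending field", {
  expect_error(plant_spec(stem_height = -1), "stem_height")
  expect_error(plant_spec(n_leaves = 0), "n_leaves")
  expect_error(plant_spec(leaf_lengths = c(0.3, 0.3)), "leaf_lengths")
  expect_error(plant_spec(n_leaves = 2, leaf_base_heights = c(0.8, 0.4)),
               "increasing")
  expect_error(plant_spec(n_leaves = 2, leaf_base_heights = c(0.5, 1.4)),
               "leaf_base_heights")
  expect_error(plant_spec(noise_sigma = -0.1), "noise_sigma")
  expect_error(plant_spec(outlier_fraction = 1), "outlier_fraction")
})

test_that("generated plants have forced counts, exact height and labels", {
  spec <- plant_spec(stem_height = 1.0, n_leaves = 5, noise_sigma = 0,
                     seed = 3)
  p <- make_plant(spec)
  expect_equal(p$traits$leaf_number, 5L)
  z <- p$cloud$coords[, 3]
  expect_equal((max(z) - min(z)) * 100, p$traits$plant_height)
  expect_setequal(unique(p$cloud$semantic), c(0L, 1L))
  expect_equal(sort(unique(p$cloud$instance)), 0:5)
  # every point has exactly one label and instance
  expect_equal(length(p$cloud$semantic), n_points(p$cloud))
  # stem points are instance 0, leaves 1..5
  expect_true(all(p$cloud$instance[p$cloud$semantic == 0L] == 0L))
  expect_true(all(p$cloud$instance[p$cloud$semantic == 1L] >= 1L))
})

test_that("identical spec and seed give bit-identical plants", {
  spec <- plant_spec(seed = 77)
  a <- make_plant(spec)
  b <- make_plant(spec)
  expect_identical(a$cloud$coords, b$cloud$coords)
  expect_identical(a$traits, b$traits)
})

test_that("ground and outlier augmentation keeps exact bookkeeping", {
  spec0 <- plant_spec(ground_extent = 0, outlier_fraction = 0, seed = 5)
  p <- make_plant(spec0)
  expect_identical(add_ground_and_outliers(p$cloud, spec0), p$cloud)

  spec <- plant_spec(ground_extent = 2, outlier_fraction = 0.05,
                     noise_sigma = 0.01, seed = 5)
  pg <- add_ground_and_outliers(make_plant(spec)$cloud, spec)
  ground <- pg$semantic == 2L
  outl <- pg$semantic == 3L
  n_ground <- sum(ground)
  expect_equal(n_ground, spec$points_per_organ * ceiling(2^2))
  expect_true(all(abs(pg$coords[ground, 3]) < 3 * spec$noise_sigma))
  expect_true(all(abs(pg$coords[ground, 1:2]) <= 1))
  # outliers make up the requested fraction of the final cloud
  expect_equal(sum(outl) / n_points(pg), spec$outlier_fraction,
               tolerance = 0.01)
  # total is plant + ground + outliers exactly
  expect_equal(n_points(pg),
               n_points(make_plant(spec)$cloud) + n_ground + sum(outl))
  expect_true(all(pg$semantic %in% 0:3))
})

test_that("make_field draws reproducible plants from ranges", {
  f <- make_field(4, seed = 9)
  expect_length(f, 4)
  g <- make_field(4, seed = 9)
  expect_identical(f[[2]]$cloud$coords, g[[2]]$cloud$coords)
  expect_identical(f[[3]]$traits, g[[3]]$traits)
  expect_error(make_field(0), "n_plants")
  expect_error(make_field(2, list(stem_height = c(2, 1))), "stem_height")

  # degenerate ranges: records agree field-wise up to sampling jitter
  pt <- make_field(3, list(stem_height = c(1.2, 1.2), n_leaves = c(5, 5),
                           leaf_length = c(0.4, 0.4),
                           width_ratio = c(0.5, 0.5),
                           noise_sigma = c(0, 0)), seed = 4)
  hts <- sapply(pt, function(x) x$traits$plant_height)
  expect_equal(max(hts) - min(hts), 0, tolerance = 1e-9)
  expect_true(all(sapply(pt, function(x) x$traits$leaf_number) == 5))
  lens <- sapply(pt, function(x) x$traits$leaf_lengths)
  expect_equal(max(lens) - min(lens), 0, tolerance = 1e-9)
})

test_that("generator traits agree with geometric recomputation (no noise)", {
  spec <- plant_spec(stem_height = 1.4, n_leaves = 6, noise_sigma = 0,
                     points_per_organ = 500, seed = 13)
  p <- make_plant(spec)
  rec <- extract_traits(p$cloud)
  expect_equal(rec$plant_height, p$traits$plant_height, tolerance = 1e-6)
  expect_equal(rec$leaf_number, p$traits$leaf_number)
  expect_equal(sort(rec$leaf_lengths), sort(p$traits$leaf_lengths),
               tolerance = 0.02)
  expect_equal(sort(rec$leaf_widths), sort(p$traits$leaf_widths),
               tolerance = 0.02)
  expect_lt(abs(rec$internode_length - p$traits$internode_length), 1)
})

test_that("plant specs round-trip through JSON", {
  spec <- plant_spec(stem_height = 1.3, n_leaves = 4, seed = 99)
  f <- withr::local_tempfile(fileext = ".json")
  write_plant_spec(spec, f)
  back <- read_plant_spec(f)
  expect_equal(back, spec, tolerance = 1e-12)
  expect_identical(make_plant(back)$cloud$coords,
                   make_plant(spec)$cloud$coords)
})
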