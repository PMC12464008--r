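#' Specification of a synthetic tobacco-like plant
#'
#' Describes one plant as a vertical stem (cylinder) carrying planar
#' elliptical leaves attached at strictly increasing heights. Leaves are
#' planar elliptical discs so that the ground-truth length and width are
#' analytically known: the minimum-area bounding rectangle of an ellipse
#' with semi-axes `L/2` and `W/2` has sides exactly `L` and `W`.
#' Coordinates use z-up with the stem base at the origin; all lengths are
#' in metres.
#'
#' @param stem_height stem height (m).
#' @param stem_radius stem cylinder radius (m).
#' @param n_leaves number of leaves.
#' @param leaf_lengths per-leaf blade lengths (m); default tapers with
#'   height.
#' @param leaf_widths per-leaf blade widths (m); default half the length.
#' @param leaf_base_heights attachment heights (m), strictly increasing in
#'   `(0, stem_height]`; default evenly spaced over the upper stem.
#' @param leaf_azimuths leaf directions (rad); default spiral phyllotaxis
#'   at the golden angle.
#' @param leaf_droop angle below horizontal of the leaf plane (rad).
#' @param points_per_organ surface points sampled per organ.
#' @param noise_sigma isotropic Gaussian coordinate noise scale (m).
#' @param outlier_fraction fraction of the final cloud that is scattered
#'   outlier points, in `[0, 1)` (used by [add_ground_and_outliers()]).
#' @param ground_extent side (m) of the square ground patch at `z = 0`
#'   (used by [add_ground_and_outliers()]; 0 = no ground).
#' @param seed integer seed making the plant reproducible.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(stem_height = 1.2, stem_radius = 0.015, n_leaves = 6L,
                       leaf_lengths = NULL, leaf_widths = NULL,
                       leaf_base_heights = NULL, leaf_azimuths = NULL,
                       leaf_droop = pi / 6, points_per_organ = 400L,
                       noise_sigma = 0.002, outlier_fraction = 0,
                       ground_extent = 0, seed = 1L) {
  n_leaves <- as.integer(n_leaves)
  if (!is.finite(stem_height) || stem_height <= 0)
    stop("invalid plant spec: stem_height must be > 0")
  if (!is.finite(stem_radius) || stem_radius <= 0)
    stop("invalid plant spec: stem_radius must be > 0")
  if (n_leaves < 1L) stop("invalid plant spec: n_leaves must be >= 1")
  if (is.null(leaf_base_heights))
    leaf_base_heights <- seq(0.3 * stem_height, 0.95 * stem_height,
                             length.out = n_leaves)
  if (is.null(leaf_lengths))
    leaf_lengths <- seq(0.4 * stem_height, 0.25 * stem_height,
                        length.out = n_leaves)
  if (is.null(leaf_widths)) leaf_widths <- 0.5 * leaf_lengths
  if (is.null(leaf_azimuths))
    leaf_azimuths <- (seq_len(n_leaves) - 1) * 2.399963229728653  # golden angle
  if (length(leaf_lengths) != n_leaves)
    stop("invalid plant spec: leaf_lengths must have length n_leaves")
  if (length(leaf_widths) != n_leaves)
    stop("invalid plant spec: leaf_widths must have length n_leaves")
  if (length(leaf_base_heights) != n_leaves)
    stop("invalid plant spec: leaf_base_heights must have length n_leaves")
  if (length(leaf_azimuths) != n_leaves)
    stop("invalid plant spec: leaf_azimuths must have length n_leaves")
  if (any(leaf_lengths <= 0)) stop("invalid plant spec: leaf_lengths must be > 0")
  if (any(leaf_widths <= 0)) stop("invalid plant spec: leaf_widths must be > 0")
  if (any(leaf_widths > leaf_lengths))
    stop("invalid plant spec: leaf_widths must not exceed leaf_lengths")
  if (any(leaf_base_heights <= 0) || any(leaf_base_heights > stem_height))
    stop("invalid plant spec: leaf_base_heights must lie in (0, stem_height]")
  if (n_leaves > 1L && any(diff(leaf_base_heights) <= 0))
    stop("invalid plant spec: leaf_base_heights must be strictly increasing")
  if (!is.finite(leaf_droop) || leaf_droop < 0 || leaf_droop >= pi / 2)
    stop("invalid plant spec: leaf_droop must be in [0, pi/2)")
  if (points_per_organ < 4L)
    stop("invalid plant spec: points_per_organ must be >= 4")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("invalid plant spec: noise_sigma must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("invalid plant spec: outlier_fraction must be in [0, 1)")
  if (ground_extent < 0) stop("invalid plant spec: ground_extent must be >= 0")
  structure(list(stem_height = stem_height, stem_radius = stem_radius,
                 n_leaves = n_leaves, leaf_lengths = leaf_lengths,
                 leaf_widths = leaf_widths,
                 leaf_base_heights = leaf_base_heights,
                 leaf_azimuths = leaf_azimuths, leaf_droop = leaf_droop,
                 points_per_organ = as.integer(points_per_organ),
                 noise_sigma = noise_sigma,
                 outlier_fraction = outlier_fraction,
                 ground_extent = ground_extent, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Write or read a plant specification as JSON
#'
#' Round-trippable key-value serialization of a [plant_spec()], so plant
#' configurations can be stored alongside generated clouds.
#'
#' @param spec a [plant_spec()].
#' @param path file to write to / read from.
#' @return `write_plant_spec()` returns `path` invisibly;
#'   `read_plant_spec()` returns the validated [plant_spec()].
#' @export
write_plant_spec <- function(spec, path) {
  stopifnot(inherits(spec, "plant_spec"))
  # 17 significant digits: doubles survive the decimal round-trip exactly
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_plant_spec
#' @export
read_plant_spec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(plant_spec, vals)
}

#' Ground-truth phenotypic record for one plant
#'
#' The five phenotypic parameters, all lengths in centimetres: plant height
#' (ground to highest point), per-leaf lengths and widths, leaf number, and
#' internode length (vertical distance between the bases of the upper and
#' middle leaves, the middle leaf being the median rank by base height).
#'
#' @param plant_height cm.
#' @param leaf_lengths cm, one per leaf.
#' @param leaf_widths cm, one per leaf.
#' @param internode_length cm, `NA` when fewer than two leaves were found.
#' @return object of class `trait_record`; `leaf_number` is the number of
#'   leaves.
#' @export
trait_record <- function(plant_height, leaf_lengths, leaf_widths,
                         internode_length = NA_real_) {
  if (!is.finite(plant_height) || plant_height < 0)
    stop("plant_height must be a non-negative length")
  if (length(leaf_lengths) != length(leaf_widths))
    stop("leaf_lengths and leaf_widths must have the same length")
  if (any(leaf_lengths <= 0) || any(leaf_widths <= 0))
    stop("leaf dimensions must be > 0")
  structure(list(plant_height = plant_height,
                 leaf_lengths = as.numeric(leaf_lengths),
                 leaf_widths = as.numeric(leaf_widths),
                 leaf_number = length(leaf_lengths),
                 internode_length = internode_length),
            class = "trait_record")
}

#' @export
print.trait_record <- function(x, ...) {
  cat(sprintf(paste0("<trait_record> height %.1f cm | %d leaves | ",
                     "mean length %.1f cm | mean width %.1f cm | ",
                     "internode %s cm\n"),
              x$plant_height, x$leaf_number, mean(x$leaf_lengths),
              mean(x$leaf_widths),
              if (is.na(x$internode_length)) "NA"
              else sprintf("%.1f", x$internode_length)))
  invisible(x)
}

# Internode length from base heights: upper = highest leaf, middle = leaf of
# median rank (ceiling(n/2) in ascending base-height order).
internode_from_base_heights <- function(base_z) {
  n <- length(base_z)
  if (n < 2L) return(NA_real_)
  s <- sort(base_z)
  abs(s[n] - s[ceiling(n / 2)])
}

#' Generate a labeled synthetic plant point cloud
#'
#' Samples the stem as a cylinder and each leaf as a planar elliptical disc
#' attached at its base height and azimuth, tilted downward by the droop
#' angle. Each organ contributes `points_per_organ` surface points; four
#' anchor points per leaf (the ends of the major and minor axes) and two
#' stem anchors (base and apex) pin the exact extremes. Per-point semantic
#' labels (0 = stem, 1 = leaf) and instance ids (0 = stem, 1..n for leaves)
#' are attached, then isotropic Gaussian noise of scale `noise_sigma` is
#' added to the coordinates. The returned `trait_record` holds the exact
#' generator values, measured on the noiseless surface points.
#'
#' @param spec a [plant_spec()].
#' @return list with elements `cloud` ([labeled_cloud()]) and `traits`
#'   ([trait_record()]); bit-reproducible for a fixed `spec$seed`.
#' @export
make_plant <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(spec$seed)
  npo <- spec$points_per_organ
  r <- spec$stem_radius
  h <- spec$stem_height

  # stem: cylinder surface, with base and apex anchors
  ns <- npo - 2L
  theta <- runif(ns, 0, 2 * pi)
  z <- runif(ns, 0, h)
  stem <- rbind(cbind(r * cos(theta), r * sin(theta), z),
                c(r, 0, 0), c(-r, 0, h))

  leaves <- vector("list", spec$n_leaves)
  for (j in seq_len(spec$n_leaves)) {
    L <- spec$leaf_lengths[j]; W <- spec$leaf_widths[j]
    phi <- spec$leaf_azimuths[j]; d <- spec$leaf_droop
    base <- c(r * cos(phi), r * sin(phi), spec$leaf_base_heights[j])
    u <- c(cos(d) * cos(phi), cos(d) * sin(phi), -sin(d))  # length direction
    v <- c(-sin(phi), cos(phi), 0)                          # width direction
    center <- base + u * (L / 2)
    nl <- npo - 4L
    rho <- sqrt(runif(nl))
    ang <- runif(nl, 0, 2 * pi)
    a <- c(rho * cos(ang), -1, 1, 0, 0) * (L / 2)
    b <- c(rho * sin(ang), 0, 0, -1, 1) * (W / 2)
    leaves[[j]] <- cbind(center[1] + a * u[1] + b * v[1],
                         center[2] + a * u[2] + b * v[2],
                         center[3] + a * u[3] + b * v[3])
  }
  coords <- rbind(stem, do.call(rbind, leaves))
  semantic <- c(rep(0L, nrow(stem)), rep(1L, spec$n_leaves * npo))
  instance <- c(rep(0L, nrow(stem)), rep(seq_len(spec$n_leaves), each = npo))

  traits <- trait_record(
    plant_height = (max(coords[, 3]) - min(coords[, 3])) * 100,
    leaf_lengths = spec$leaf_lengths * 100,
    leaf_widths = spec$leaf_widths * 100,
    internode_length =
      internode_from_base_heights(spec$leaf_base_heights) * 100)

  if (spec$noise_sigma > 0)
    coords <- coords + matrix(rnorm(length(coords), 0, spec$noise_sigma),
                              nrow = nrow(coords))
  list(cloud = labeled_cloud(coords, semantic = semantic, instance = instance),
       traits = traits)
}

#' Add a ground plane and scattered outliers to a plant cloud
#'
#' Appends points on the plane `z = 0` over a square of side
#' `spec$ground_extent` centred at the origin (semantic label 2, instance
#' -1) and uniformly scattered outlier points (label 3, instance -1) so
#' that outliers make up `spec$outlier_fraction` of the final cloud.
#' Ground points receive vertical noise truncated at three noise sigmas.
#' With `ground_extent = 0` and `outlier_fraction = 0` the cloud is
#' returned unchanged.
#'
#' @param cloud a [labeled_cloud()] with semantic labels.
#' @param spec the [plant_spec()] the cloud came from.
#' @return the augmented [labeled_cloud()]; seeded by `spec$seed`.
#' @export
add_ground_and_outliers <- function(cloud, spec) {
  stopifnot(inherits(spec, "plant_spec"))
  if (is.null(cloud$semantic)) stop("cloud must carry semantic labels")
  if (spec$ground_extent == 0 && spec$outlier_fraction == 0) return(cloud)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(spec$seed + 1L)
  out <- cloud
  if (spec$ground_extent > 0) {
    e <- spec$ground_extent
    ng <- spec$points_per_organ * as.integer(ceiling(e^2))
    gz <- if (spec$noise_sigma > 0) {
      # truncated normal: |z| < 3 sigma
      stats::qnorm(stats::runif(ng, stats::pnorm(-3), stats::pnorm(3))) *
        spec$noise_sigma
    } else rep(0, ng)
    g <- cbind(runif(ng, -e / 2, e / 2), runif(ng, -e / 2, e / 2), gz)
    out <- bind_clouds(out, labeled_cloud(
      g, semantic = rep(2L, ng),
      instance = if (!is.null(cloud$instance)) rep(-1L, ng)))
  }
  if (spec$outlier_fraction > 0) {
    f <- spec$outlier_fraction
    n0 <- n_points(out)
    no <- max(1L, round(f / (1 - f) * n0))
    lo <- apply(out$coords, 2, min); hi <- apply(out$coords, 2, max)
    pad <- 0.2 * pmax(hi - lo, 1e-3)
    o <- cbind(runif(no, lo[1] - pad[1], hi[1] + pad[1]),
               runif(no, lo[2] - pad[2], hi[2] + pad[2]),
               runif(no, lo[3] - pad[3], hi[3] + pad[3]))
    out <- bind_clouds(out, labeled_cloud(
      o, semantic = rep(3L, no),
      instance = if (!is.null(out$instance)) rep(-1L, no)))
  }
  out
}

#' Default parameter ranges for a synthetic field
#'
#' Plausible tobacco-scale ranges: stems 0.6-1.8 m, 4-10 leaves, leaf
#' blades 0.2-0.6 m long with width 40-70 percent of length, droop 10-35
#' degrees. The leaf count of short plants is capped so that consecutive
#' leaf bases stay at least ~0.12 m apart, as on a real stalk.
#'
#' @return named list of `c(lo, hi)` ranges.
#' @export
default_spec_ranges <- function() {
  list(stem_height = c(0.6, 1.8),
       n_leaves = c(4, 10),
       leaf_length = c(0.2, 0.6),
       width_ratio = c(0.4, 0.7),
       leaf_droop = c(0.17, 0.61),
       noise_sigma = c(0.002, 0.002),
       points_per_organ = c(400, 400))
}

#' Generate a field of independent synthetic plants
#'
#' Draws `n_plants` plant specifications uniformly from `spec_ranges` and
#' generates each plant with [make_plant()]. Deterministic under `seed`.
#'
#' @param n_plants number of plants (>= 1).
#' @param spec_ranges named list of `c(lo, hi)` ranges; see
#'   [default_spec_ranges()] for the recognised names and defaults.
#' @param seed integer seed.
#' @return list of length `n_plants`; each element has `cloud`, `traits`
#'   and the `spec` used.
#' @export
make_field <- function(n_plants, spec_ranges = default_spec_ranges(),
                       seed = 1L) {
  if (n_plants < 1L) stop("n_plants must be >= 1")
  ranges <- utils::modifyList(default_spec_ranges(), spec_ranges)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[2] < rg[1])
      stop("invalid range for '", nm, "': need finite c(lo, hi), lo <= hi")
  }
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  plant_seeds <- sample.int(2^30, n_plants)
  draws <- lapply(seq_len(n_plants), function(i) {
    u <- function(nm) runif(1, ranges[[nm]][1], ranges[[nm]][2])
    h <- u("stem_height")
    n_max <- max(2L, as.integer(floor(0.7 * h / 0.12)) + 1L)
    n <- min(as.integer(round(u("n_leaves"))), n_max)
    # evenly spaced bases over the upper stem with bounded jitter, so that
    # leaves never crowd closer than ~60% of the nominal gap
    bh <- seq(0.25 * h, 0.95 * h, length.out = n)
    if (n > 1L) {
      gap <- diff(bh)[1]
      bh <- bh + runif(n, -0.2 * gap, 0.2 * gap)
      bh <- pmin(sort(bh), h)
    }
    ll <- runif(n, ranges$leaf_length[1], ranges$leaf_length[2])
    ww <- ll * runif(n, ranges$width_ratio[1], ranges$width_ratio[2])
    list(h = h, n = n, bh = bh, ll = ll, ww = ww,
         droop = u("leaf_droop"), noise = u("noise_sigma"),
         npo = as.integer(round(u("points_per_organ"))),
         az0 = runif(1, 0, 2 * pi))
  })
  lapply(seq_len(n_plants), function(i) {
    d <- draws[[i]]
    spec <- plant_spec(
      stem_height = d$h, n_leaves = d$n, leaf_lengths = d$ll,
      leaf_widths = d$ww, leaf_base_heights = d$bh,
      leaf_azimuths = d$az0 + (seq_len(d$n) - 1) * 2.399963229728653,
      leaf_droop = d$droop, points_per_organ = d$npo,
      noise_sigma = d$noise, seed = plant_seeds[i])
    c(make_plant(spec), list(spec = spec))
  })
}
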