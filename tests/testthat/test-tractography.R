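test_that("tracking parameter validation", {
  expect_error(tracking_params(step_length_mm = 0), class = "tc_config_error")
  expect_error(tracking_params(samples_per_seed_voxel = 0), class = "tc_config_error")
  expect_error(tracking_params(curvature_threshold = 1.5), class = "tc_config_error")
})

test_that("dispersion-free direction sampling returns the axis, antipodally aligned", {
  tb <- straight_tube()
  pos <- c(20, 8, 8)
  r1 <- sample_direction(tb$field, pos, c(1, 0, 0), n = 5, rng_seed = 1)
  expect_equal(r1$dirs, matrix(rep(c(1, 0, 0), each = 5), 5, 3))
  r2 <- sample_direction(tb$field, pos, c(-1, 0, 0), n = 5, rng_seed = 1)
  expect_equal(r2$dirs, matrix(rep(c(-1, 0, 0), each = 5), 5, 3))
  expect_error(sample_direction(tb$field, c(-1, 8, 8), c(1, 0, 0)),
               class = "tc_out_of_bounds")
  expect_error(sample_direction(tb$field, c(20, 0.5, 0.5), c(1, 0, 0)),
               class = "tc_no_population")
})

test_that("population selection frequencies match volume fractions (3 SE at 2e4)", {
  f <- empty_field(c(1, 1, 1), 1)
  f$kappa <- 50
  f$orientations[1, 1, 1, 1, ] <- c(0, 0, 1)
  f$orientations[1, 1, 1, 2, ] <- c(1, 0, 0)
  f$fractions[1, 1, 1, 1:2] <- c(0.7, 0.3)
  n <- 2e4
  r <- sample_direction(f, c(0.5, 0.5, 0.5), c(0, 0, 1), n = n, rng_seed = 2)
  p <- mean(r$pop == 1)
  expect_lt(abs(p - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  # fraction floor excludes the minor population entirely
  r2 <- sample_direction(f, c(0.5, 0.5, 0.5), c(0, 0, 1), n = 1000,
                         fraction_floor = 0.4, rng_seed = 2)
  expect_true(all(r2$pop == 1))
})

test_that("straight-tube propagation: accepted, in-tube, evenly stepped", {
  tb <- straight_tube()
  pars <- tracking_params(samples_per_seed_voxel = 1, rng_seed = 5)
  sl <- propagate(c(1.2, 8.1, 7.9), tb$field, tb$seed, tb$target, tb$excl, pars)
  expect_identical(sl$status, "accepted")
  pts <- sl$points
  # consecutive points step_length apart
  steps <- sqrt(rowSums(diff(pts)^2))
  expect_lt(max(abs(steps - pars$step_length_mm)), 1e-6)
  # all points within tube_radius + step of the centerline
  d <- sqrt((pts[, 2] - tb$center_yz[1])^2 + (pts[, 3] - tb$center_yz[2])^2)
  expect_lt(max(d), tb$radius + pars$step_length_mm)
  # a reached target is the last point
  v <- floor(pts[nrow(pts), ] / tb$vs) + 1
  expect_true(tb$target[v[1], v[2], v[3]])
  expect_error(propagate(c(20, 8, 8), tb$field, tb$seed, tb$target, tb$excl, pars),
               class = "tc_config_error")  # not in the seed mask
})

test_that("an 80-degree turn is blocked at curvature threshold 0.2, a 60-degree turn is not", {
  pars <- tracking_params(samples_per_seed_voxel = 200, rng_seed = 8)
  b80 <- bend_field(80)
  m80 <- suppressWarnings(
    connectivity_from_masks(b80$field, b80$seed, b80$target, b80$excl, pars))
  expect_identical(m80$n_accepted, 0)
  expect_gt(m80$n_terminated_curvature, 0.9 * m80$n_attempted)
  b60 <- bend_field(60)
  m60 <- suppressWarnings(
    connectivity_from_masks(b60$field, b60$seed, b60$target, b60$excl, pars))
  expect_gt(m60$n_accepted, 0.9 * m60$n_attempted)
})

test_that("a full-section exclusion slab rejects every streamline", {
  tb <- straight_tube()
  excl <- tb$excl
  excl[20, , ] <- TRUE                       # whole cross-section, no bypass
  pars <- tracking_params(samples_per_seed_voxel = 100, rng_seed = 4)
  m <- suppressWarnings(
    connectivity_from_masks(tb$field, tb$seed, tb$target, excl, pars))
  expect_identical(m$n_accepted, 0)
  expect_gt(m$n_rejected_exclusion, 0.95 * m$n_attempted)
  expect_true(all(m$counts == 0L))
  expect_error(normalized_map(m), class = "tc_no_streamlines")
})

test_that("tracking is deterministic for a fixed seed", {
  tb <- straight_tube()
  pars <- tracking_params(samples_per_seed_voxel = 20, rng_seed = 13)
  m1 <- connectivity_from_masks(tb$field, tb$seed, tb$target, tb$excl, pars)
  m2 <- connectivity_from_masks(tb$field, tb$seed, tb$target, tb$excl, pars)
  expect_identical(m1$counts, m2$counts)
  expect_identical(m1$n_accepted, m2$n_accepted)
})

test_that("the curvature gate holds along every emitted streamline", {
  ph <- test_phantom()
  pars <- tracking_params(samples_per_seed_voxel = 5, rng_seed = 17)
  m <- connectivity_from_masks(ph$fiber_field, ph$seed_mask_left,
                               ph$target_mask_right, ph$exclusion_mask,
                               pars, collect = 500L)
  checked <- 0L
  for (sl in m$streamlines) {
    pts <- sl$points
    if (nrow(pts) < 3) next
    d <- diff(pts)
    d <- d / sqrt(rowSums(d^2))
    cosines <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
    expect_gte(min(cosines), 0.2 - 1e-9)
    checked <- checked + 1L
  }
  expect_gt(checked, 100L)
})

test_that("threshold semantics: counts cutoffs, support at zero, empty beyond max", {
  set.seed(6)
  counts <- array(0L, c(6, 6, 6))
  counts[2:5, 2:5, 2:5] <- as.integer(sample(0:40, 64, replace = TRUE))
  m <- manual_map(counts, n_accepted = 4000)
  # t = 0.001 with 4000 accepted -> include counts >= 4
  expect_identical(as.vector(threshold_map(m, 0.001)), as.vector(counts >= 4))
  expect_identical(sum(threshold_map(m, 0)), sum(counts > 0))
  expect_identical(sum(threshold_map(m, max(counts) / 4000 + 1e-9)), 0L)
  # monotone containment
  t1 <- threshold_map(m, 0.0005); t2 <- threshold_map(m, 0.002)
  expect_true(all(t1[t2]))
  expect_lte(sum(t2), sum(t1))
})

test_that("the full tracking protocol parameter set runs on the default phantom", {
  # full 2000 samples/voxel, 0.5 mm steps, curvature 0.2; the single heaviest
  # test in the suite (a few minutes of compiled propagation)
  ph <- test_phantom()
  pars <- tracking_params(samples_per_seed_voxel = 2000, rng_seed = 19)
  m <- run_tractography(ph, pars, "left")
  expect_gt(m$n_accepted, 0)
  expect_identical(m$n_attempted, sum(ph$seed_mask_left) * 2000)
  expect_lte(max(normalized_map(m)), 1)
})
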