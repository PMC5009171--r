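test_that("landmark affine: identity, exact recovery, noise bound, degeneracy", {
  src <- cbind(c(1, 4, 2, 7, 5, 3), c(2, 1, 6, 3, 5, 8))
  # identity
  aff <- fit_affine_landmarks(src, src)
  expect_equal(aff$A, diag(2), tolerance = 1e-12)
  expect_equal(aff$t, c(0, 0), tolerance = 1e-12)
  expect_equal(aff$rms, 0, tolerance = 1e-12)
  # rotation by 30 degrees plus translation (5, -2): exact recovery
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  dst <- src %*% t(R) + rep(c(5, -2), each = 6)
  aff <- fit_affine_landmarks(src, dst)
  expect_lt(max(abs(aff$A - R)), 1e-9)
  expect_lt(max(abs(aff$t - c(5, -2))), 1e-9)
  expect_lt(aff$rms, 1e-9)
  # isotropic noise sigma = 0.5 on an identity map: translation < 3 sigma / sqrt(6)
  set.seed(31)
  sigma <- 0.5
  aff <- fit_affine_landmarks(src, src + matrix(stats::rnorm(12, 0, sigma), 6, 2))
  expect_lt(sqrt(sum(aff$t^2)), 3 * sigma / sqrt(6))
  # degenerate configurations
  expect_error(fit_affine_landmarks(src[1:2, ], src[1:2, ]), class = "tc_degenerate")
  col <- cbind(1:5, 2 * (1:5))
  expect_error(fit_affine_landmarks(col, col), class = "tc_degenerate")
})

test_that("affine inversion round-trips points", {
  aff <- fit_affine_landmarks(cbind(c(0, 3, 1, 5), c(0, 1, 4, 3)),
                              cbind(c(2, 6, 1, 9), c(1, 3, 7, 6)))
  p <- cbind(stats::runif(10, 0, 5), stats::runif(10, 0, 5))
  expect_equal(affine_apply(affine_invert(aff), affine_apply(aff, p)), p,
               tolerance = 1e-10)
})

test_that("initial reconstruction round-trips an undeformed stack", {
  ph <- test_phantom()
  st <- simulate_sectioning(ph$intensity_volume, 0.5, 1)
  init <- initial_reconstruct(st)
  expect_equal(init$slices, st$block_faces, tolerance = 1e-12)
  e <- reconstruction_error(init)
  expect_equal(e$landmark_mean_mm, 0, tolerance = 1e-9)
  expect_equal(max(e$intensity_rms), 0, tolerance = 1e-9)
  expect_equal(e$curvature_ratio, 1, tolerance = 1e-9)
})

test_that("affine-only deformations are recovered almost exactly; nonlinear ones are not", {
  ph <- test_phantom()
  st <- simulate_sectioning(ph$intensity_volume, 0.5, 2)
  # slightly smoothed slices keep the double-resampling residual dominated by
  # the transform rather than the tube edge's curvature at the pixel scale
  st$slices <- lapply(st$slices, tractconcord:::gauss_smooth2d, sigma = 1)
  st$block_faces <- st$slices
  sp <- st$in_plane_spacing_mm
  nx <- nrow(st$slices[[1]]); ny <- ncol(st$slices[[1]])
  gx <- matrix((seq_len(nx) - 0.5) * sp, nx, ny)
  gy <- matrix((seq_len(ny) - 0.5) * sp, nx, ny, byrow = TRUE)
  th <- 3 * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) * 1.02
  tv <- c(0.8, -0.5)
  aff_stack <- st
  for (k in seq_along(st$slices)) {
    px <- A[1, 1] * gx + A[1, 2] * gy + tv[1]
    py <- A[2, 1] * gx + A[2, 2] * gy + tv[2]
    aff_stack$slices[[k]] <- matrix(
      tractconcord:::cpp_bilinear2(st$block_faces[[k]], as.numeric(px),
                                   as.numeric(py), sp, 0), nx, ny)
    lm <- st$landmarks[[k]]
    dst <- cbind(lm$x_dst, lm$y_dst)
    src <- t(solve(A, t(dst) - tv))
    aff_stack$landmarks[[k]] <- data.frame(x_src = src[, 1], y_src = src[, 2],
                                           x_dst = dst[, 1], y_dst = dst[, 2])
  }
  init <- initial_reconstruct(aff_stack)
  m <- 5L
  ii <- (m + 1):(nx - m); jj <- (m + 1):(ny - m)
  rms_aff <- vapply(seq_along(init$slices), function(k) {
    B <- st$block_faces[[k]][ii, jj]
    sqrt(mean((init$slices[[k]][ii, jj] - B)^2)) / (max(B) - min(B))
  }, numeric(1))
  expect_lt(max(rms_aff), 0.02)
  # genuinely nonlinear warps leave a strictly larger residual
  nl <- deform_stack(st, amplitude_mm = 2, smoothness_mm = 5, seed = 3)
  init_nl <- initial_reconstruct(nl)
  rms_nl <- vapply(seq_along(init_nl$slices), function(k) {
    B <- st$block_faces[[k]][ii, jj]
    sqrt(mean((init_nl$slices[[k]][ii, jj] - B)^2)) / (max(B) - min(B))
  }, numeric(1))
  expect_gt(mean(rms_nl), mean(rms_aff))
})

test_that("an aligned stack is a fixed point of the refinement", {
  ph <- test_phantom()
  st <- simulate_sectioning(ph$intensity_volume, 0.01, 20)
  rec <- refine_nonlinear(initial_reconstruct(st), ph$intensity_volume,
                          recon_config(n_iterations = 1))
  sp <- st$in_plane_spacing_mm
  mag <- mean(vapply(rec$fields, function(f) mean(sqrt(f$dx^2 + f$dy^2)), numeric(1)))
  expect_lt(mag, 0.1 * sp)
})

test_that("nonlinear refinement improves on affine-only and respects regularity", {
  b <- test_recon_bundle()
  pre <- stack_landmark_error(b$std)
  expect_gt(pre, 0.5)  # the regime genuinely deforms the stack
  # refinement recovers most of the deformation
  expect_lt(b$err_refined$landmark_mean_mm, 0.25 * pre)
  # paired comparison: nonlinear <= affine-only
  expect_lte(b$err_refined$landmark_mean_mm, b$err_affine$landmark_mean_mm)
  # sub-pixel residual
  expect_lt(b$err_refined$landmark_mean_mm, b$std$in_plane_spacing_mm)
  # cost is non-increasing overall and the run did not abort
  tr <- b$rec$cost_trace
  expect_lt(tr[length(tr)], tr[1])
  # emitted fields keep a positive Jacobian on >= 99% of pixels
  sp <- b$std$in_plane_spacing_mm
  frac_pos <- vapply(b$rec$fields, function(f) {
    dxx <- tractconcord:::diff_central(f$dx, 1) / sp + 1
    dxy <- tractconcord:::diff_central(f$dx, 2) / sp
    dyx <- tractconcord:::diff_central(f$dy, 1) / sp
    dyy <- tractconcord:::diff_central(f$dy, 2) / sp + 1
    mean(dxx * dyy - dxy * dyx > 0)
  }, numeric(1))
  expect_gte(min(frac_pos), 0.99)
})

test_that("reference anchoring preserves curvature; neighbor-only alignment straightens", {
  vol <- banana_volume()
  st <- deform_stack(simulate_sectioning(vol, 1, 1), 0, 5, 1)
  init <- initial_reconstruct(st)
  anchored <- refine_nonlinear(init, vol,
                               recon_config(weight_reference = 0.5,
                                            weight_neighbors = c(0.25, 0.25)))
  free <- refine_nonlinear(init, vol,
                           recon_config(weight_reference = 0,
                                        weight_neighbors = c(0.5, 0.5)))
  r_anchored <- reconstruction_error(anchored)$curvature_ratio
  r_free <- reconstruction_error(free)$curvature_ratio
  expect_gte(r_anchored, 0.9)
  expect_lte(r_anchored, 1.1)
  expect_lt(r_free, 0.9)
})

test_that("missing landmarks abort the initial reconstruction", {
  ph <- test_phantom()
  st <- simulate_sectioning(ph$intensity_volume, 0.5, 4)
  st$landmarks[[2]] <- st$landmarks[[2]][1:2, ]
  expect_error(initial_reconstruct(st), class = "tc_degenerate")
})
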