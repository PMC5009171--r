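# 3D reconstruction of deformed serial sections.
#
# Stage 1: per-slice landmark-based 6-DOF affine to the block-face frame,
# then stacking (the initial reconstruction). Stage 2: iterative multivariate
# nonlinear refinement -- for each slice a demons-style displacement update is
# computed from a weighted sum-of-squared-difference cost over the two
# neighbouring slices (current estimates, Gauss-Seidel order) and the
# corresponding reference-volume slice, smoothed, and composed onto the
# running field. The reference term anchors the stack to true 3D geometry and
# prevents the straightening of curved structures that pure inter-slice
# alignment produces (the "banana problem").

#' Reconstruction configuration
#'
#' @param n_iterations maximum refinement iterations (default 20, after which
#'   consecutive iterations are visually indistinguishable on the intended
#'   deformation regime).
#' @param weight_reference cost weight of the reference-volume slice.
#' @param weight_neighbors length-2 weights of the (previous, next) slices.
#' @param smoothing_sigma_mm Gaussian regularization of each update field.
#' @param convergence_tol stop when the mean update magnitude (mm) falls
#'   below this.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 20L, weight_reference = 0.5,
                         weight_neighbors = c(0.25, 0.25),
                         smoothing_sigma_mm = 2, convergence_tol = 0.01) {
  if (n_iterations < 1) tc_stop("tc_config_error", "n_iterations must be >= 1")
  w <- c(weight_reference, weight_neighbors)
  if (any(w < 0) || sum(w) <= 0)
    tc_stop("tc_config_error", "cost weights must be >= 0 and sum to > 0")
  cfg <- list(n_iterations = as.integer(n_iterations),
              weight_reference = weight_reference,
              weight_neighbors = weight_neighbors,
              smoothing_sigma_mm = smoothing_sigma_mm,
              convergence_tol = convergence_tol)
  class(cfg) <- "recon_config"
  cfg
}

#' Least-squares 6-DOF affine from landmark pairs
#'
#' @param src_points,dst_points m x 2 matrices (mm), m >= 3, non-collinear.
#' @return an `affine2d` object: `A` (2 x 2), `t` (length 2), `rms` residual.
#' @export
fit_affine_landmarks <- function(src_points, dst_points) {
  src_points <- as.matrix(src_points); dst_points <- as.matrix(dst_points)
  m <- nrow(src_points)
  if (m < 3L || nrow(dst_points) != m)
    tc_stop("tc_degenerate", "at least 3 matched landmark pairs are required")
  ctr <- sweep(src_points, 2, colMeans(src_points))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-8 * max(sv[1], .Machine$double.eps))
    tc_stop("tc_degenerate", "landmarks are collinear; affine is not identifiable")
  X <- cbind(src_points, 1)
  beta <- solve(crossprod(X), crossprod(X, dst_points))
  A <- t(beta[1:2, ])
  tvec <- as.numeric(beta[3, ])
  res <- dst_points - (src_points %*% t(A) + rep(tvec, each = m))
  out <- list(A = A, t = tvec, rms = sqrt(mean(rowSums(res^2))))
  class(out) <- "affine2d"
  out
}

#' Apply a 2D affine to points
#' @param aff an `affine2d`.
#' @param pts m x 2 matrix.
#' @return m x 2 matrix.
#' @export
affine_apply <- function(aff, pts) {
  pts <- rbind(pts)  # tolerate a bare length-2 vector
  pts %*% t(aff$A) + rep(aff$t, each = nrow(pts))
}

#' Invert a 2D affine
#' @param aff an `affine2d`.
#' @return the inverse `affine2d`.
#' @export
affine_invert <- function(aff) {
  Ai <- solve(aff$A)
  out <- list(A = Ai, t = as.numeric(-Ai %*% aff$t), rms = aff$rms)
  class(out) <- "affine2d"
  out
}

slice_grid <- function(nx, ny, sp) {
  list(G1 = matrix(axis_centers(nx, sp), nx, ny),
       G2 = matrix(axis_centers(ny, sp), nx, ny, byrow = TRUE))
}

resample_slice <- function(img, px, py, sp) {
  matrix(cpp_bilinear2(img, as.numeric(px), as.numeric(py), sp, 0),
         nrow(px), ncol(px))
}

#' Initial reconstruction: landmark affine to block faces, then stacking
#'
#' Each deformed slice is resampled through the inverse of its fitted affine
#' into the block-face frame; out-of-view pixels are background (0).
#'
#' @param stack a `slice_stack` whose slices carry >= 3 landmark pairs.
#' @return an object of class `initial_recon`: aligned `slices`, per-slice
#'   `affines` (deformed -> block-face frame), and the input `stack`.
#' @export
initial_reconstruct <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  sp <- stack$in_plane_spacing_mm
  nx <- nrow(stack$slices[[1]]); ny <- ncol(stack$slices[[1]])
  g <- slice_grid(nx, ny, sp)
  affines <- vector("list", length(stack$slices))
  slices <- vector("list", length(stack$slices))
  for (i in seq_along(stack$slices)) {
    lm <- stack$landmarks[[i]]
    if (is.null(lm) || nrow(lm) < 3L)
      tc_stop("tc_degenerate", "slice %d has no usable landmark set; affine missing", i)
    aff <- fit_affine_landmarks(cbind(lm$x_src, lm$y_src), cbind(lm$x_dst, lm$y_dst))
    inv <- affine_invert(aff)
    P <- affine_apply(inv, cbind(as.numeric(g$G1), as.numeric(g$G2)))
    slices[[i]] <- matrix(cpp_bilinear2(stack$slices[[i]], P[, 1], P[, 2], sp, 0), nx, ny)
    affines[[i]] <- aff
  }
  out <- list(slices = slices, affines = affines, stack = stack)
  class(out) <- "initial_recon"
  out
}

#' Slice a reference volume at the stack's plane positions
#'
#' @param reference_volume 3D array (with voxel metadata) in the same world
#'   frame as the stack.
#' @param stack a `slice_stack`.
#' @return list of 2D matrices, one per slice.
#' @export
slice_reference <- function(reference_volume, stack) {
  vs <- voxel_size(reference_volume)
  sp <- stack$in_plane_spacing_mm
  nx <- nrow(stack$slices[[1]]); ny <- ncol(stack$slices[[1]])
  g <- slice_grid(nx, ny, sp)
  lapply(stack$slice_positions_mm, function(z) {
    pts <- cbind(as.numeric(g$G1), as.numeric(g$G2), z)
    matrix(cpp_trilinear(as.numeric(reference_volume), dim(reference_volume), vs,
                         pts, 0), nx, ny)
  })
}

# One demons update of moving M toward fixed F (Thirion normalization; the
# (diff/sp)^2 term keeps units consistent and bounds the step).
demons_update <- function(M, F_, sp) {
  diffi <- F_ - M
  gx <- diff_central(F_, 1) / sp
  gy <- diff_central(F_, 2) / sp
  den <- gx^2 + gy^2 + (diffi / sp)^2
  den[den < 1e-12] <- Inf
  list(dx = diffi * gx / den, dy = diffi * gy / den)
}

#' Iterative multivariate nonlinear refinement
#'
#' @param init an `initial_recon` (or a `slice_stack`, which is affinely
#'   initialized first).
#' @param reference_volume reference 3D volume in the stack's world frame.
#' @param config a [recon_config()].
#' @return an object of class `recon_result`: refined `slices`, total
#'   per-slice displacement `fields` (block-face frame, mm), `affines`,
#'   `cost_trace`, iterations used, and the source stack.
#' @export
refine_nonlinear <- function(init, reference_volume, config = recon_config()) {
  if (inherits(init, "slice_stack")) init <- initial_reconstruct(init)
  stopifnot(inherits(init, "initial_recon"))
  stack <- init$stack
  sp <- stack$in_plane_spacing_mm
  n <- length(init$slices)
  nx <- nrow(init$slices[[1]]); ny <- ncol(init$slices[[1]])
  g <- slice_grid(nx, ny, sp)
  refs <- slice_reference(reference_volume, stack)
  S <- init$slices                      # fixed resampling sources
  M <- S                                # current estimates
  flds <- rep(list(list(dx = matrix(0, nx, ny), dy = matrix(0, nx, ny))), n)
  wr <- config$weight_reference
  wn <- config$weight_neighbors
  sig_px <- config$smoothing_sigma_mm / sp
  cost_trace <- numeric(0)
  n_bad <- 0L
  iter_done <- 0L

  slice_cost <- function(i) {
    w <- c(wr, if (i > 1) wn[1] else 0, if (i < n) wn[2] else 0)
    c0 <- w[1] * mean((M[[i]] - refs[[i]])^2)
    c1 <- if (i > 1) w[2] * mean((M[[i]] - M[[i - 1]])^2) else 0
    c2 <- if (i < n) w[3] * mean((M[[i]] - M[[i + 1]])^2) else 0
    (c0 + c1 + c2) / sum(w)
  }

  for (iter in seq_len(config$n_iterations)) {
    upd_mag <- 0
    for (i in seq_len(n)) {
      w <- c(wr, if (i > 1) wn[1] else 0, if (i < n) wn[2] else 0)
      sw <- sum(w)
      if (sw <= 0) next
      du <- list(dx = matrix(0, nx, ny), dy = matrix(0, nx, ny))
      add <- function(du, u, wk) list(dx = du$dx + wk * u$dx, dy = du$dy + wk * u$dy)
      if (w[1] > 0) du <- add(du, demons_update(M[[i]], refs[[i]], sp), w[1] / sw)
      if (w[2] > 0) du <- add(du, demons_update(M[[i]], M[[i - 1]], sp), w[2] / sw)
      if (w[3] > 0) du <- add(du, demons_update(M[[i]], M[[i + 1]], sp), w[3] / sw)
      du$dx <- gauss_smooth2d(du$dx, sig_px)
      du$dy <- gauss_smooth2d(du$dy, sig_px)
      # compose: d_new(x) = du(x) + d_old(x + du(x))
      px <- g$G1 + du$dx; py <- g$G2 + du$dy
      dxo <- resample_slice(flds[[i]]$dx, px, py, sp)
      dyo <- resample_slice(flds[[i]]$dy, px, py, sp)
      flds[[i]] <- list(dx = du$dx + dxo, dy = du$dy + dyo)
      M[[i]] <- resample_slice(S[[i]], g$G1 + flds[[i]]$dx, g$G2 + flds[[i]]$dy, sp)
      upd_mag <- upd_mag + mean(sqrt(du$dx^2 + du$dy^2))
    }
    iter_done <- iter
    cost <- mean(vapply(seq_len(n), slice_cost, numeric(1)))
    # divergence = meaningfully above the best cost seen (tolerates the small
    # jitter of the demons equilibrium between reference and neighbor terms)
    if (length(cost_trace) && cost > 1.01 * min(cost_trace)) n_bad <- n_bad + 1L
    else n_bad <- 0L
    cost_trace <- c(cost_trace, cost)
    if (n_bad >= 3L)
      tc_stop("tc_divergence",
              "refinement diverged: cost increased over 3 consecutive iterations (trace tail: %s)",
              paste(signif(utils::tail(cost_trace, 4), 4), collapse = ", "))
    if (upd_mag / n < config$convergence_tol) break
  }
  out <- list(slices = M, fields = flds, affines = init$affines,
              cost_trace = cost_trace, n_iterations = iter_done,
              stack = stack, config = config)
  class(out) <- "recon_result"
  out
}

# Estimated block-face-frame -> deformed-slice map for slice i:
# G(x) = F^{-1}(x + d(x)); with `fields = NULL` the affine-only map.
recon_map_points <- function(affines, fields, i, pts, sp) {
  q <- pts
  if (!is.null(fields)) q <- q + eval_field(fields[[i]], q, sp)
  affine_apply(affine_invert(affines[[i]]), q)
}

# Mean perpendicular deviation of the 3D curve of per-slice bright-structure
# centroids (x, y, slice position) from its total-least-squares line; the
# curvature statistic used for the banana-problem check (0 for a straight
# stack, positive for a curved one).
centerline_deviation <- function(slices, sp, threshold = NULL,
                                 slice_positions = seq_along(slices)) {
  if (is.null(threshold)) {
    v <- unlist(slices, use.names = FALSE)
    threshold <- 0.5 * (stats::quantile(v, 0.02) + stats::quantile(v, 0.998))
  }
  cent <- t(vapply(slices, function(sl) {
    w <- pmax(sl - threshold, 0)
    if (sum(w) == 0) return(c(NA_real_, NA_real_))
    nx <- nrow(sl); ny <- ncol(sl)
    c(sum(matrix(axis_centers(nx, sp), nx, ny) * w),
      sum(matrix(axis_centers(ny, sp), nx, ny, byrow = TRUE) * w)) / sum(w)
  }, numeric(2)))
  cent <- cbind(cent, slice_positions)
  ok <- stats::complete.cases(cent)
  cent <- cent[ok, , drop = FALSE]
  if (nrow(cent) < 3) return(NA_real_)
  rel <- sweep(cent, 2, colMeans(cent))
  sv <- svd(rel)
  proj <- outer(rel %*% sv$v[, 1], sv$v[, 1])[, 1, ]
  mean(sqrt(rowSums((rel - proj)^2)))
}

#' Reconstruction error metrics against ground truth
#'
#' @param recon an `initial_recon` or `recon_result`.
#' @param truth_slices the undeformed ground-truth slices (defaults to the
#'   stack's block faces).
#' @return list with `landmark_mean_mm`, `landmark_p95_mm`, per-slice
#'   `intensity_rms` (normalized), and `curvature_ratio` (reconstructed vs
#'   truth centerline deviation).
#' @export
reconstruction_error <- function(recon, truth_slices = NULL) {
  stack <- recon$stack
  sp <- stack$in_plane_spacing_mm
  if (is.null(truth_slices)) truth_slices <- stack$block_faces
  fields <- if (inherits(recon, "recon_result")) recon$fields else NULL
  errs <- unlist(lapply(seq_along(stack$slices), function(i) {
    lm <- stack$landmarks[[i]]
    est <- recon_map_points(recon$affines, fields, i, cbind(lm$x_dst, lm$y_dst), sp)
    vnorm(est - cbind(lm$x_src, lm$y_src))
  }))
  rms <- vapply(seq_along(recon$slices), function(i) {
    B <- truth_slices[[i]]
    rng <- max(B) - min(B)
    if (rng == 0) return(0)
    sqrt(mean((recon$slices[[i]] - B)^2)) / rng
  }, numeric(1))
  list(landmark_mean_mm = mean(errs),
       landmark_p95_mm = as.numeric(stats::quantile(errs, 0.95)),
       intensity_rms = rms,
       curvature_ratio = centerline_deviation(recon$slices, sp,
                             slice_positions = stack$slice_positions_mm) /
                         centerline_deviation(truth_slices, sp,
                             slice_positions = stack$slice_positions_mm))
}
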