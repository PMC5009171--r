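# Simulated serial sectioning and per-slice deformation.
#
# A slice stack holds ordered 2D sections cut perpendicular to the third
# axis, matched undeformed block-face images, >= 6 landmark pairs per slice
# (deformed-slice coords <-> block-face coords, mm) and -- for synthetic
# stacks -- the exact applied per-slice warp. The stored displacement d is
# defined on the pixel grid and extended off-grid bilinearly; the deformed
# slice is D(x) = B(x + d(x)) with B the block face.

#' Simulate serial sectioning of a volume
#'
#' Sections of `section_thickness_mm` are cut perpendicular to the sectioning
#' axis and every `retention_interval`-th is kept, giving an inter-plane
#' spacing of thickness x interval (10 um sections with every 20th retained
#' give 200 um). Block faces are copies of the undeformed slices, true warp
#' fields start as identity, and landmarks are placed at Harris-corner points
#' of each block face.
#'
#' @param volume 3D array with `voxel_size_mm` metadata.
#' @param section_thickness_mm cutting thickness in mm.
#' @param retention_interval keep every k-th section (k >= 1).
#' @param axis sectioning axis (1-3); the stack's slices are perpendicular to it.
#' @param n_landmarks landmarks to place per slice (>= 6).
#' @return an object of class `slice_stack`.
#' @export
simulate_sectioning <- function(volume, section_thickness_mm, retention_interval,
                                axis = 3L, n_landmarks = 8L) {
  vs <- voxel_size(volume)
  if (retention_interval < 1L) tc_stop("tc_config_error", "retention_interval must be >= 1")
  if (n_landmarks < 6L) tc_stop("tc_config_error", "at least 6 landmarks per slice are required")
  if (axis != 3L) volume <- as_volume(aperm(volume, order(replace(1:3, c(axis, 3L), c(3L, axis)))), vs)
  dims <- dim(volume)
  spacing <- section_thickness_mm * retention_interval
  extent_z <- dims[3] * vs
  if (spacing > extent_z)
    tc_stop("tc_bad_geometry", "slice spacing %.3g mm exceeds volume extent %.3g mm", spacing, extent_z)
  n_slices <- floor(extent_z / spacing)
  zpos <- (seq_len(n_slices) - 0.5) * spacing

  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    g <- zpos[k] / vs - 0.5            # fractional plane index (0-based)
    i0 <- floor(g)
    f <- g - i0
    i0 <- min(max(i0, 0), dims[3] - 1L)
    i1 <- min(i0 + 1L, dims[3] - 1L)
    sl <- (1 - f) * volume[, , i0 + 1L] + f * volume[, , i1 + 1L]
    slices[[k]] <- matrix(sl, dims[1], dims[2])
  }
  landmarks <- lapply(slices, function(sl) {
    pts <- harris_landmarks(sl, vs, n = n_landmarks)
    data.frame(x_src = pts[, 1], y_src = pts[, 2], x_dst = pts[, 1], y_dst = pts[, 2])
  })
  stack <- list(slices = slices, block_faces = slices, landmarks = landmarks,
                in_plane_spacing_mm = vs, slice_spacing_mm = spacing,
                section_thickness_mm = section_thickness_mm,
                retention_interval = as.integer(retention_interval),
                slice_positions_mm = zpos,
                true_fields = rep(list(NULL), n_slices))
  class(stack) <- "slice_stack"
  stack
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("slice_stack: %d slices of %d x %d px @ %.3g mm, spacing %.3g mm\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$in_plane_spacing_mm, x$slice_spacing_mm))
  invisible(x)
}

#' Harris-type corner landmarks
#'
#' Returns the `n` strongest Harris corner responses of an image with a
#' minimum mutual distance enforced (greedy suppression). If fewer than 6
#' survive, deterministic interior grid points are appended so every slice
#' always carries at least 6 landmarks.
#'
#' @param img 2D matrix.
#' @param sp pixel spacing in mm.
#' @param n number of landmarks sought.
#' @param min_dist_mm minimum mutual distance (default 4 pixels).
#' @return m x 2 matrix of (x, y) positions in mm.
#' @export
harris_landmarks <- function(img, sp, n = 8L, min_dist_mm = 4 * sp) {
  nx <- nrow(img); ny <- ncol(img)
  gx <- (rbind(img[-1, ], img[nx, ]) - rbind(img[1, ], img[-nx, ])) / 2
  gy <- (cbind(img[, -1], img[, ny]) - cbind(img[, 1], img[, -ny])) / 2
  Ixx <- gauss_smooth2d(gx * gx, 1.5)
  Iyy <- gauss_smooth2d(gy * gy, 1.5)
  Ixy <- gauss_smooth2d(gx * gy, 1.5)
  R <- (Ixx * Iyy - Ixy^2) - 0.06 * (Ixx + Iyy)^2
  b <- 3L                              # exclude the border
  R[c(seq_len(b), nx - seq_len(b) + 1L), ] <- -Inf
  R[, c(seq_len(b), ny - seq_len(b) + 1L)] <- -Inf
  ord <- order(R, decreasing = TRUE)
  chosen <- matrix(numeric(0), 0, 2)
  for (lin in ord[seq_len(min(length(ord), 4000L))]) {
    if (nrow(chosen) >= n) break
    i <- (lin - 1L) %% nx + 1L
    j <- (lin - 1L) %/% nx + 1L
    p <- c((i - 0.5) * sp, (j - 0.5) * sp)
    if (nrow(chosen) == 0 || min(vnorm(sweep(chosen, 2, p))) >= min_dist_mm)
      chosen <- rbind(chosen, p)
  }
  if (nrow(chosen) < 6L) {             # deterministic fallback grid
    gxs <- (c(0.25, 0.5, 0.75)) * nx * sp
    gys <- (c(0.25, 0.5, 0.75)) * ny * sp
    for (p in asplit(as.matrix(expand.grid(gxs, gys)), 1)) {
      if (nrow(chosen) >= 6L) break
      p <- as.numeric(p)
      if (nrow(chosen) == 0 || min(vnorm(sweep(chosen, 2, p))) >= min_dist_mm / 2)
        chosen <- rbind(chosen, p)
    }
  }
  unname(chosen)
}

# Evaluate a stored displacement field (list(dx, dy), pixel grid) at mm points.
eval_field <- function(field, pts, sp) {
  cbind(cpp_bilinear2(field$dx, pts[, 1], pts[, 2], sp, 0),
        cpp_bilinear2(field$dy, pts[, 1], pts[, 2], sp, 0))
}

# phi(x) = x + d(x)
warp_points <- function(field, pts, sp) pts + eval_field(field, pts, sp)

# Solve phi(src) = dst by fixed-point iteration (d is a contraction for the
# regularized fields used here).
invert_field_points <- function(field, dst, sp, tol = 1e-10, max_iter = 300L) {
  x <- dst
  for (it in seq_len(max_iter)) {
    r <- warp_points(field, x, sp) - dst
    if (max(abs(r)) < tol) break
    x <- x - r
  }
  x
}

# Minimum discrete Jacobian determinant of phi(x) = x + d(x) on the grid.
min_jacobian <- function(field, sp) {
  dxx <- diff_central(field$dx, 1) / sp + 1
  dxy <- diff_central(field$dx, 2) / sp
  dyx <- diff_central(field$dy, 1) / sp
  dyy <- diff_central(field$dy, 2) / sp + 1
  min(dxx * dyy - dxy * dyx)
}

diff_central <- function(m, axis) {
  n <- dim(m)[axis]
  if (axis == 1)
    (rbind(m[-1, , drop = FALSE], m[n, ]) - rbind(m[1, ], m[-n, , drop = FALSE])) / 2
  else
    (cbind(m[, -1, drop = FALSE], m[, n]) - cbind(m[, 1], m[, -n, drop = FALSE])) / 2
}

#' Apply smooth random deformations to a slice stack
#'
#' Each slice is independently warped by a band-limited random displacement
#' field (Gaussian-smoothed white noise with characteristic length
#' `smoothness_mm`, scaled to a maximum displacement of about `amplitude_mm`)
#' composed with a small random affine whose magnitude also scales with the
#' amplitude. Fields are rejection-sampled until the discrete Jacobian
#' determinant exceeds 0.1 everywhere, so the stored ground-truth warps stay
#' invertible. Landmarks are moved consistently with the warp (src on the
#' deformed slice, dst on the block face, dst = warp(src) by construction).
#'
#' @param stack a [simulate_sectioning()] result.
#' @param amplitude_mm approximate maximum displacement (0 returns the stack
#'   unchanged, with explicit zero fields).
#' @param smoothness_mm characteristic length of the random field.
#' @param seed integer seed; per-slice substreams are derived from it.
#' @param max_tries rejection-sampling attempts per slice before erroring.
#' @return the deformed `slice_stack` with `true_fields` filled in.
#' @export
deform_stack <- function(stack, amplitude_mm = 2, smoothness_mm = 5, seed = 1L,
                         max_tries = 25L) {
  stopifnot(inherits(stack, "slice_stack"))
  if (amplitude_mm < 0) tc_stop("tc_config_error", "amplitude_mm must be >= 0")
  sp <- stack$in_plane_spacing_mm
  nx <- nrow(stack$slices[[1]]); ny <- ncol(stack$slices[[1]])
  if (amplitude_mm == 0) {
    stack$true_fields <- rep(list(list(dx = matrix(0, nx, ny), dy = matrix(0, nx, ny))),
                             length(stack$slices))
    return(stack)
  }
  gx <- axis_centers(nx, sp); gy <- axis_centers(ny, sp)
  G1 <- matrix(gx, nx, ny); G2 <- matrix(gy, nx, ny, byrow = TRUE)
  cx <- nx * sp / 2; cy <- ny * sp / 2
  sig_px <- smoothness_mm / sp

  for (k in seq_along(stack$slices)) {
    B <- stack$block_faces[[k]]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      set.seed(derive_seed(seed, sprintf("warp_%d_%d", k, try)))
      ang <- stats::rnorm(1, 0, 0.5 * pi / 180 * amplitude_mm)
      sc <- exp(stats::rnorm(2, 0, 0.005 * amplitude_mm))
      sh <- stats::rnorm(1, 0, 0.005 * amplitude_mm)
      tr <- stats::rnorm(2, 0, 0.15 * amplitude_mm)
      A <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2) %*%
           matrix(c(sc[1], 0, sh, sc[2]), 2)
      ux <- gauss_smooth2d(matrix(stats::rnorm(nx * ny), nx, ny), sig_px)
      uy <- gauss_smooth2d(matrix(stats::rnorm(nx * ny), nx, ny), sig_px)
      mmax <- max(sqrt(ux^2 + uy^2))
      if (mmax > 0) { ux <- ux / mmax * amplitude_mm; uy <- uy / mmax * amplitude_mm }
      # phi(x) = C + A (x - C) + t + u(x); stored as displacement phi(x) - x
      dx <- (A[1, 1] * (G1 - cx) + A[1, 2] * (G2 - cy)) + cx + tr[1] + ux - G1
      dy <- (A[2, 1] * (G1 - cx) + A[2, 2] * (G2 - cy)) + cy + tr[2] + uy - G2
      field <- list(dx = dx, dy = dy)
      if (min_jacobian(field, sp) > 0.1) { ok <- TRUE; break }
    }
    if (!ok) tc_stop("tc_fold", "slice %d: could not draw a fold-free warp (amplitude too large)", k)
    phx <- G1 + field$dx; phy <- G2 + field$dy
    D <- matrix(cpp_bilinear2(B, as.numeric(phx), as.numeric(phy), sp, 0), nx, ny)
    lm <- stack$landmarks[[k]]
    dst <- cbind(lm$x_dst, lm$y_dst)
    src <- invert_field_points(field, dst, sp)
    stack$landmarks[[k]] <- data.frame(x_src = src[, 1], y_src = src[, 2],
                                       x_dst = dst[, 1], y_dst = dst[, 2])
    stack$slices[[k]] <- D
    stack$true_fields[[k]] <- field
  }
  stack
}

#' Restack slices into a volume
#'
#' With retention interval 1, no deformation and section thickness equal to
#' the voxel size this reproduces the sectioned volume exactly.
#'
#' @param stack a `slice_stack`.
#' @param slices optionally override the stack's slices (e.g. aligned ones).
#' @return 3D array; isotropic stacks carry `voxel_size_mm` metadata.
#' @export
restack <- function(stack, slices = stack$slices) {
  nx <- nrow(slices[[1]]); ny <- ncol(slices[[1]])
  vol <- array(unlist(slices, use.names = FALSE), dim = c(nx, ny, length(slices)))
  if (isTRUE(all.equal(stack$in_plane_spacing_mm, stack$slice_spacing_mm)))
    vol <- as_volume(vol, stack$in_plane_spacing_mm)
  else {
    attr(vol, "in_plane_spacing_mm") <- stack$in_plane_spacing_mm
    attr(vol, "slice_spacing_mm") <- stack$slice_spacing_mm
  }
  vol
}

#' Undo the stored ground-truth warps
#'
#' Numerically inverts each slice's true field and resamples the deformed
#' slice through the inverse, recovering the block face up to interpolation.
#'
#' @param stack a deformed `slice_stack` with `true_fields` set.
#' @return list of recovered 2D slices.
#' @export
undeform_stack <- function(stack) {
  sp <- stack$in_plane_spacing_mm
  nx <- nrow(stack$slices[[1]]); ny <- ncol(stack$slices[[1]])
  G <- cbind(as.numeric(matrix(axis_centers(nx, sp), nx, ny)),
             as.numeric(matrix(axis_centers(ny, sp), nx, ny, byrow = TRUE)))
  lapply(seq_along(stack$slices), function(k) {
    f <- stack$true_fields[[k]]
    if (is.null(f)) return(stack$slices[[k]])
    inv <- invert_field_points(f, G, sp, tol = 1e-8)
    matrix(cpp_bilinear2(stack$slices[[k]], inv[, 1], inv[, 2], sp, NaN), nx, ny)
  })
}
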