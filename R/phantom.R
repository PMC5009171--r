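# Synthetic phantom: a curved, decussating tubular tract between a
# dentate-like seed blob and the contralateral thalamus-like target blob,
# with a crossing-fiber midline zone, per-voxel fiber populations, ROI labels
# (dentate / peduncle / decussation) and a textured intensity volume standing
# in for the structural / block-face contrast.

ROI_CODES <- c(dentate_left = 1L, peduncle_left = 2L, decussation = 3L,
               peduncle_right = 4L, dentate_right = 5L)

#' Phantom configuration
#'
#' @param grid_shape integer vector of 3 voxel counts (all >= 16).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param tube_radius_mm tract tube radius (>= 1 voxel).
#' @param arc_params optional list with elements `left` and `right`, each a
#'   5 x 3 matrix of control points in relative grid coordinates (0..1); the
#'   default is a mirror-symmetric pair of S-curves that cross the midline
#'   once at mid-height.
#' @param crossing_zone_extent_mm full width of the midline crossing zone.
#' @param dispersion_kappa Watson concentration of fiber orientations about
#'   the local centerline tangent (> 0; > 1e5 is treated as dispersion-free).
#' @param rng_seed master seed; all phantom randomness (texture bumps) flows
#'   from it through named substreams.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L), voxel_size_mm = 0.5,
                           tube_radius_mm = 1.5, arc_params = NULL,
                           crossing_zone_extent_mm = 3, dispersion_kappa = 60,
                           rng_seed = 42L) {
  cfg <- list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
              tube_radius_mm = tube_radius_mm, arc_params = arc_params,
              crossing_zone_extent_mm = crossing_zone_extent_mm,
              dispersion_kappa = dispersion_kappa, rng_seed = as.integer(rng_seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 16L))
    tc_stop("tc_config_error", "grid_shape must have 3 entries, all >= 16 (grid too small for two non-degenerate arcs)")
  if (cfg$voxel_size_mm <= 0)
    tc_stop("tc_config_error", "voxel_size_mm must be positive")
  if (cfg$tube_radius_mm < cfg$voxel_size_mm)
    tc_stop("tc_config_error", "tube_radius_mm must be at least one voxel")
  if (cfg$dispersion_kappa <= 0)
    tc_stop("tc_config_error", "dispersion_kappa must be > 0")
  if (!is.null(cfg$arc_params)) {
    for (side in c("left", "right")) {
      m <- cfg$arc_params[[side]]
      if (is.null(m) || !is.matrix(m) || nrow(m) != 5L || ncol(m) != 3L)
        tc_stop("tc_config_error", "arc_params$%s must be a 5 x 3 matrix", side)
    }
  }
  invisible(cfg)
}

default_arcs <- function() {
  # the x-excursion at mid-height is steep enough that the left and right
  # tangents at the decussation cross at close to 90 degrees: a streamline
  # cannot hop onto the twin bundle without a turn sharper than the 0.2
  # curvature gate (~78 degrees), so the decussation is traversed, not a trap
  # the right arc is the left one rotated 180 degrees about the vertical
  # central axis (x and y both mirrored): at the crossing the twin tangent is
  # (-tx, -ty, tz), so hopping bundles needs a turn of ~88 degrees -- blocked
  # by the curvature gate
  left <- cbind(x = c(0.26, 0.30, 0.50, 0.70, 0.74),
                y = c(0.50, 0.42, 0.50, 0.58, 0.50),
                z = c(0.10, 0.30, 0.50, 0.70, 0.90))
  right <- left
  right[, 1] <- 1 - left[, 1]
  right[, 2] <- 1 - left[, 2]
  list(left = left, right = right)
}

# Natural cubic splines through the 5 control points; dense sampling with
# analytic tangents and normalized arc length.
centerline <- function(ctrl_rel, extent_mm, n_dense = 601L) {
  tt <- seq(0, 1, length.out = nrow(ctrl_rel))
  fx <- stats::splinefun(tt, ctrl_rel[, 1] * extent_mm[1], method = "natural")
  fy <- stats::splinefun(tt, ctrl_rel[, 2] * extent_mm[2], method = "natural")
  fz <- stats::splinefun(tt, ctrl_rel[, 3] * extent_mm[3], method = "natural")
  ts <- seq(0, 1, length.out = n_dense)
  pts <- cbind(fx(ts), fy(ts), fz(ts))
  tan <- cbind(fx(ts, deriv = 1), fy(ts, deriv = 1), fz(ts, deriv = 1))
  tan <- tan / vnorm(tan)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  s <- s / s[length(s)]
  list(points = pts, tangents = tan, s = s)
}

# Mark all voxels within `radius` of the dense centerline, remembering the
# nearest centerline sample per voxel (for tangents and arc-length labels).
splat_tube <- function(cl, dims, vs, radius) {
  dist2 <- array(Inf, dim = dims)
  nearest <- array(0L, dim = dims)
  rv <- ceiling(radius / vs) + 1L
  for (q in seq_len(nrow(cl$points))) {
    p <- cl$points[q, ]
    c0 <- pmax(1L, floor(p / vs - rv) + 1L)
    c1 <- pmin(dims, ceiling(p / vs + rv))
    if (any(c0 > c1)) next
    ii <- c0[1]:c1[1]; jj <- c0[2]:c1[2]; kk <- c0[3]:c1[3]
    dx2 <- ((ii - 0.5) * vs - p[1])^2
    dy2 <- ((jj - 0.5) * vs - p[2])^2
    dz2 <- ((kk - 0.5) * vs - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    cur <- dist2[ii, jj, kk]
    upd <- d2 < cur
    if (any(upd)) {
      cur[upd] <- d2[upd]
      dist2[ii, jj, kk] <- cur
      nr <- nearest[ii, jj, kk]
      nr[upd] <- q
      nearest[ii, jj, kk] <- nr
    }
  }
  mask <- dist2 <= radius^2
  list(mask = mask, dist = sqrt(dist2), nearest = nearest)
}

#' Build the crossing-fiber phantom
#'
#' Constructs ground-truth left/right tract masks from spline centerlines,
#' seed/target end caps, a midsagittal exclusion slab below the decussation,
#' ROI labels ordered seed -> crossing, the per-voxel fiber field (tangent
#' orientations, two populations in the crossing zone, Watson dispersion
#' concentration) and a textured intensity volume.
#'
#' @param config a [phantom_config()].
#' @return an object of class `phantom`.
#' @export
build_phantom <- function(config) {
  validate_phantom_config(config)
  dims <- config$grid_shape
  vs <- config$voxel_size_mm
  extent <- dims * vs
  mid_x <- extent[1] / 2
  arcs <- if (is.null(config$arc_params)) default_arcs() else config$arc_params

  side_data <- list()
  for (side in c("left", "right")) {
    cl <- centerline(arcs[[side]], extent)
    sp <- splat_tube(cl, dims, vs, config$tube_radius_mm)
    idx <- which(sp$mask)
    nearest <- sp$nearest[idx]
    side_data[[side]] <- list(
      cl = cl, mask = sp$mask, dist = sp$dist, idx = idx,
      s = cl$s[nearest], tangent = cl$tangents[nearest, , drop = FALSE])
  }

  # crossing zone: voxels within half the stated extent of the midsagittal plane
  xs <- axis_centers(dims[1], vs)
  in_zone_x <- abs(xs - mid_x) <= config$crossing_zone_extent_mm / 2
  zone3 <- array(in_zone_x, dim = dims)  # recycles along y, z

  tract_l <- side_data$left$mask
  tract_r <- side_data$right$mask
  union_tract <- tract_l | tract_r
  crossing <- zone3 & union_tract

  # seed / target end caps (subsets of the tract support by construction)
  cap <- function(sd, lo) {
    m <- array(FALSE, dim = dims)
    m[sd$idx[if (lo) sd$s <= 0.06 else sd$s >= 0.94]] <- TRUE
    m
  }
  seed_left <- cap(side_data$left, TRUE)     # left dentate
  seed_right <- cap(side_data$right, TRUE)   # right dentate
  target_right <- cap(side_data$left, FALSE) # right thalamus (end of left tract)
  target_left <- cap(side_data$right, FALSE) # left thalamus (end of right tract)

  # exclusion: one-voxel midsagittal slab strictly below the decussation
  kz <- axis_centers(dims[3], vs)
  if (!any(crossing))
    tc_stop("tc_config_error", "arcs never enter the crossing zone; no decussation")
  z_dec_min <- min(kz[apply(crossing, 3, any)])
  zlim <- z_dec_min - 1.0
  col_x <- which(abs(xs - mid_x) <= vs * 0.6)
  repeat {                                   # never block the tract itself
    excl <- array(FALSE, dim = dims)
    if (zlim > 0) excl[col_x, , kz < zlim] <- TRUE
    if (!any(excl & union_tract)) break
    zlim <- zlim - vs
  }

  # ROI labels: dentate (s < 0.2), peduncle (0.2 <= s < start of decussation),
  # decussation shared between sides where the tubes mingle
  roi <- array(0L, dim = dims)
  for (side in c("left", "right")) {
    sd <- side_data[[side]]
    in_dec <- crossing[sd$idx]
    s_dec_lo <- if (any(in_dec)) min(sd$s[in_dec]) else 0.45
    dent <- sd$idx[sd$s < 0.2]
    ped <- sd$idx[sd$s >= 0.2 & sd$s < s_dec_lo & !in_dec]
    roi[dent] <- ROI_CODES[[paste0("dentate_", side)]]
    roi[ped] <- ROI_CODES[[paste0("peduncle_", side)]]
  }
  roi[crossing] <- ROI_CODES[["decussation"]]

  # fiber field: tangent populations, mirrored second population in the
  # crossing zone, shared Watson concentration
  K <- 3L
  ori <- array(0, dim = c(dims, K, 3L))
  fra <- array(0, dim = c(dims, K))
  nvox <- prod(dims)
  set_pop <- function(idx, p, dirs, f) {
    base <- idx + nvox * (p - 1L)
    fra[base] <<- f
    ori[base] <<- dirs[, 1]
    ori[base + nvox * K] <<- dirs[, 2]
    ori[base + 2L * nvox * K] <<- dirs[, 3]
  }
  both <- tract_l & tract_r
  for (side in c("left", "right")) {
    sd <- side_data[[side]]
    own_only <- !(both[sd$idx])
    in_dec <- crossing[sd$idx]
    # single-tube voxels outside the crossing zone: one population
    i1 <- own_only & !in_dec
    set_pop(sd$idx[i1], 1L, sd$tangent[i1, , drop = FALSE], 0.6)
    # single-tube voxels inside the crossing zone: own tangent + the twin
    # bundle's tangent (x and y negated, matching the rotated geometry)
    i2 <- own_only & in_dec
    if (any(i2)) {
      tg <- sd$tangent[i2, , drop = FALSE]
      mir <- tg; mir[, 1] <- -mir[, 1]; mir[, 2] <- -mir[, 2]
      set_pop(sd$idx[i2], 1L, tg, 0.5)
      set_pop(sd$idx[i2], 2L, mir, 0.35)
    }
  }
  bidx <- which(both)
  if (length(bidx)) {  # voxels shared by the two tubes: both tangents
    tl <- side_data$left; tr <- side_data$right
    ml <- match(bidx, tl$idx); mr <- match(bidx, tr$idx)
    set_pop(bidx, 1L, tl$tangent[ml, , drop = FALSE], 0.45)
    set_pop(bidx, 2L, tr$tangent[mr, , drop = FALSE], 0.45)
  }

  # intensity: dim background, bright tube with a soft one-voxel shoulder,
  # plus smooth random texture bumps (gives landmarks + registration signal)
  dmin <- pmin(side_data$left$dist, side_data$right$dist)
  edge <- pmax(dmin - config$tube_radius_mm, 0)
  inten <- 0.15 + 0.75 * exp(-(edge^2) / (2 * (0.75 * vs)^2))
  inten[!is.finite(inten)] <- 0.15
  set.seed(derive_seed(config$rng_seed, "texture"))
  nb <- 30L
  ctr <- cbind(stats::runif(nb, 0, extent[1]), stats::runif(nb, 0, extent[2]),
               stats::runif(nb, 0, extent[3]))
  amp <- stats::runif(nb, 0.1, 0.3) * sample(c(-1, 1), nb, replace = TRUE)
  sig <- stats::runif(nb, 1.5, 3)
  gx <- axis_centers(dims[1], vs); gy <- axis_centers(dims[2], vs); gz <- axis_centers(dims[3], vs)
  for (b in seq_len(nb)) {
    bump <- outer(outer(exp(-(gx - ctr[b, 1])^2 / (2 * sig[b]^2)),
                        exp(-(gy - ctr[b, 2])^2 / (2 * sig[b]^2)), "*"),
                  exp(-(gz - ctr[b, 3])^2 / (2 * sig[b]^2)), "*")
    inten <- inten + amp[b] * bump
  }
  inten <- pmin(pmax(inten, 0), 1.2)

  ph <- list(
    config = config,
    tract_mask_left = as_volume(tract_l, vs),
    tract_mask_right = as_volume(tract_r, vs),
    roi_labels = as_volume(roi, vs),
    seed_mask_left = as_volume(seed_left, vs),
    seed_mask_right = as_volume(seed_right, vs),
    target_mask_left = as_volume(target_left, vs),
    target_mask_right = as_volume(target_right, vs),
    exclusion_mask = as_volume(excl, vs),
    fiber_field = list(orientations = ori, fractions = fra,
                       kappa = config$dispersion_kappa, voxel_size_mm = vs),
    intensity_volume = as_volume(array(inten, dim = dims), vs),
    geometry = lapply(side_data, function(sd)
      list(idx = sd$idx, s = sd$s, tangent = sd$tangent,
           centerline = sd$cl$points, centerline_tangents = sd$cl$tangents))
  )
  class(ph) <- "phantom"
  ph
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$roi_labels)
  cat(sprintf("phantom: %d x %d x %d voxels @ %.3g mm\n", d[1], d[2], d[3],
              voxel_size(x$roi_labels)))
  cat(sprintf("  tract voxels: left %d, right %d (shared %d)\n",
              sum(x$tract_mask_left), sum(x$tract_mask_right),
              sum(x$tract_mask_left & x$tract_mask_right)))
  cat(sprintf("  seed/target voxels (left tract): %d -> %d; kappa = %g\n",
              sum(x$seed_mask_left), sum(x$target_mask_right),
              x$fiber_field$kappa))
  invisible(x)
}

#' Extract a ROI mask from a phantom
#'
#' @param phantom a [build_phantom()] result.
#' @param roi one of `"dentate"`, `"peduncle"`, `"decussation"`, `"tract"`.
#' @param side `"left"` or `"right"`; ignored for the shared decussation.
#' @return logical volume.
#' @export
roi_mask <- function(phantom, roi = c("dentate", "peduncle", "decussation", "tract"),
                     side = c("left", "right")) {
  roi <- match.arg(roi)
  side <- match.arg(side)
  vs <- voxel_size(phantom$roi_labels)
  m <- switch(roi,
    tract = if (side == "left") phantom$tract_mask_left else phantom$tract_mask_right,
    decussation = phantom$roi_labels == ROI_CODES[["decussation"]],
    phantom$roi_labels == ROI_CODES[[paste0(roi, "_", side)]])
  as_volume(array(m, dim = dim(phantom$roi_labels)), vs)
}
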