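# Shared fixtures, memoised across test files (helpers are loaded once per
# test session). Everything is generated in code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# The default phantom (48^3 @ 0.5 mm, kappa 60), shared by most suites.
test_phantom <- function() fixture("phantom", build_phantom(phantom_config(rng_seed = 7)))

# A moderately sampled connectivity map of the left tract on the default
# phantom (300 attempts per seed voxel; scaled down from the full protocol's
# 2000 to keep the suite within budget -- the full protocol is exercised once
# in the acceptance suite).
test_map_left <- function() fixture("map_left", {
  run_tractography(test_phantom(),
                   tracking_params(samples_per_seed_voxel = 300, rng_seed = 3),
                   side = "left")
})

# Reference segmentation used for evaluation: the left tract, with the whole
# decussation included for both sides.
test_ref_left <- function() fixture("ref_left", {
  ph <- test_phantom()
  dec <- roi_mask(ph, "decussation") & (ph$tract_mask_left | ph$tract_mask_right)
  as_volume(ph$tract_mask_left | dec, voxel_size(ph$tract_mask_left))
})

# The default deformation-regime reconstruction bundle (sectioning at the
# 10 um / every-20th geometry, amplitude 2 mm, smoothness 5 mm).
test_recon_bundle <- function() fixture("recon_bundle", {
  ph <- test_phantom()
  st <- simulate_sectioning(ph$intensity_volume, 0.01, 20)
  std <- deform_stack(st, amplitude_mm = 2, smoothness_mm = 5, seed = 5)
  init <- initial_reconstruct(std)
  rec <- refine_nonlinear(init, ph$intensity_volume, recon_config())
  list(ph = ph, st = st, std = std, init = init, rec = rec,
       err_affine = reconstruction_error(init),
       err_refined = reconstruction_error(rec))
})

# Mean landmark displacement of a deformed stack (the pre-reconstruction
# error the pipeline starts from).
stack_landmark_error <- function(stack) {
  mean(unlist(lapply(stack$landmarks, function(lm)
    sqrt((lm$x_dst - lm$x_src)^2 + (lm$y_dst - lm$y_src)^2))))
}

# ---- simple synthetic fiber fields -----------------------------------------

empty_field <- function(dims, vs, K = 3L) {
  list(orientations = array(0, dim = c(dims, K, 3L)),
       fractions = array(0, dim = c(dims, K)),
       kappa = 1e9, voxel_size_mm = vs)
}

# Straight tube along +x through the volume center.
straight_tube <- function(nx = 40L, ny = 16L, nz = 16L, vs = 1, radius = 2.5,
                          kappa = 1e9) {
  dims <- c(nx, ny, nz)
  f <- empty_field(dims, vs)
  f$kappa <- kappa
  cy <- ny * vs / 2; cz <- nz * vs / 2
  yy <- (seq_len(ny) - 0.5) * vs; zz <- (seq_len(nz) - 0.5) * vs
  tube2d <- outer((yy - cy)^2, (zz - cz)^2, "+") <= radius^2
  tube <- array(rep(tube2d, each = nx), dim = dims)
  idx <- which(tube)
  nv <- prod(dims)
  f$fractions[idx] <- 0.6
  f$orientations[idx] <- 1          # population 1, x component
  seed <- array(FALSE, dims); seed[1:2, , ] <- tube[1:2, , ]
  target <- array(FALSE, dims); target[(nx - 1):nx, , ] <- tube[(nx - 1):nx, , ]
  excl <- array(FALSE, dims)
  list(field = f, tube = tube, seed = seed, target = target, excl = excl,
       center_yz = c(cy, cz), radius = radius, vs = vs, dims = dims)
}

# Whole-volume field pointing +x before x0 and turned by `angle_deg` (in the
# x-y plane) after it; dispersion-free. Target slab only reachable through
# the turn.
bend_field <- function(angle_deg, nx = 60L, ny = 60L, nz = 8L, vs = 1,
                       x0 = 20, x_target = 35) {
  dims <- c(nx, ny, nz)
  f <- empty_field(dims, vs)
  a <- angle_deg * pi / 180
  nv <- prod(dims)
  xs <- (seq_len(nx) - 0.5) * vs
  before <- array(xs < x0, dim = dims)
  idx_b <- which(before); idx_a <- which(!before)
  f$fractions[c(idx_b, idx_a)] <- 0.6
  K <- 3L
  f$orientations[idx_b] <- 1                                  # +x
  f$orientations[idx_a] <- cos(a)
  f$orientations[idx_a + nv * K] <- sin(a)                    # y component
  seed <- array(FALSE, dims); seed[2, 8, 4] <- TRUE
  target <- array(xs >= x_target, dim = dims)
  excl <- array(FALSE, dims)
  list(field = f, seed = seed, target = target, excl = excl, dims = dims)
}

# Curved single-tube volume for the banana-problem demonstration.
banana_volume <- function(nx = 32L, nz = 14L, vs = 1, A = 5, radius = 1.8) {
  vol <- array(0, dim = c(nx, nx, nz))
  gx <- (seq_len(nx) - 0.5) * vs
  for (k in seq_len(nz)) {
    cx <- nx / 2 * vs + A * sin(pi * (k - 0.5) / nz)
    vol[, , k] <- 0.1 + 0.9 * exp(-outer((gx - cx)^2, (gx - nx / 2 * vs)^2, "+") /
                                    (2 * radius^2))
  }
  as_volume(vol, vs)
}

# ---- independent brute-force oracles ---------------------------------------

brute_confusion <- function(pred, ref, roi) {
  tp <- fp <- tn <- fn <- 0L
  d <- dim(pred)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!roi[i, j, k]) next
    p <- pred[i, j, k]; r <- ref[i, j, k]
    if (p && r) tp <- tp + 1L
    else if (p && !r) fp <- fp + 1L
    else if (!p && r) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

brute_dice <- function(pred, ref) {
  inter <- np <- nr <- 0L
  d <- dim(pred)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (pred[i, j, k]) np <- np + 1L
    if (ref[i, j, k]) nr <- nr + 1L
    if (pred[i, j, k] && ref[i, j, k]) inter <- inter + 1L
  }
  if (np + nr == 0L) return(0)
  2 * inter / (np + nr)
}

# Rank statistic: P(value at a reference voxel > value at a non-reference
# voxel), ties counted half; exhaustive pair comparison.
brute_auc <- function(values, ref, roi) {
  v1 <- values[ref & roi]; v0 <- values[!ref & roi]
  if (!length(v1) || !length(v0)) return(NA_real_)
  mean(outer(v1, v0, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Small synthetic connectivity map with known counts.
manual_map <- function(counts, n_accepted, vs = 1) {
  m <- list(counts = as_volume(counts, vs), n_accepted = n_accepted,
            n_attempted = n_accepted, n_rejected_exclusion = 0,
            n_terminated_curvature = 0, n_rejected_no_target = 0,
            normalize_by = "accepted", label = "manual")
  class(m) <- "connectivity_map"
  m
}
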