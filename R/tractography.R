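# Probabilistic streamline tractography through a synthetic fiber field.
#
# Semantics: streamlines are launched bidirectionally from jittered points in
# each seed voxel; at every step a fiber population of the containing voxel
# is sampled proportional to its volume fraction (populations below the
# fraction floor excluded, the deterministic analog of ARD pruning), a
# direction is drawn from the Watson dispersion distribution about its axis
# and sign-aligned with the previous direction; a draw whose cosine with the
# previous direction falls below the curvature threshold terminates that
# branch (it does not reject the streamline); entering the exclusion mask
# rejects the whole streamline; a streamline is accepted iff it reaches the
# target mask, where it terminates. Accepted streamlines increment each
# visited voxel at most once, and maps are normalized by the number of
# streamlines generated between the seed and target mask (i.e. accepted).

#' Tracking parameters
#'
#' Defaults follow the standard probabilistic protocol for this tract: 0.5 mm
#' steps, 2000 streamlines per seed voxel, curvature threshold 0.2 (a maximum
#' turn of about 78 degrees per step) and no anisotropy threshold.
#'
#' @param step_length_mm propagation step in mm.
#' @param samples_per_seed_voxel streamline attempts per seed voxel.
#' @param curvature_threshold minimum cosine between consecutive steps.
#' @param max_steps maximum steps per half-track; default 4 x grid diagonal /
#'   step (resolved against the field at run time when `NULL`).
#' @param fraction_floor minimum volume fraction for a population to be
#'   sampled.
#' @param rng_seed integer seed.
#' @param normalize_by `"accepted"` (default) or `"attempted"`: denominator
#'   of the connectivity-map normalization.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(step_length_mm = 0.5, samples_per_seed_voxel = 2000L,
                            curvature_threshold = 0.2, max_steps = NULL,
                            fraction_floor = 0.05, rng_seed = 1L,
                            normalize_by = c("accepted", "attempted")) {
  if (step_length_mm <= 0) tc_stop("tc_config_error", "step_length_mm must be > 0")
  if (samples_per_seed_voxel < 1) tc_stop("tc_config_error", "samples_per_seed_voxel must be >= 1")
  if (curvature_threshold < -1 || curvature_threshold > 1)
    tc_stop("tc_config_error", "curvature_threshold must lie in [-1, 1]")
  p <- list(step_length_mm = step_length_mm,
            samples_per_seed_voxel = as.integer(samples_per_seed_voxel),
            curvature_threshold = curvature_threshold,
            max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
            fraction_floor = fraction_floor, rng_seed = as.integer(rng_seed),
            normalize_by = match.arg(normalize_by))
  class(p) <- "tracking_params"
  p
}

resolve_max_steps <- function(params, field) {
  if (!is.null(params$max_steps)) return(params$max_steps)
  dims <- dim(field$fractions)[1:3]
  diag_mm <- sqrt(sum((dims * field$voxel_size_mm)^2))
  as.integer(ceiling(4 * diag_mm / params$step_length_mm))
}

field_dims <- function(field) dim(field$fractions)[1:3]

#' Sample a propagation direction from a fiber field
#'
#' Selects one fiber population of the voxel containing `position_mm` with
#' probability proportional to its volume fraction (populations below
#' `fraction_floor` excluded), draws from the Watson dispersion distribution
#' about its mean axis, and sign-flips the draw to have non-negative dot
#' product with `previous_direction`.
#'
#' @param field a phantom's `fiber_field`.
#' @param position_mm length-3 position in mm.
#' @param previous_direction length-3 unit vector.
#' @param n number of draws.
#' @param fraction_floor minimum fraction for a population to be considered.
#' @param rng_seed integer seed.
#' @return list with `dirs` (n x 3 unit vectors) and `pop` (1-based
#'   population index per draw).
#' @export
sample_direction <- function(field, position_mm, previous_direction, n = 1L,
                             fraction_floor = 0.05, rng_seed = 1L) {
  vs <- field$voxel_size_mm
  dims <- field_dims(field)
  v <- floor(position_mm / vs) + 1L
  if (any(v < 1L) || any(v > dims))
    tc_stop("tc_out_of_bounds", "position (%g, %g, %g) mm outside the field extent",
            position_mm[1], position_mm[2], position_mm[3])
  K <- dim(field$fractions)[4]
  axes <- matrix(0, K, 3)
  for (p in seq_len(K)) axes[p, ] <- field$orientations[v[1], v[2], v[3], p, ]
  fr <- field$fractions[v[1], v[2], v[3], ]
  if (all(fr < fraction_floor | fr <= 0))
    tc_stop("tc_no_population", "voxel (%d, %d, %d) has no population above the fraction floor",
            v[1], v[2], v[3])
  res <- cpp_sample_dirs(axes, fr, field$kappa, previous_direction,
                         fraction_floor, as.integer(n), as.double(rng_seed))
  res
}

#' Propagate a single streamline
#'
#' Bidirectional propagation from one seed point; see the module notes above
#' for the acceptance/rejection semantics. Mostly a testing/inspection
#' surface -- [run_tractography()] drives the same compiled core in bulk.
#'
#' @param seed_point_mm length-3 seed position in mm (must lie inside the
#'   seed mask).
#' @param field fiber field.
#' @param seed_mask,target_mask,exclusion_mask logical volumes.
#' @param params [tracking_params()].
#' @return list with `points` (m x 3 matrix, consecutive rows `step_length_mm`
#'   apart, oriented so that a reached target is last) and `status` (one of
#'   `accepted`, `rejected_exclusion`, `rejected_no_target`,
#'   `terminated_curvature_then_rejected`).
#' @export
propagate <- function(seed_point_mm, field, seed_mask, target_mask,
                      exclusion_mask, params = tracking_params()) {
  vs <- field$voxel_size_mm
  dims <- field_dims(field)
  v <- floor(seed_point_mm / vs) + 1L
  if (any(v < 1L) || any(v > dims))
    tc_stop("tc_out_of_bounds", "seed point outside the volume")
  if (!seed_mask[v[1], v[2], v[3]])
    tc_stop("tc_config_error", "seed point is not inside the seed mask")
  res <- cpp_track(field$orientations, field$fractions, field$kappa,
                   params$fraction_floor, c(dims, dim(field$fractions)[4]), vs,
                   as.integer(target_mask), as.integer(exclusion_mask),
                   matrix(integer(0), 0, 3),
                   matrix(seed_point_mm, 1, 3), 0L,
                   params$step_length_mm, params$curvature_threshold,
                   resolve_max_steps(params, field),
                   as.double(params$rng_seed), 1L)
  res$streamlines[[1]]
}

#' Run tractography from every seed voxel
#'
#' Launches `samples_per_seed_voxel` attempts from uniformly jittered points
#' within each seed voxel and accumulates accepted streamlines into a
#' connectivity map (visit set per streamline: each accepted streamline
#' increments a voxel at most once). Deterministic for a fixed seed.
#'
#' @param phantom a [build_phantom()] result.
#' @param params [tracking_params()].
#' @param side which tract to track: seed in the ipsilateral dentate, target
#'   the contralateral thalamus.
#' @return an object of class `connectivity_map`: `counts` (integer volume),
#'   `n_accepted`, `n_attempted`, per-status tallies, and the normalization
#'   mode. `n_accepted == 0` yields a valid map flagged with a warning state.
#' @export
run_tractography <- function(phantom, params = tracking_params(),
                             side = c("left", "right")) {
  side <- match.arg(side)
  field <- phantom$fiber_field
  seed_mask <- if (side == "left") phantom$seed_mask_left else phantom$seed_mask_right
  target_mask <- if (side == "left") phantom$target_mask_right else phantom$target_mask_left
  connectivity_from_masks(field, seed_mask, target_mask, phantom$exclusion_mask,
                          params, label = paste0("drtt_", side))
}

#' Tractography between explicit masks
#'
#' Lower-level entry used by [run_tractography()]; exposed for custom
#' phantoms and tests.
#'
#' @inheritParams run_tractography
#' @param field fiber field.
#' @param seed_mask,target_mask,exclusion_mask logical volumes.
#' @param label map label.
#' @return a `connectivity_map`.
#' @export
connectivity_from_masks <- function(field, seed_mask, target_mask, exclusion_mask,
                                    params = tracking_params(), label = "map",
                                    collect = 0L) {
  dims <- field_dims(field)
  vs <- field$voxel_size_mm
  sv <- which(array(seed_mask, dim = dims), arr.ind = TRUE)
  if (nrow(sv) == 0) tc_stop("tc_config_error", "empty seed mask")
  res <- cpp_track(field$orientations, field$fractions, field$kappa,
                   params$fraction_floor, c(dims, dim(field$fractions)[4]), vs,
                   as.integer(target_mask), as.integer(exclusion_mask),
                   sv, matrix(numeric(0), 0, 3),
                   params$samples_per_seed_voxel,
                   params$step_length_mm, params$curvature_threshold,
                   resolve_max_steps(params, field),
                   as.double(params$rng_seed), as.integer(collect))
  map <- list(counts = as_volume(res$counts, vs),
              n_accepted = res$n_accepted, n_attempted = res$n_attempted,
              n_rejected_exclusion = res$n_rejected_exclusion,
              n_terminated_curvature = res$n_terminated_curvature,
              n_rejected_no_target = res$n_rejected_no_target,
              normalize_by = params$normalize_by, label = label)
  if (collect > 0) map$streamlines <- res$streamlines
  class(map) <- "connectivity_map"
  if (map$n_accepted == 0) {
    map$warning_state <- "no accepted streamlines; normalization undefined"
    warning("connectivity map '", label, "': no accepted streamlines")
  }
  map
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("connectivity_map '%s': %g/%g accepted (excl %g, curv %g, lost %g)\n",
              x$label, x$n_accepted, x$n_attempted, x$n_rejected_exclusion,
              x$n_terminated_curvature, x$n_rejected_no_target))
  invisible(x)
}

norm_denominator <- function(map) {
  d <- if (identical(map$normalize_by, "attempted")) map$n_attempted else map$n_accepted
  if (d <= 0)
    tc_stop("tc_no_streamlines", "normalization undefined: no %s streamlines",
            map$normalize_by)
  d
}

#' Normalized connectivity map
#'
#' Per-voxel visit counts divided by the total number of streamlines
#' generated between the seed and target mask (accepted streamlines by
#' default; switchable to attempts via the tracking parameters).
#'
#' @param map a `connectivity_map`.
#' @return numeric volume of values in `[0, 1]`.
#' @export
normalized_map <- function(map) {
  as_volume(array(map$counts / norm_denominator(map), dim = dim(map$counts)),
            voxel_size(map$counts))
}

#' Threshold a connectivity map
#'
#' A voxel is included iff its normalized value is at least `t`; `t = 0`
#' includes exactly the voxels visited by at least one accepted streamline
#' (the support of the counts).
#'
#' @param map a `connectivity_map`.
#' @param t threshold as a fraction of total streamlines (0.001 = 0.1%).
#' @return logical volume.
#' @export
threshold_map <- function(map, t) {
  if (t < 0) tc_stop("tc_config_error", "threshold must be >= 0")
  if (t == 0) return(as_volume(array(map$counts > 0L, dim = dim(map$counts)),
                               voxel_size(map$counts)))
  nm <- normalized_map(map)
  as_volume(array(nm >= t, dim = dim(nm)), voxel_size(nm))
}
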