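# Orchestration: phantom -> tractography (both sides) -> sectioning ->
# deformation -> reconstruction -> overlap evaluation, with every
# intermediate persisted in a standard format and all randomness fanned out
# from one master seed through named substreams (adding a stage never
# perturbs an earlier one).

#' Full run configuration
#'
#' @param phantom a [phantom_config()].
#' @param tracking a [tracking_params()].
#' @param recon a [recon_config()].
#' @param deformation list with `amplitude_mm` and `smoothness_mm`.
#' @param sectioning list with `section_thickness_mm` and `retention_interval`
#'   (defaults: 10 um sections, every 20th kept -> 200 um spacing).
#' @param evaluation list with `n_thresholds`, `max_threshold`,
#'   `max_margin_mm`.
#' @param master_seed integer; per-stage seeds are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       tracking = tracking_params(),
                       recon = recon_config(),
                       deformation = list(amplitude_mm = 2, smoothness_mm = 5),
                       sectioning = list(section_thickness_mm = 0.01,
                                         retention_interval = 20L),
                       evaluation = list(n_thresholds = 100L,
                                         max_threshold = 0.0035,
                                         max_margin_mm = 3),
                       master_seed = 1L) {
  validate_phantom_config(phantom)
  stopifnot(inherits(tracking, "tracking_params"), inherits(recon, "recon_config"))
  if (deformation$amplitude_mm < 0)
    tc_stop("tc_config_error", "deformation amplitude must be >= 0")
  cfg <- list(phantom = phantom, tracking = tracking, recon = recon,
              deformation = deformation, sectioning = sectioning,
              evaluation = evaluation, master_seed = as.integer(master_seed))
  class(cfg) <- "run_config"
  cfg
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full pipeline
#'
#' Executes every stage in order, persists each intermediate under
#' `output_dir` (NIfTI volumes, CSV landmark tables and reports, JSON
#' summaries, SVG plots where the graphics device allows), and returns a
#' manifest. Two runs with the same configuration produce byte-identical
#' report files.
#'
#' @param config a [run_config()].
#' @param output_dir writable output directory (created if missing).
#' @return an object of class `run_manifest` (also written as
#'   `manifest.json`): config hash, package version, per-stage status and
#'   emitted files.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "run_config"))
  # re-validate sub-configs before any stage runs (fields may have been edited)
  config$tracking <- do.call(tracking_params, unclass(config$tracking))
  config$recon <- do.call(recon_config, unclass(config$recon))
  validate_phantom_config(config$phantom)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, 2) != 0)
    tc_stop("tc_io_error", "output_dir '%s' is not writable", output_dir)
  cfg_plain <- rapply(unclass(config), identity, how = "replace")
  manifest <- list(config_hash = config_hash(cfg_plain),
                   package_version = as.character(utils::packageVersion("tractconcord")),
                   stages = list(), files = character(0))
  persist <- function(stage) {
    manifest$stages[[stage]] <<- "done"
    mpath <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  emit <- function(path) manifest$files <<- c(manifest$files, basename(path))
  fail_stage <- function(stage, e) {
    manifest$stages[[stage]] <<- paste("failed:", conditionMessage(e))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tc_stop("tc_stage_error", "stage '%s' failed: %s", stage, conditionMessage(e))
  }
  run_stage <- function(stage, expr) {
    log_stage(stage, "start")
    r <- tryCatch(expr, error = function(e) fail_stage(stage, e))
    persist(stage)
    r
  }

  ms <- config$master_seed
  ph <- run_stage("phantom", {
    cfg <- config$phantom
    cfg$rng_seed <- derive_seed(ms, "phantom")
    p <- build_phantom(cfg)
    for (nm in c("intensity_volume", "roi_labels", "exclusion_mask")) {
      f <- file.path(output_dir, paste0(nm, ".nii")); write_volume(p[[nm]], f); emit(f)
    }
    for (nm in c("tract_mask_left", "tract_mask_right", "seed_mask_left",
                 "seed_mask_right", "target_mask_left", "target_mask_right")) {
      f <- file.path(output_dir, paste0(nm, ".nii")); write_volume(p[[nm]], f); emit(f)
    }
    p
  })

  maps <- run_stage("tractography", {
    out <- list()
    for (side in c("left", "right")) {
      tp <- config$tracking
      tp$rng_seed <- derive_seed(ms, paste0("tracking_", side))
      m <- run_tractography(ph, tp, side)
      f <- file.path(output_dir, sprintf("connectivity_%s.nii", side))
      write_volume(m$counts, f, "int32"); emit(f)
      out[[side]] <- m
    }
    fj <- file.path(output_dir, "tractography_summary.json")
    jsonlite::write_json(lapply(out, function(m)
      list(n_accepted = m$n_accepted, n_attempted = m$n_attempted)),
      fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(fj)
    out
  })

  stack <- run_stage("sectioning", {
    s <- simulate_sectioning(ph$intensity_volume,
                             config$sectioning$section_thickness_mm,
                             config$sectioning$retention_interval)
    s <- deform_stack(s, config$deformation$amplitude_mm,
                      config$deformation$smoothness_mm,
                      seed = derive_seed(ms, "warps"))
    write_stack(s, file.path(output_dir, "stack"))
    emit(file.path(output_dir, "stack"))
    s
  })

  recon <- run_stage("reconstruction", {
    r <- refine_nonlinear(initial_reconstruct(stack), ph$intensity_volume, config$recon)
    vol <- restack(stack, r$slices)
    f <- file.path(output_dir, "reconstructed.nii")
    if (!is.null(attr(vol, "slice_spacing_mm"))) {
      vol2 <- as_volume(unclass(vol), stack$in_plane_spacing_mm)  # spacing noted in JSON
      write_volume(vol2, f)
    } else write_volume(vol, f)
    emit(f)
    err <- reconstruction_error(r)
    fj <- file.path(output_dir, "reconstruction_error.json")
    jsonlite::write_json(err[c("landmark_mean_mm", "landmark_p95_mm", "curvature_ratio")],
                         fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(fj)
    r
  })

  report <- run_stage("evaluation", {
    ev <- config$evaluation
    thr <- default_thresholds(ev$n_thresholds, ev$max_threshold)
    reps <- list()
    for (side in c("left", "right")) {
      ref <- if (side == "left") ph$tract_mask_left else ph$tract_mask_right
      rois <- list(dentate = bounding_roi(roi_mask(ph, "dentate", side), pad = 4L),
                   peduncle = bounding_roi(roi_mask(ph, "peduncle", side), pad = 4L),
                   decussation = bounding_roi(roi_mask(ph, "decussation"), pad = 4L),
                   tract_box = bounding_roi(ref, pad = 4L))
      # the whole decussation serves as reference for both sides
      ref_eval <- ref | (roi_mask(ph, "decussation") &
                         (ph$tract_mask_left | ph$tract_mask_right))
      reps[[side]] <- evaluate_overlap(maps[[side]],
                                       as_volume(ref_eval, voxel_size(ref)),
                                       rois, thr, ev$max_margin_mm)
    }
    avg <- average_reports(reps)
    fcsv <- file.path(output_dir, "overlap_curves.csv")
    write_report(avg, fcsv); emit(fcsv)
    fj <- file.path(output_dir, "overlap_summary.json")
    jsonlite::write_json(list(summary = avg$summary, dilation = avg$dilation),
                         fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(fj)
    plot_overlap_report(avg, output_dir)
    avg
  })

  manifest$stages[["complete"]] <- "done"
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(manifest = manifest, phantom = ph, maps = maps, stack = stack,
              recon = recon, report = report)
  class(res) <- "run_manifest"
  invisible(res)
}

#' Padded bounding-box analysis ROI
#'
#' The evaluation region used for confusion counts: the bounding box of a
#' structure mask padded by `pad` voxels. Restricting the TN count to a
#' stated region keeps specificity meaningful (it otherwise depends on how
#' many zeros the compared volumes happen to contain).
#'
#' @param mask logical volume with voxel metadata.
#' @param pad padding in voxels on every side.
#' @return logical volume.
#' @export
bounding_roi <- function(mask, pad = 4L) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  out <- array(FALSE, dim = d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  as_volume(out, voxel_size(mask))
}

#' Write a slice stack to a directory
#'
#' Slices and block faces go to one NIfTI volume each (stack order along the
#' third axis; in-plane spacing in the header, slice spacing in
#' `stack_meta.json`), landmarks to `landmarks.csv`
#' (slice_index, x_src, y_src, x_dst, y_dst), true fields (when present) to a
#' 4D NIfTI with the two displacement components along the fourth axis.
#'
#' @param stack a `slice_stack`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- stack$in_plane_spacing_mm
  write_volume(as_volume(restack_plain(stack$slices), sp), file.path(dir, "slices.nii"))
  write_volume(as_volume(restack_plain(stack$block_faces), sp), file.path(dir, "block_faces.nii"))
  lm <- do.call(rbind, lapply(seq_along(stack$landmarks), function(i)
    cbind(slice_index = i, stack$landmarks[[i]])))
  utils::write.csv(lm, file.path(dir, "landmarks.csv"), row.names = FALSE)
  if (!is.null(stack$true_fields[[1]])) {
    n <- length(stack$true_fields)
    nx <- nrow(stack$slices[[1]]); ny <- ncol(stack$slices[[1]])
    f4 <- array(0, dim = c(nx, ny, n, 2))
    for (i in seq_len(n)) {
      f4[, , i, 1] <- stack$true_fields[[i]]$dx
      f4[, , i, 2] <- stack$true_fields[[i]]$dy
    }
    write_volume(as_volume(f4, sp), file.path(dir, "true_fields.nii"))
  }
  meta <- list(in_plane_spacing_mm = sp, slice_spacing_mm = stack$slice_spacing_mm,
               section_thickness_mm = stack$section_thickness_mm,
               retention_interval = stack$retention_interval,
               n_slices = length(stack$slices))
  jsonlite::write_json(meta, file.path(dir, "stack_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

restack_plain <- function(slices)
  array(unlist(slices, use.names = FALSE),
        dim = c(nrow(slices[[1]]), ncol(slices[[1]]), length(slices)))

#' Write 8-bit PNG previews of a slice stack
#'
#' Convenience inspection output (one `slice_###.png` per section, intensity
#' rescaled to the stack's range). The lossless interchange format for stacks
#' remains NIfTI ([write_stack()]); this needs the suggested `png` package.
#'
#' @param stack a `slice_stack`.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_slice_previews <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    tc_stop("tc_io_error", "the 'png' package is required for PNG previews")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(unlist(stack$slices, use.names = FALSE))
  files <- vapply(seq_along(stack$slices), function(k) {
    f <- file.path(dir, sprintf("slice_%03d.png", k))
    img <- (stack$slices[[k]] - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    png::writePNG(t(img), f)   # rows = y, columns = x
    f
  }, character(1))
  invisible(files)
}

#' Read a slice stack written by [write_stack()]
#' @param dir directory containing the stack files.
#' @return a `slice_stack`.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack_meta.json"), simplifyVector = TRUE)
  vols <- read_volume(file.path(dir, "slices.nii"))
  bfs <- read_volume(file.path(dir, "block_faces.nii"))
  n <- dim(vols)[3]
  lm <- utils::read.csv(file.path(dir, "landmarks.csv"))
  ffile <- file.path(dir, "true_fields.nii")
  tf <- rep(list(NULL), n)
  if (file.exists(ffile)) {
    f4 <- read_volume(ffile)
    tf <- lapply(seq_len(n), function(i) list(dx = f4[, , i, 1], dy = f4[, , i, 2]))
  }
  stack <- list(
    slices = lapply(seq_len(n), function(i) vols[, , i]),
    block_faces = lapply(seq_len(n), function(i) bfs[, , i]),
    landmarks = lapply(seq_len(n), function(i) {
      s <- lm[lm$slice_index == i, c("x_src", "y_src", "x_dst", "y_dst")]
      rownames(s) <- NULL
      s
    }),
    in_plane_spacing_mm = meta$in_plane_spacing_mm,
    slice_spacing_mm = meta$slice_spacing_mm,
    section_thickness_mm = meta$section_thickness_mm,
    retention_interval = meta$retention_interval,
    slice_positions_mm = (seq_len(n) - 0.5) * meta$slice_spacing_mm,
    true_fields = tf)
  class(stack) <- "slice_stack"
  stack
}

#' Write / read an overlap report as tidy CSV
#'
#' @param report an `overlap_report`.
#' @param path CSV path for the per-threshold curves.
#' @return the path / the report.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$curves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  curves <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi", "threshold", "TP", "FP", "TN", "FN", "TPR", "FPR", "SI")
  miss <- setdiff(need, names(curves))
  if (length(miss))
    tc_stop("tc_bad_format", "report CSV is missing column(s): %s", paste(miss, collapse = ", "))
  summary <- do.call(rbind, lapply(split(curves, curves$roi), function(cc)
    data.frame(roi = cc$roi[1], auc = roc_auc(cc$FPR, cc$TPR),
               optimal_threshold = optimal_threshold(cc), max_si = max(cc$SI))))
  rownames(summary) <- NULL
  out <- list(curves = curves, summary = summary)
  class(out) <- "overlap_report"
  out
}

#' Read / write configurations as YAML
#' @param config a `run_config`.
#' @param path YAML path.
#' @return the path / the `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), identity, how = "replace"), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_config, y$phantom)
  if (!is.null(y$tracking)) args$tracking <- do.call(tracking_params, y$tracking)
  if (!is.null(y$recon)) args$recon <- do.call(recon_config, y$recon)
  for (nm in c("deformation", "sectioning", "evaluation", "master_seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(run_config, args)
}

#' Plot ROC, SI and dilation curves of a report
#'
#' Writes `roc.svg`, `si_curves.svg` and `fn_dilation.svg` when an SVG device
#' is available (silently skipped otherwise, e.g. on cairo-less builds).
#'
#' @param report an `overlap_report`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
plot_overlap_report <- function(report, dir) {
  if (!capabilities("cairo")) return(invisible(character(0)))
  files <- character(0)
  rois <- unique(report$curves$roi)
  cols <- grDevices::hcl.colors(max(3, length(rois)), "Dark 3")[seq_along(rois)]
  dev <- function(name, expr) {
    f <- file.path(dir, name)
    grDevices::svg(f, width = 5, height = 5)
    on.exit(grDevices::dev.off())
    expr()
    files <<- c(files, f)
  }
  dev("roc.svg", function() {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR", ylab = "TPR",
                   main = "ROC by ROI")
    graphics::abline(0, 1, lty = 3, col = "grey")
    for (q in seq_along(rois)) {
      cc <- report$curves[report$curves$roi == rois[q], ]
      o <- order(cc$FPR)
      graphics::lines(cc$FPR[o], cc$TPR[o], col = cols[q], lwd = 2)
    }
    graphics::legend("bottomright", legend = rois, col = cols, lwd = 2, bty = "n")
  })
  dev("si_curves.svg", function() {
    graphics::plot(NA, xlim = range(report$curves$threshold) * 100,
                   ylim = c(0, 1), xlab = "connectivity threshold (%)",
                   ylab = "Dice SI", main = "SI vs threshold")
    for (q in seq_along(rois)) {
      cc <- report$curves[report$curves$roi == rois[q], ]
      graphics::lines(cc$threshold * 100, cc$SI, col = cols[q], lwd = 2)
    }
    graphics::legend("topright", legend = rois, col = cols, lwd = 2, bty = "n")
  })
  if (!is.null(report$dilation)) dev("fn_dilation.svg", function() {
    graphics::plot(NA, xlim = range(report$dilation$margin_mm), ylim = c(0, 1),
                   xlab = "dilation margin (mm)", ylab = "fraction of reference covered",
                   main = "FN spatial extent")
    for (q in seq_along(rois)) {
      cc <- report$dilation[report$dilation$roi == rois[q], ]
      graphics::lines(cc$margin_mm, cc$coverage, col = cols[q], lwd = 2, type = "b", pch = 16)
    }
    graphics::legend("bottomright", legend = rois, col = cols, lwd = 2, bty = "n")
  })
  invisible(files)
}
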