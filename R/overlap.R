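# Voxel-wise concordance between thresholded tractography and a reference
# segmentation: confusion counts, TPR/FPR (ROC), Dice similarity index,
# threshold sweeps with AUC and optimal-threshold selection, and the
# false-negative dilation profile. Evaluation is restricted to a stated
# analysis ROI by default, because specificity depends directly on how many
# zeros the compared masks contain; a whole-volume mode is available through
# an all-ones ROI.

check_congruent <- function(...) {
  ds <- lapply(list(...), dim)
  if (!all(vapply(ds[-1], identical, logical(1), ds[[1]])))
    tc_stop("tc_shape_mismatch", "masks are not congruent in shape")
}

#' Confusion counts over a region of interest
#'
#' @param pred_mask,ref_mask,roi_mask congruent logical volumes; counts are
#'   computed only over `roi_mask` voxels.
#' @return list with `TP`, `FP`, `TN`, `FN` (their sum is the ROI volume).
#' @export
confusion_counts <- function(pred_mask, ref_mask, roi_mask) {
  check_congruent(pred_mask, ref_mask, roi_mask)
  if (!any(roi_mask)) tc_stop("tc_degenerate", "roi_mask is empty")
  p <- pred_mask[roi_mask]; r <- ref_mask[roi_mask]
  list(TP = sum(p & r), FP = sum(p & !r), TN = sum(!p & !r), FN = sum(!p & r))
}

#' True-positive and false-positive rates
#'
#' TPR = TP / (TP + FN) (sensitivity); FPR = FP / (FP + TN)
#' (1 - specificity). Empty denominators raise an undefined-rate condition
#' rather than propagating NaN.
#'
#' @param counts a [confusion_counts()] result.
#' @return list with `TPR` and `FPR`.
#' @export
tpr_fpr <- function(counts) {
  if (counts$TP + counts$FN <= 0)
    tc_stop("tc_undefined_rate", "TPR undefined: no reference-positive voxels in the ROI")
  if (counts$FP + counts$TN <= 0)
    tc_stop("tc_undefined_rate", "FPR undefined: no reference-negative voxels in the ROI")
  list(TPR = counts$TP / (counts$TP + counts$FN),
       FPR = counts$FP / (counts$FP + counts$TN))
}

#' Dice similarity index
#'
#' SI = 2 |pred & ref| / (|pred| + |ref|), in `[0, 1]`; defined as 0 when both
#' masks are empty (a degenerate output should not score as perfect overlap).
#'
#' @param pred_mask,ref_mask congruent logical volumes.
#' @return the similarity index.
#' @export
dice_si <- function(pred_mask, ref_mask) {
  check_congruent(pred_mask, ref_mask)
  denom <- sum(pred_mask) + sum(ref_mask)
  if (denom == 0) return(0)
  2 * sum(pred_mask & ref_mask) / denom
}

#' Default connectivity-threshold grid
#'
#' 100 evenly spaced values over 0 to 0.35% of total streamlines.
#'
#' @param n number of thresholds.
#' @param max_threshold upper end (fraction; 0.0035 = 0.35%).
#' @return numeric vector of thresholds, ascending.
#' @export
default_thresholds <- function(n = 100L, max_threshold = 0.0035) {
  seq(0, max_threshold, length.out = n)
}

#' ROC and Dice curves over a threshold sweep
#'
#' For each threshold the map is binarized, confusion counts, TPR, FPR and SI
#' computed over the ROI. AUC is the trapezoid over (FPR, TPR) sorted by FPR
#' with (0,0) and (1,1) anchors (with one threshold per distinct map value
#' this equals the rank statistic with ties counted half). The optimal
#' threshold is the smallest one attaining the maximal SI (the larger, more
#' sensitive mask is preferred at equal SI).
#'
#' @param map a `connectivity_map` with accepted streamlines.
#' @param ref_mask reference segmentation (logical volume).
#' @param roi_mask analysis ROI (logical volume).
#' @param thresholds ascending threshold grid (fractions).
#' @param roi_name label used in the output rows.
#' @return an object of class `overlap_report`: `curves` (one row per
#'   threshold: roi, threshold, TP, FP, TN, FN, TPR, FPR, SI) and `summary`
#'   (roi, auc, optimal_threshold, max_si).
#' @export
roc_and_si_curves <- function(map, ref_mask, roi_mask, thresholds = default_thresholds(),
                              roi_name = "roi") {
  if (is.unsorted(thresholds)) tc_stop("tc_config_error", "thresholds must be ascending")
  check_congruent(map$counts, ref_mask, roi_mask)
  norm_denominator(map)  # errors when normalization is undefined
  rows <- lapply(thresholds, function(t) {
    pred <- threshold_map(map, t)
    cc <- confusion_counts(pred, ref_mask, roi_mask)
    rates <- tpr_fpr(cc)
    si <- dice_si(pred & roi_mask, ref_mask & roi_mask)
    data.frame(roi = roi_name, threshold = t, TP = cc$TP, FP = cc$FP,
               TN = cc$TN, FN = cc$FN, TPR = rates$TPR, FPR = rates$FPR, SI = si)
  })
  curves <- do.call(rbind, rows)
  report <- list(curves = curves,
                 summary = data.frame(roi = roi_name,
                                      auc = roc_auc(curves$FPR, curves$TPR),
                                      optimal_threshold = optimal_threshold(curves),
                                      max_si = max(curves$SI)))
  class(report) <- "overlap_report"
  report
}

roc_auc <- function(fpr, tpr) {
  pts <- unique(rbind(c(0, 0), cbind(fpr, tpr), c(1, 1)))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) + utils::tail(pts[, 2], -1)) / 2)
}

optimal_threshold <- function(curves) {
  mx <- max(curves$SI)
  min(curves$threshold[curves$SI >= mx - 1e-12])
}

#' Evaluate a map against a reference over several ROIs
#'
#' Convenience wrapper running [roc_and_si_curves()] and
#' [fn_dilation_profile()] (at each ROI's optimal threshold) per ROI.
#'
#' @inheritParams roc_and_si_curves
#' @param rois named list of logical ROI volumes.
#' @param max_margin_mm largest dilation margin for the FN profile.
#' @return an `overlap_report` with row-bound curves/summaries and a
#'   `dilation` data.frame (roi, margin_mm, coverage).
#' @export
evaluate_overlap <- function(map, ref_mask, rois, thresholds = default_thresholds(),
                             max_margin_mm = 3) {
  reps <- lapply(names(rois), function(nm)
    roc_and_si_curves(map, ref_mask, rois[[nm]], thresholds, roi_name = nm))
  curves <- do.call(rbind, lapply(reps, `[[`, "curves"))
  summary <- do.call(rbind, lapply(reps, `[[`, "summary"))
  dil <- do.call(rbind, lapply(seq_along(reps), function(q) {
    nm <- names(rois)[q]
    pred <- threshold_map(map, summary$optimal_threshold[q])
    prof <- fn_dilation_profile(pred, ref_mask, rois[[nm]], max_margin_mm)
    cbind(roi = nm, prof)
  }))
  report <- list(curves = curves, summary = summary, dilation = dil)
  class(report) <- "overlap_report"
  report
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# One 6-connected (face-neighbor) binary dilation step.
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' False-negative dilation profile
#'
#' Dilates the tractography mask one voxel at a time (6-connected
#' structuring element) and reports, at each margin, the fraction of
#' reference voxels (within the ROI) covered -- the spatial extent of the
#' false negatives. Requires isotropic voxels so the margin in mm is
#' k x voxel size.
#'
#' @param pred_mask thresholded tractography mask (logical volume with voxel
#'   metadata).
#' @param ref_mask,roi_mask congruent logical volumes.
#' @param max_margin_mm profile extent in mm.
#' @return data.frame with `margin_mm` and `coverage` (non-decreasing,
#'   reaching 1 once the margin exceeds the largest ref-to-mask distance).
#'   An empty `pred_mask` yields an all-zero profile flagged with attribute
#'   `empty_prediction`.
#' @export
fn_dilation_profile <- function(pred_mask, ref_mask, roi_mask, max_margin_mm) {
  check_congruent(pred_mask, ref_mask, roi_mask)
  vs <- voxel_size(pred_mask)
  if (!is.null(attr(pred_mask, "pixdim")))
    tc_stop("tc_bad_geometry", "fn_dilation_profile requires isotropic voxels")
  refroi <- ref_mask & roi_mask
  nref <- sum(refroi)
  if (nref == 0) tc_stop("tc_degenerate", "no reference voxels inside the ROI")
  ks <- 0:floor(max_margin_mm / vs + 1e-9)
  if (!any(pred_mask)) {
    warning("empty prediction mask: dilation profile is identically zero")
    out <- data.frame(margin_mm = ks * vs, coverage = 0)
    attr(out, "empty_prediction") <- TRUE
    return(out)
  }
  cur <- pred_mask
  cov <- numeric(length(ks))
  for (q in seq_along(ks)) {
    if (q > 1) cur <- dilate6(cur)
    cov[q] <- sum(cur & refroi) / nref
  }
  data.frame(margin_mm = ks * vs, coverage = cov)
}

#' Average overlap reports across raters
#'
#' Rates (TPR, FPR, SI) and summary statistics (AUC, max SI, optimal
#' threshold, dilation coverage) are averaged arithmetically per cell;
#' confusion counts are summed for reference. All reports must share the
#' same (roi, threshold) grid.
#'
#' @param reports list of `overlap_report` objects.
#' @return the averaged `overlap_report`.
#' @export
average_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  base <- reports[[1]]
  for (r in reports[-1]) {
    if (!identical(r$curves$roi, base$curves$roi) ||
        !isTRUE(all.equal(r$curves$threshold, base$curves$threshold)))
      tc_stop("tc_grid_mismatch", "reports do not share the same (roi, threshold) grid")
  }
  avg <- base
  cell_stat <- function(field, col, fun) {
    m <- vapply(reports, function(r) as.numeric(r[[field]][[col]]),
                numeric(nrow(base[[field]])))
    apply(matrix(m, nrow = nrow(base[[field]])), 1, fun)
  }
  for (col in c("TPR", "FPR", "SI"))
    avg$curves[[col]] <- cell_stat("curves", col, mean)
  for (col in c("TP", "FP", "TN", "FN"))
    avg$curves[[col]] <- cell_stat("curves", col, sum)
  for (col in c("auc", "optimal_threshold", "max_si"))
    avg$summary[[col]] <- cell_stat("summary", col, mean)
  if (!is.null(base$dilation)) {
    for (r in reports[-1])
      if (is.null(r$dilation) || !identical(dim(r$dilation), dim(base$dilation)))
        tc_stop("tc_grid_mismatch", "reports do not share the same dilation grid")
    avg$dilation$coverage <- rowMeans(sapply(reports, function(r) r$dilation$coverage))
  }
  avg
}
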