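random_masks <- function(seed, d = c(8, 8, 8), p_pred = 0.3, p_ref = 0.3) {
  set.seed(seed)
  list(pred = as_volume(array(stats::runif(prod(d)) < p_pred, d), 1),
       ref = as_volume(array(stats::runif(prod(d)) < p_ref, d), 1),
       roi = as_volume(array(stats::runif(prod(d)) < 0.8, d), 1))
}

test_that("confusion counts match the brute-force tally on random masks", {
  for (s in 1:30) {
    mk <- random_masks(s)
    got <- confusion_counts(mk$pred, mk$ref, mk$roi)
    expect_identical(got, brute_confusion(mk$pred, mk$ref, mk$roi))
  }
})

test_that("TPR/FPR arithmetic and degenerate signalling", {
  expect_equal(tpr_fpr(list(TP = 3, FN = 1, FP = 1, TN = 9)),
               list(TPR = 0.75, FPR = 0.1))
  expect_equal(tpr_fpr(list(TP = 5, FN = 0, FP = 0, TN = 5)),
               list(TPR = 1, FPR = 0))
  expect_equal(tpr_fpr(list(TP = 5, FN = 0, FP = 5, TN = 0)),
               list(TPR = 1, FPR = 1))
  expect_error(tpr_fpr(list(TP = 0, FN = 0, FP = 1, TN = 1)),
               class = "tc_undefined_rate")
  expect_error(tpr_fpr(list(TP = 1, FN = 1, FP = 0, TN = 0)),
               class = "tc_undefined_rate")
})

test_that("Dice similarity: identities, symmetry, worked value, empty convention", {
  mk <- random_masks(3)
  expect_equal(dice_si(mk$ref, mk$ref), 1)
  expect_equal(dice_si(mk$pred, mk$ref), dice_si(mk$ref, mk$pred))
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- TRUE; b[3:4, 2, 1] <- TRUE
  expect_equal(dice_si(a, b), 0)                 # disjoint
  expect_equal(dice_si(a, a & FALSE), 0)         # one empty
  expect_equal(dice_si(a & FALSE, b & FALSE), 0) # both empty, by convention
  # |pred| = 4, |ref| = 6, overlap 3 -> 0.6
  p <- array(FALSE, c(4, 4, 4)); r <- p
  p[1:4, 1, 1] <- TRUE
  r[2:4, 1, 1] <- TRUE; r[1:3, 2, 1] <- TRUE
  expect_equal(dice_si(p, r), 2 * 3 / (4 + 6))
  expect_error(dice_si(a, array(FALSE, c(3, 3, 3))), class = "tc_shape_mismatch")
})

test_that("AUC equals the exhaustive rank statistic on random maps", {
  for (s in 1:30) {
    set.seed(100 + s)
    d <- c(8, 8, 8)
    counts <- array(stats::rpois(prod(d), 1.2), d)
    ref <- as_volume(array(stats::runif(prod(d)) < 0.3, d), 1)
    roi <- as_volume(array(TRUE, d), 1)
    m <- manual_map(counts, n_accepted = 50)
    vals <- counts / 50
    thr <- sort(unique(c(0, as.numeric(vals[vals > 0]))))
    rep <- roc_and_si_curves(m, ref, roi, thr)
    expect_equal(rep$summary$auc, brute_auc(vals, ref, roi), tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 and the optimal threshold attains max SI", {
  d <- c(8, 8, 8)
  ref <- array(FALSE, d); ref[3:6, 3:6, 3:6] <- TRUE
  counts <- array(0L, d); counts[ref] <- 10L; counts[1, 1, ] <- 1L
  m <- manual_map(counts, n_accepted = 20)
  thr <- sort(unique(c(0, as.numeric(counts[counts > 0]) / 20)))
  rep <- roc_and_si_curves(m, as_volume(ref, 1), as_volume(array(TRUE, d), 1), thr)
  expect_equal(rep$summary$auc, 1)
  si_at_opt <- rep$curves$SI[rep$curves$threshold == rep$summary$optimal_threshold]
  expect_equal(si_at_opt, max(rep$curves$SI))
  # ties at max SI break toward the smaller threshold
  expect_equal(rep$summary$optimal_threshold,
               min(rep$curves$threshold[rep$curves$SI == max(rep$curves$SI)]))
})

test_that("dilation profile: identities, erosion duality, single-voxel cross", {
  d <- c(12, 12, 12)
  ref <- array(FALSE, d); ref[4:9, 4:9, 4:9] <- TRUE
  roi <- as_volume(array(TRUE, d), 1)
  ref <- as_volume(ref, 1)
  # pred = ref -> full coverage at every margin
  prof <- fn_dilation_profile(ref, ref, roi, 3)
  expect_true(all(prof$coverage == 1))
  # an opened shape: dilating its erosion by one step recovers it exactly
  dil6 <- tractconcord:::dilate6
  open_ref <- as_volume(dil6(ref), 1)
  eroded <- as_volume(!dil6(!open_ref), 1)
  prof2 <- fn_dilation_profile(eroded, open_ref, roi, 2)
  expect_lt(prof2$coverage[1], 1)
  expect_equal(prof2$coverage[2], 1)
  # single voxel vs centered 3x3x3 cube: 6-connected cross covers 7/27 at k=1
  pred <- array(FALSE, d); pred[6, 6, 6] <- TRUE
  cube <- array(FALSE, d); cube[5:7, 5:7, 5:7] <- TRUE
  prof3 <- fn_dilation_profile(as_volume(pred, 1), as_volume(cube, 1), roi, 1)
  expect_equal(prof3$coverage[2], 7 / 27)
  # non-decreasing everywhere
  expect_true(all(diff(prof3$coverage) >= 0))
  # empty prediction: flagged all-zero profile
  expect_warning(p0 <- fn_dilation_profile(as_volume(array(FALSE, d), 1), ref, roi, 2))
  expect_true(all(p0$coverage == 0))
  expect_true(isTRUE(attr(p0, "empty_prediction")))
})

test_that("anisotropic volumes are rejected by the dilation profile", {
  d <- c(8, 8, 8)
  m <- as_volume(array(TRUE, d), 1)
  bad <- m
  attr(bad, "pixdim") <- c(1, 1, 2)
  expect_error(fn_dilation_profile(bad, m, m, 2), class = "tc_bad_geometry")
})

test_that("rater averaging: identity, arithmetic mean, order independence", {
  mk <- random_masks(7)
  counts <- array(stats::rpois(512, 1), c(8, 8, 8))
  maps <- lapply(1:3, function(s) {
    set.seed(200 + s)
    manual_map(array(stats::rpois(512, 1.5), c(8, 8, 8)), n_accepted = 40)
  })
  thr <- seq(0, 0.1, length.out = 20)
  reps <- lapply(maps, function(m) roc_and_si_curves(m, mk$ref, mk$roi, thr))
  expect_equal(average_reports(list(reps[[1]], reps[[1]]))$curves$SI,
               reps[[1]]$curves$SI)
  avg <- average_reports(reps)
  expect_equal(avg$curves$SI, (reps[[1]]$curves$SI + reps[[2]]$curves$SI +
                               reps[[3]]$curves$SI) / 3)
  expect_equal(avg$curves$TP, reps[[1]]$curves$TP + reps[[2]]$curves$TP +
                              reps[[3]]$curves$TP)
  perm <- average_reports(reps[c(3, 1, 2)])
  expect_equal(perm$curves$SI, avg$curves$SI)
  expect_equal(perm$summary$auc, avg$summary$auc)
  # mismatched grids are refused
  other <- roc_and_si_curves(maps[[1]], mk$ref, mk$roi, seq(0, 0.2, length.out = 20))
  expect_error(average_reports(list(reps[[1]], other)), class = "tc_grid_mismatch")
})
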