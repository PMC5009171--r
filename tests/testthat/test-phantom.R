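test_that("configuration validation rejects degenerate worlds", {
  expect_s3_class(phantom_config(), "phantom_config")
  expect_error(phantom_config(grid_shape = c(8, 48, 48)), class = "tc_config_error")
  expect_error(phantom_config(dispersion_kappa = 0), class = "tc_config_error")
  expect_error(phantom_config(voxel_size_mm = 1, tube_radius_mm = 0.5),
               class = "tc_config_error")
  expect_error(phantom_config(arc_params = list(left = diag(3), right = diag(3))),
               class = "tc_config_error")
})

test_that("phantom construction is deterministic", {
  a <- build_phantom(phantom_config(grid_shape = c(32, 32, 32), voxel_size_mm = 0.75,
                                    rng_seed = 11))
  b <- build_phantom(phantom_config(grid_shape = c(32, 32, 32), voxel_size_mm = 0.75,
                                    rng_seed = 11))
  expect_identical(a$tract_mask_left, b$tract_mask_left)
  expect_identical(a$fiber_field$orientations, b$fiber_field$orientations)
  expect_identical(a$intensity_volume, b$intensity_volume)
})

test_that("left and right tracts are mirror images (voxel counts within 5%)", {
  ph <- test_phantom()
  nl <- sum(ph$tract_mask_left); nr <- sum(ph$tract_mask_right)
  expect_lt(abs(nl - nr) / max(nl, nr), 0.05)
})

test_that("each centerline crosses the midline exactly once", {
  ph <- test_phantom()
  mid <- dim(ph$roi_labels)[1] * voxel_size(ph$roi_labels) / 2
  for (side in c("left", "right")) {
    sgn <- sign(ph$geometry[[side]]$centerline[, 1] - mid)
    sgn <- sgn[sgn != 0]
    expect_identical(sum(diff(sgn) != 0), 1L)
  }
})

test_that("mask invariants hold: seeds/targets inside tract, exclusion outside", {
  ph <- test_phantom()
  expect_true(all(ph$tract_mask_left[ph$seed_mask_left]))
  expect_true(all(ph$tract_mask_right[ph$seed_mask_right]))
  expect_true(all(ph$tract_mask_left[ph$target_mask_right]))  # end of left tract
  expect_true(all(ph$tract_mask_right[ph$target_mask_left]))
  union_tract <- ph$tract_mask_left | ph$tract_mask_right
  expect_false(any(ph$exclusion_mask & union_tract))
  expect_false(any(ph$exclusion_mask & (ph$seed_mask_left | ph$seed_mask_right |
                                        ph$target_mask_left | ph$target_mask_right)))
  expect_gt(sum(ph$exclusion_mask), 0)
})

test_that("fiber field: every tract voxel populated, crossing zone has 2 populations", {
  ph <- test_phantom()
  fr <- ph$fiber_field$fractions
  nv <- prod(dim(ph$roi_labels))
  idx <- which(ph$tract_mask_left | ph$tract_mask_right)
  f1 <- fr[idx]; f2 <- fr[idx + nv]; f3 <- fr[idx + 2 * nv]
  expect_true(all(f1 > 0))                       # >= 1 population everywhere
  expect_true(all(f1 >= f2 & f2 >= f3))          # ordered fractions
  expect_true(all(f1 + f2 + f3 <= 1 + 1e-12))
  dec <- which(ph$roi_labels == 3L)
  expect_true(all(fr[dec + nv] > 0))             # two populations in the crossing zone
  # orientations of populated slots are unit norm
  ori <- ph$fiber_field$orientations
  n1 <- sqrt(ori[idx]^2 + ori[idx + 3 * nv]^2 + ori[idx + 6 * nv]^2)
  expect_equal(n1, rep(1, length(idx)), tolerance = 1e-9)
})

test_that("first orientation equals the local centerline tangent (own-side voxels)", {
  ph <- test_phantom()
  nv <- prod(dim(ph$roi_labels))
  own <- setdiff(ph$geometry$left$idx, which(ph$tract_mask_right))
  sel <- match(own, ph$geometry$left$idx)
  ori <- ph$fiber_field$orientations
  got <- cbind(ori[own], ori[own + 3 * nv], ori[own + 6 * nv])
  expect_lt(max(abs(got - ph$geometry$left$tangent[sel, ])), 1e-6)
})

test_that("ROI labels are ordered seed -> crossing and the decussation is shared", {
  ph <- test_phantom()
  for (side in c("left", "right")) {
    g <- ph$geometry[[side]]
    lab <- ph$roi_labels[g$idx]
    dent <- g$s[lab == if (side == "left") 1L else 5L]
    ped <- g$s[lab == if (side == "left") 2L else 4L]
    dec <- g$s[lab == 3L]
    expect_true(length(dent) > 0 && length(ped) > 0 && length(dec) > 0)
    expect_lt(max(dent), min(ped) + 1e-9)
    expect_lt(max(ped), min(dec) + 1e-9)
  }
  dec_mask <- ph$roi_labels == 3L
  expect_gt(sum(dec_mask & ph$tract_mask_left), 0)
  expect_gt(sum(dec_mask & ph$tract_mask_right), 0)
})
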