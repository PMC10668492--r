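test_that("morphological operators honour radius-zero identity and set inclusion", {
  p <- quiet_pair()
  m <- p$baseline_mask
  expect_identical(morph_op(m, "erode", 0), m)
  expect_error(morph_op(m, "shrink", 1), "unknown")
  # erode-then-dilate (opening) is contained in the closing, on random blobs
  set.seed(3)
  for (i in 1:5) {
    blob <- array(FALSE, c(16, 16, 16))
    idx <- cbind(sample(4:13, 30, TRUE), sample(4:13, 30, TRUE), sample(4:13, 30, TRUE))
    blob[idx] <- TRUE
    blob <- morph_op(blob, "dilate", 1)
    opened <- morph_op(morph_op(blob, "erode", 1), "dilate", 1)
    closed <- morph_op(blob, "close", 1)
    expect_true(all(closed[opened]))
  }
  # open(close(x)) returns a large convex mask unchanged
  conv <- morph_op(p$baseline_mask, "dilate", 1)
  expect_identical(morph_op(morph_op(conv, "close", 1), "open", 1), conv)
})

test_that("morphology radii are metric: anisotropic spacing halves voxel reach", {
  m <- array(FALSE, c(15, 15, 15)); m[8, 8, 8] <- TRUE
  d_iso <- morph_op(m, "dilate", 4, spacing_mm = c(1, 1, 1))
  d_ani <- morph_op(m, "dilate", 4, spacing_mm = c(1, 1, 2))
  # along z the 4 mm ball reaches 4 voxels at 1 mm but only 2 at 2 mm spacing
  expect_true(d_iso[8, 8, 12])
  expect_false(d_ani[8, 8, 12])
  expect_true(d_ani[8, 8, 10])
  expect_true(d_ani[12, 8, 8])  # x unaffected
})

test_that("the peritumoral ring is exactly the (0, width] distance band", {
  p <- quiet_pair()
  ring <- peritumoral_ring(region_mask(p$baseline_mask, p$spacing_mm), 3)
  d <- distance_transform(p$baseline_mask, p$spacing_mm)
  expect_true(all(d[ring$array] > 0 & d[ring$array] <= 3 + 1e-6))
  outside <- !ring$array & !p$baseline_mask
  expect_true(all(d[outside] > 3 - 1e-6 | d[outside] == 0 | d[outside] > 3))
  expect_false(any(ring$array & p$baseline_mask))
  expect_identical(sum(peritumoral_ring(p$baseline_mask, 0,
                                        spacing_mm = p$spacing_mm)$array), 0L)
  expect_error(peritumoral_ring(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("masking fills the background and preserves in-mask voxels", {
  p <- quiet_pair()
  v <- p$baseline_volume
  expect_identical(apply_mask(v, array(TRUE, dim(v))), v)
  expect_true(all(apply_mask(v, array(FALSE, dim(v)), -1000) == -1000))
  half <- array(FALSE, dim(v)); half[1:32, , ] <- TRUE
  out <- apply_mask(v, half)
  expect_identical(out[1:32, , ], v[1:32, , ])
  expect_true(all(out[33:64, , ] == 0))
  expect_error(apply_mask(v, array(TRUE, c(2, 2, 2))), "mismatch")
})

test_that("active-contour refinement recovers an eroded initialisation", {
  spec <- phantom_spec(texture_sd_hu = 10, noise_sd_hu = 15, seed = 12)
  p <- generate_pair(spec)
  truth <- p$baseline_mask
  init <- morph_op(truth, "erode", 2, spacing_mm = p$spacing_mm)
  refined <- refine_mask(p$baseline_volume, region_mask(init, p$spacing_mm),
                         iterations = 30)
  expect_gte(dice_coef(refined, truth), dice_coef(init, truth))
  expect_gt(dice_coef(refined, truth), 0.9)
  # zero iterations leave the initialisation untouched
  same <- refine_mask(p$baseline_volume, region_mask(truth, p$spacing_mm),
                      iterations = 0)
  expect_identical(same$array, truth)
})

test_that("rater simulation produces tagged, nonempty, distinct masks", {
  p <- quiet_pair()
  rat <- simulate_raters(p$followup_mask, n_raters = 2, n_repeats = 2,
                         spacing_mm = p$spacing_mm, seed = 4)
  expect_length(rat, 2)
  expect_identical(rat[[2]][[1]]$rater_id, "R2")
  expect_identical(rat[[1]][[2]]$repeat_id, 2L)
  expect_true(all(vapply(rat, function(r) all(vapply(r, function(m) sum(m$array) > 0,
                                                     logical(1))), logical(1))))
})
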