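test_that("view extraction picks the equatorial slice and a tight square crop", {
  spec <- phantom_spec(radii_mm = c(6, 6, 6), texture_sd_hu = 0, noise_sd_hu = 0,
                       seed = 1)
  v <- generate_volume(spec, 0)
  vs <- extract_views(v$volume, v$mask, margin_px = 3)
  cen <- spec$nodule_center_mm / spec$spacing_mm + 1
  expect_equal(unname(vs$slice_index), round(cen), tolerance = 1)
  for (a in c("x", "y", "z")) {
    side <- dim(vs$views[[a]])[1]
    expect_identical(dim(vs$views[[a]])[1], dim(vs$views[[a]])[2])
    # side ~ diameter + 2 * margin (voxelised)
    expect_lt(abs(side - (12 + 2 * 3)), 3)
    expect_true(any(vs$mask_views[[a]]))
  }
  # single voxel mask -> 1x1 before margin
  single <- array(FALSE, dim(v$mask)); single[10, 20, 30] <- TRUE
  vs1 <- extract_views(v$volume, single, margin_px = 0)
  expect_identical(dim(vs1$views$x), c(1L, 1L))
  expect_error(extract_views(v$volume, array(FALSE, dim(v$mask))), "empty")
})

test_that("maximal-area ties break to the lowest slice index", {
  m <- array(FALSE, c(8, 8, 8))
  m[3, 4:5, 4:5] <- TRUE
  m[6, 4:5, 4:5] <- TRUE  # same x-slice area
  v <- array(0, c(8, 8, 8))
  vs <- extract_views(v, m)
  expect_identical(unname(vs$slice_index["x"]), 3L)
})

test_that("view extraction commutes with intensity rescaling", {
  p <- active_pair()
  v1 <- extract_views(p$followup_volume, p$followup_mask)
  v2 <- extract_views(p$followup_volume * 2 + 10, p$followup_mask)
  expect_equal(v2$views$y, v1$views$y * 2 + 10, tolerance = 1e-10)
  expect_identical(v1$boxes, v2$boxes)
})

test_that("SSIM matches a brute-force windowed computation to 1e-8", {
  set.seed(5)
  a <- matrix(runif(64), 8, 8)
  b <- a + matrix(rnorm(64, sd = 0.1), 8, 8)
  w <- 5; sigma <- 1.5
  L <- max(a, b) - min(a, b)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- exp(-((1:w - 3)^2) / (2 * sigma^2)); kern <- outer(g, g); kern <- kern / sum(kern)
  vals <- c()
  for (i in 1:(8 - w + 1)) for (j in 1:(8 - w + 1)) {
    pa <- a[i:(i + w - 1), j:(j + w - 1)]; pb <- b[i:(i + w - 1), j:(j + w - 1)]
    mua <- sum(kern * pa); mub <- sum(kern * pb)
    va <- sum(kern * pa^2) - mua^2; vb <- sum(kern * pb^2) - mub^2
    cab <- sum(kern * pa * pb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + c1) * (2 * cab + c2)) /
                ((mua^2 + mub^2 + c1) * (va + vb + c2)))
  }
  expect_equal(ssim(a, b, window = 5, sigma = 1.5), mean(vals), tolerance = 1e-8)
  expect_identical(ssim(a, a), 1)
  expect_identical(ssim(matrix(3, 4, 4), matrix(3, 4, 4)), 1)
  # contrast inversion about the intensity midpoint scores negative
  # (luminance preserved, structure inverted)
  set.seed(6)
  z <- matrix(runif(256), 16, 16)
  expect_lt(ssim(z, 1 - z, window = 7), 0)
})

test_that("intensity registration recovers known translations and rotations", {
  base <- smooth_image()
  f <- base[15:50, 15:50]
  mov_t <- apply_transform2d(base, c(tx = 5, ty = -3, theta_deg = 0, scale = 1))$image
  r <- register(f, mov_t[15:50, 15:50], "monomodal_intensity")
  # the estimate is the inverse of the warp that generated the moving image
  expect_lt(max(abs(r$transform[c("tx", "ty")] - c(-5, 3))), 0.5)
  expect_lt(abs(r$transform["theta_deg"]), 1)
  expect_gt(r$ssim, r$ssim_unregistered)
  mov_r <- apply_transform2d(base, c(tx = 0, ty = 0, theta_deg = 10, scale = 1))$image
  for (meth in c("monomodal_intensity", "multimodal_mi")) {
    r2 <- register(f, mov_r[15:50, 15:50], meth)
    expect_lt(abs(r2$transform["theta_deg"] + 10), 1)
    expect_lt(max(abs(r2$transform[c("tx", "ty")])), 0.5)
  }
  # identical pair: identity transform, SSIM 1
  r3 <- register(f, f)
  expect_identical(unname(r3$transform), c(0, 0, 0, 1))
  expect_identical(r3$ssim, 1)
})

test_that("keypoint registration recovers the transform or signals fallback", {
  base <- blocky_image()
  f <- base[16:75, 16:75]
  mov <- apply_transform2d(base, c(tx = 4, ty = -2, theta_deg = 0, scale = 1))$image
  r <- register(f, mov[16:75, 16:75], "keypoint")
  expect_false(r$fallback_needed)
  expect_lt(max(abs(r$transform[c("tx", "ty")] - c(-4, 2))), 0.5)
  mov_r <- apply_transform2d(base, c(tx = 0, ty = 0, theta_deg = 8, scale = 1))$image
  r2 <- register(f, mov_r[16:75, 16:75], "keypoint")
  expect_lt(abs(r2$transform["theta_deg"] + 8), 1)
  # featureless images cannot be keypoint-matched
  flat <- matrix(seq(0, 1e-3, length.out = 1600), 40, 40)
  r3 <- register(flat, t(flat), "keypoint")
  expect_true(r3$fallback_needed)
})

test_that("registration never worsens SSIM beyond tolerance (identity safeguard)", {
  set.seed(8)
  a <- matrix(runif(900), 30, 30)
  b <- matrix(runif(900), 30, 30)  # unrelated pair: nothing to align
  r <- register(a, b, "monomodal_intensity")
  expect_gte(r$ssim, r$ssim_unregistered - 0.02)
})

test_that("spine fallback realigns a translated pair via the rigid landmark", {
  spec <- phantom_spec(growth_rates_per_day = c(0, 0, 0), noise_sd_hu = 2,
                       motion = list(translation_mm = c(2, -2, 0),
                                     rotation_deg = c(0, 0, 0)), seed = 31)
  pair <- generate_pair(spec)
  vp <- extract_view_pair(pair)
  sp <- spine_crop_pair(pair, vp$fixed$slice_index, vp$moving$slice_index)
  fb <- spine_fallback_register(sp$fixed$z, sp$moving$z,
                                vp$moving$views$z, vp$fixed$views$z)
  expect_true(fb$fallback_used)
  expect_lt(max(abs(fb$transform[c("tx", "ty")] - c(-2, 2))), 0.75)
  expect_gt(fb$ssim, fb$ssim_unregistered)
  # zero motion: spine-estimated transform is the identity
  quiet <- quiet_pair()
  vq <- extract_view_pair(quiet)
  sq <- spine_crop_pair(quiet, vq$fixed$slice_index, vq$moving$slice_index)
  fb0 <- spine_fallback_register(sq$fixed$z, sq$moving$z,
                                 vq$moving$views$z, vq$fixed$views$z)
  expect_lt(max(abs(fb0$transform[c("tx", "ty", "theta_deg")])), 0.2)
})

test_that("subtraction is antisymmetric, zero for identical inputs, rim-focused for growth", {
  p <- quiet_pair()
  vp <- extract_view_pair(p)
  s <- subtract_views(vp$moving$views$x, vp$fixed$views$x)
  expect_true(all(s$raw == 0))
  expect_true(all(s$image == 0.5))  # zero difference maps to mid-range
  set.seed(9)
  a <- matrix(runif(100), 10, 10); b <- matrix(runif(100), 10, 10)
  expect_equal(subtract_views(a, b)$raw, -subtract_views(b, a)$raw,
               tolerance = 1e-12)
  expect_error(subtract_views(a, matrix(0, 5, 5)), "mismatch")
  # noiseless growth: strongest differences concentrate in the growth rim
  spec <- phantom_spec(radii_mm = c(5, 5, 5), growth_rates_per_day = rep(0.004, 3),
                       interval_days = 120, texture_sd_hu = 20, noise_sd_hu = 0,
                       seed = 17)
  pg <- generate_pair(spec)
  vg <- extract_view_pair(pg)
  raw <- subtract_views(vg$moving$views$z, vg$fixed$views$z)$raw
  rim <- vg$fixed$mask_views$z & !vg$moving$mask_views$z
  thr <- stats::quantile(abs(raw), 0.9)
  top <- abs(raw) >= thr
  expect_gte(mean(rim[top]), 0.8)
})

test_that("the full view pipeline gives exactly-zero delta images on a static pair", {
  ds <- delta_image_set(quiet_pair())
  expect_s3_class(ds, "delta_image_set")
  for (a in c("x", "y", "z")) {
    expect_true(all(ds$raw[[a]] == 0))
    expect_identical(dim(ds$images[[a]]), c(64L, 64L))
  }
  expect_identical(nrow(ds$log), 3L)
})
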