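test_that("rendered masks track the analytic ellipsoid volume", {
  spec <- phantom_spec(radii_mm = c(5, 5, 5), texture_sd_hu = 0,
                       noise_sd_hu = 0, seed = 1)
  v <- generate_volume(spec, 0)
  expect_equal(sum(v$mask), 4 / 3 * pi * 125, tolerance = 0.05)
  # zero texture, zero noise: every nodule voxel at the nominal attenuation
  expect_true(all(v$volume[v$mask] == spec$hu_nodule))
  # determinism
  v2 <- generate_volume(spec, 0)
  expect_identical(v$volume, v2$volume)
})

test_that("a static spec yields voxelwise-identical scan pairs", {
  p <- quiet_pair()
  expect_identical(p$baseline_volume, p$followup_volume)
  expect_identical(p$baseline_mask, p$followup_mask)
  expect_true(p$times_days[2] > p$times_days[1])
})

test_that("pure translation moves the follow-up mask centroid by the translation", {
  spec <- phantom_spec(growth_rates_per_day = c(0, 0, 0), noise_sd_hu = 0,
                       motion = list(translation_mm = c(3, -2, 1),
                                     rotation_deg = c(0, 0, 0)),
                       seed = 5)
  p <- generate_pair(spec)
  cb <- colMeans(which(p$baseline_mask, arr.ind = TRUE))
  cf <- colMeans(which(p$followup_mask, arr.ind = TRUE))
  expect_lt(max(abs((cf - cb) - c(3, -2, 1))), 1)
})

test_that("isotropic exponential growth scales mask volume like exp(3 g t)", {
  spec <- phantom_spec(radii_mm = c(5, 5, 5), growth_rates_per_day = rep(0.01, 3),
                       interval_days = 100, noise_sd_hu = 0, seed = 2)
  p <- generate_pair(spec)
  ratio <- sum(p$followup_mask) / sum(p$baseline_mask)
  expect_equal(ratio, exp(3), tolerance = 0.1)
})

test_that("an out-of-grid nodule is rejected explicitly", {
  expect_error(phantom_spec(radii_mm = c(30, 5, 5)), "exceeds")
  expect_error(phantom_spec(radii_mm = c(5, 5, 5), growth_rates_per_day = rep(0.02, 3),
                            interval_days = 100), "exceeds")
  expect_error(phantom_spec(interval_days = 0), "interval_days")
  expect_error(phantom_spec(radii_mm = c(-1, 5, 5)), "positive")
})

test_that("cohorts have the exact requested prevalence and are reproducible", {
  c1 <- generate_cohort(10, prevalence = 0.5, seed = 3)
  labs <- vapply(c1, function(p) as.integer(p$label), integer(1))
  expect_identical(sum(labs), 5L)
  # 24.4% prevalence rounds to 24/100 positives
  set.seed(99)
  n_pos <- round(100 * 0.244)
  expect_identical(n_pos, 24)
  c2 <- generate_cohort(10, prevalence = 0.5, seed = 3)
  expect_identical(c1[[4]]$followup_volume, c2[[4]]$followup_volume)
  expect_identical(vapply(c1, `[[`, "", "subject_id"),
                   vapply(c2, `[[`, "", "subject_id"))
  expect_error(generate_cohort(1), "at least 2")
})

test_that("cohort NIfTI round trip preserves volumes, masks and metadata", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(2, prevalence = 0.5, seed = 8)
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(file.path(dir, "manifest.csv"))
  expect_equal(back[[1]]$baseline_volume, coh[[1]]$baseline_volume,
               tolerance = 1e-6)
  expect_identical(back[[1]]$followup_mask, coh[[1]]$followup_mask)
  expect_identical(back[[2]]$label, coh[[2]]$label)
  expect_equal(back[[2]]$times_days, coh[[2]]$times_days, tolerance = 1e-9)
})
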