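test_that("the inventory and extracted vectors agree on names, counts, families", {
  inv <- feature_inventory()
  expect_identical(nrow(inv), 851L)
  expect_identical(anyDuplicated(inv$name), 0L)
  counts <- table(inv$family[inv$image_type == "original"])
  expect_identical(as.integer(counts[c("shape", "firstorder", "glcm", "gldm",
                                       "glrlm", "glszm", "ngtdm")]),
                   c(14L, 18L, 24L, 14L, 16L, 16L, 5L))
  fv <- small_features()
  expect_identical(names(fv), inv$name)
  expect_true(all(is.finite(fv)))
})

test_that("a constant-intensity region collapses the histogram and texture", {
  vol <- array(-50, c(12, 12, 12))
  m <- array(FALSE, c(12, 12, 12)); m[4:9, 4:9, 4:9] <- TRUE
  fv <- extract_features(vol, region_mask(m), radiomics_config(wavelet = FALSE))
  expect_identical(unname(fv["original_firstorder_Variance"]), 0)
  expect_identical(unname(fv["original_firstorder_Entropy"]), 0)
  expect_identical(unname(fv["original_glcm_Contrast"]), 0)
  expect_identical(unname(fv["original_glcm_Correlation"]), 1)
})

test_that("extraction is deterministic and rejects degenerate masks", {
  p <- active_pair()
  m <- region_mask(p$baseline_mask, p$spacing_mm)
  f1 <- extract_features(p$baseline_volume, m, radiomics_config(wavelet = FALSE))
  f2 <- extract_features(p$baseline_volume, m, radiomics_config(wavelet = FALSE))
  expect_identical(as.numeric(f1), as.numeric(f2))
  single <- array(FALSE, dim(p$baseline_mask)); single[30, 30, 30] <- TRUE
  expect_error(extract_features(p$baseline_volume, region_mask(single)),
               "more than one voxel")
})

test_that("shape features ignore intensity; first-order mean shifts additively", {
  p <- active_pair()
  m <- region_mask(p$followup_mask, p$spacing_mm)
  cfg <- radiomics_config(wavelet = FALSE)
  a <- extract_features(p$followup_volume, m, cfg)
  b <- extract_features(p$followup_volume * 3 + 100, m, cfg)
  shp <- grep("^original_shape", names(a), value = TRUE)
  expect_equal(a[shp], b[shp], tolerance = 1e-12)
  d <- extract_features(p$followup_volume + 55, m, cfg)
  expect_equal(unname(d["original_firstorder_Mean"] - a["original_firstorder_Mean"]),
               55, tolerance = 1e-9)
})

test_that("wavelet sub-bands: LLL of a constant volume is the scaled constant, H bands vanish", {
  v <- array(2, c(8, 8, 8))
  b <- wavelet_subbands(v)
  expect_identical(names(b), c("LLL", "LLH", "LHL", "HLL", "LHH", "HLH", "HHL", "HHH"))
  expect_equal(unique(as.vector(b$LLL)), 2 * 2^{3 / 2}, tolerance = 1e-12)
  expect_true(all(abs(b$HHH) < 1e-12) && all(abs(b$LLH) < 1e-12))
})

test_that("min-max normalisation maps fitted rows into [0,1] and round-trips", {
  expect_equal(unname(minmax_normalize(matrix(c(2, 6), 2, 1))$values[, 1]), c(0, 1))
  expect_equal(unname(minmax_normalize(matrix(1:3, 3, 1))$values[, 1]), c(0, 0.5, 1))
  set.seed(6)
  x <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  nrm <- minmax_normalize(x, fit_rows = 1:8)
  expect_true(all(nrm$values[1:8, ] >= 0 & nrm$values[1:8, ] <= 1))
  expect_equal(minmax_invert(nrm, nrm$values), x, tolerance = 1e-12)
  # held-out rows may leave [0,1]; the transform must still be the same map
  expect_equal(minmax_apply(nrm, x), nrm$values, tolerance = 1e-12)
  xc <- cbind(x, const = 1)
  expect_warning(nc <- minmax_normalize(xc), "constant")
  expect_true(all(nc$values[, "const"] == 0))
})
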