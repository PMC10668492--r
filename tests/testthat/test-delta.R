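test_that("delta slopes follow the time-slope definition and its algebra", {
  expect_equal(as.numeric(delta_slope(c(f = 2), c(f = 6), 0, 4)), 1.0)
  v <- stats::setNames(rnorm(10), paste0("f", 1:10))
  expect_true(all(delta_slope(v, v, 0, 30) == 0))
  expect_error(delta_slope(v, v, 10, 10), "exceed")
  expect_error(delta_slope(v, stats::setNames(v, paste0("g", 1:10)), 0, 1), "names")
  # linearity and antisymmetry under timepoint swap
  set.seed(2)
  b <- stats::setNames(rnorm(20), paste0("f", 1:20))
  f <- stats::setNames(rnorm(20), paste0("f", 1:20))
  s <- delta_slope(b, f, 3, 45)
  expect_equal(as.numeric(delta_slope(b * 5, f * 5, 3, 45)), as.numeric(s) * 5,
               tolerance = 1e-12)
  # swapping the roles of the scans flips the slope's sign
  expect_equal(as.numeric(delta_slope(f, b, 3, 45)), -as.numeric(s),
               tolerance = 1e-12)
})

test_that("the dual table binds four 851-wide blocks into 3404 named columns", {
  mk <- function(n) matrix(rnorm(2 * n), 2, n,
                           dimnames = list(c("S1", "S2"), paste0("f", 1:n)))
  full <- assemble_dual_table(mk(851), mk(851), mk(851), mk(851))
  expect_identical(ncol(full), 3404L)
  pre <- sub("\\..*$", "", colnames(full))
  expect_identical(as.integer(table(pre)[c("classic_intra", "classic_peri",
                                           "delta_intra", "delta_peri")]),
                   rep(851L, 4))
  # one omitted block
  expect_identical(ncol(assemble_dual_table(mk(851), mk(851), mk(851), NULL)), 2553L)
  bad <- mk(851); rownames(bad) <- c("S1", "S9")
  expect_error(assemble_dual_table(mk(851), bad, NULL, NULL), "subject ids")
})

test_that("ICC(2,1) matches the ANOVA mean-squares decomposition exactly", {
  # hand-built 6 subjects x 2 raters
  m <- rbind(c(9, 2), c(1, 10), c(8, 8), c(2, 6), c(10, 6), c(9, 8))
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum(m^2) - k * sum(rowMeans(m)^2) - n * sum(colMeans(m)^2) +
            n * k * grand^2) / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc21(m), oracle, tolerance = 1e-10)
})

test_that("ICC behaves at the reliability extremes and under shifts", {
  set.seed(11)
  subj <- rnorm(40, 0, 2)
  dup <- cbind(subj, subj)
  expect_identical(suppressWarnings(icc21(dup)), 1)
  expect_warning(icc21(matrix(5, 6, 2)), "zero variance")
  # equal subject and error variance -> ICC near 0.5 at large n
  set.seed(12)
  s <- rnorm(500)
  m <- cbind(s + rnorm(500), s + rnorm(500))
  expect_gt(icc21(m), 0.4); expect_lt(icc21(m), 0.6)
  # invariance to adding a constant
  expect_equal(icc21(m + 100), icc21(m), tolerance = 1e-10)
})

test_that("ICC reports and the reproducibility gate retain the right columns", {
  set.seed(13)
  n <- 30
  good <- rnorm(n, sd = 5)
  meas <- list(
    stable = array(rep(good, 4) + rnorm(4 * n, sd = 0.1), c(n, 2, 2)),
    noisy = array(rnorm(4 * n), c(n, 2, 2)))
  rep_df <- compute_icc(meas, threshold = 0.75)
  expect_s3_class(rep_df, "icc_report")
  expect_true(rep_df$pass[rep_df$feature == "stable"])
  expect_false(rep_df$pass[rep_df$feature == "noisy"])
  tab <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("stable", "noisy")))
  kept <- icc_filter(tab, rep_df)
  expect_identical(colnames(kept), "stable")
  # survivors equal a brute-force scan of the report
  brute <- rep_df$feature[rep_df$intra_icc > 0.75 & rep_df$inter_icc > 0.75]
  expect_identical(colnames(kept), intersect(colnames(tab), brute))
  expect_error(icc_filter(tab, rep_df, threshold = 1), "no feature survives")
  all_pass <- rep_df; all_pass$pass <- TRUE
  expect_identical(icc_filter(tab, all_pass), tab)
})

test_that("a static cohort yields exactly-zero delta blocks", {
  p <- quiet_pair()
  cfg <- radiomics_config(wavelet = FALSE)
  m_b <- region_mask(p$baseline_mask, p$spacing_mm)
  m_f <- region_mask(p$followup_mask, p$spacing_mm)
  fb <- extract_features(p$baseline_volume, m_b, cfg)
  ff <- extract_features(p$followup_volume, m_f, cfg)
  d <- delta_slope(fb, ff, p$times_days[1], p$times_days[2])
  expect_true(all(d == 0))
})
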