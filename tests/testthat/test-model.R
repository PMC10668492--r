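test_that("ReliefF rewards a perfect feature, nulls noise, matches a hand computation", {
  set.seed(1)
  x <- cbind(perfect = rep(0:1, 50), noise = rnorm(100))
  w <- relieff_rank(x, x[, "perfect"], K = 5)
  expect_identical(names(which.max(w)), "perfect")
  expect_lt(abs(w["noise"]), 0.05)
  expect_error(relieff_rank(x, x[, 1], K = 50), "below")
  # 6-sample hand-built table, K = 1: brute-force nearest hit/miss
  xt <- cbind(f1 = c(0, 0.1, 0.2, 1, 0.9, 0.8), f2 = c(0.5, 0.4, 0.6, 0.5, 0.6, 0.4))
  yt <- c(0, 0, 0, 1, 1, 1)
  rng <- apply(xt, 2, function(v) max(v) - min(v))
  xn <- sweep(sweep(xt, 2, apply(xt, 2, min), `-`), 2, rng, `/`)
  D <- as.matrix(dist(xn, method = "manhattan"))
  wo <- c(0, 0)
  for (i in 1:6) {
    d <- D[i, ]; d[i] <- Inf
    hit <- which.min(d + ifelse(yt == yt[i], 0, Inf))
    mis <- which.min(d + ifelse(yt != yt[i], 0, Inf))
    wo <- wo - abs(xn[hit, ] - xn[i, ]) / 6 + abs(xn[mis, ] - xn[i, ]) / 6
  }
  expect_equal(unname(relieff_rank(xt, yt, K = 1)), unname(wo), tolerance = 1e-12)
})

test_that("elastic-net selection recovers planted signal and skips degenerate columns", {
  set.seed(7)
  n <- 300; p <- 60
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, "f60"] <- 0  # zero-variance column
  y <- rbinom(n, 1, plogis(2 * X[, 1] + 2 * X[, 2] - 2 * X[, 3]))
  res <- lasso_select(X, y, alpha = 0.5, seed = 3)
  expect_true(all(c("f1", "f2", "f3") %in% res$selected))
  expect_false("f60" %in% res$selected)
  expect_true(is.finite(length(res$selected)))
  # duplicated informative column stays finite and sane
  X2 <- cbind(X, f1dup = X[, 1])
  res2 <- lasso_select(X2, y, alpha = 0.5, seed = 3)
  expect_lt(length(res2$selected), p + 1)
})

test_that("registries have the documented cardinalities and unique names", {
  sel <- default_selector_registry()
  clf <- default_classifier_registry()
  expect_length(sel, 45L)
  expect_length(clf, 32L)
  expect_identical(anyDuplicated(names(sel)), 0L)
  expect_identical(anyDuplicated(names(clf)), 0L)
  g <- enumerate_grid(sel, clf)
  expect_identical(nrow(g), 1440L)
  expect_identical(g, enumerate_grid(sel, clf))  # stable order
  expect_identical(nrow(enumerate_grid(sel[1:2], clf[1:3])), 6L)
})

test_that("AUC equals brute-force concordant-pair counting and handles extremes", {
  scores <- c(0.1, 0.9, 0.4, 0.35, 0.8, 0.22, 0.65, 0.3, 0.75, 0.5)
  labs <- c(0, 1, 0, 1, 1, 0, 0, 0, 1, 1)
  conc <- 0; npairs <- 0
  for (i in which(labs == 1)) for (j in which(labs == 0)) {
    npairs <- npairs + 1
    conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  expect_equal(roc_auc(scores, labs), conc / npairs, tolerance = 1e-12)
  expect_identical(roc_auc(labs, labs), 1)
})

test_that("cross-validation reports honest null and signal AUCs", {
  set.seed(4)
  n <- 200; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, 0.4)
  sel <- default_selector_registry()[["ttest_top10"]]
  clf <- default_classifier_registry()[["lda"]]
  r0 <- crossval_auc(sel, clf, X, y, folds = 5, replications = 5, seed = 2)
  expect_gt(r0$mean_auc, 0.38); expect_lt(r0$mean_auc, 0.62)
  ys <- rbinom(n, 1, plogis(3 * X[, 1]))
  r1 <- crossval_auc(sel, clf, X, ys, folds = 5, replications = 5, seed = 2)
  expect_gt(r1$mean_auc, 0.8)
  expect_length(r0$auc, 5L)
  expect_true(r0$ci[1] <= r0$mean_auc && r0$mean_auc <= r0$ci[2])
})

test_that("a test-fold-only label leak cannot inflate the pipeline AUC", {
  set.seed(5)
  n <- 150
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(n, 1, 0.5)
  # canary: equals the label exactly on one fifth of rows (a "test fold"),
  # noise elsewhere; a leak-free pipeline must not benefit from it
  canary <- rnorm(n)
  canary[1:30] <- y[1:30]
  Xc <- cbind(X, canary = canary)
  sel <- default_selector_registry()[["pearson_top10"]]
  clf <- default_classifier_registry()[["logistic"]]
  r <- crossval_auc(sel, clf, Xc, y, folds = 5, replications = 5, seed = 3)
  expect_lt(r$mean_auc, 0.65)
})

test_that("a 1x1 grid reproduces the direct cross-validation of that pair", {
  set.seed(6)
  X <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rbinom(80, 1, plogis(X[, 1]))
  sel <- default_selector_registry()["variance_top10"]
  clf <- default_classifier_registry()["lda"]
  g <- run_grid(X, y, sel, clf, folds = 4, replications = 3, seed = 9)
  direct <- crossval_auc(sel[[1]], clf[[1]], X, y, folds = 4, replications = 3,
                         seed = 9)
  expect_equal(g$best$mean_auc, direct$mean_auc, tolerance = 1e-12)
  expect_identical(nrow(g$grid), 1L)
})

test_that("grid optimisation finds separable structure but not permuted labels", {
  set.seed(7)
  n <- 200
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- as.integer(X[, 1] + X[, 2] > 0)  # separable by construction
  sel <- default_selector_registry()[c("ttest_top10", "pearson_top10")]
  clf <- default_classifier_registry()[c("lda", "svm_linear_c1")]
  g <- run_grid(X, y, sel, clf, folds = 4, replications = 2, seed = 4)
  expect_gte(g$best$mean_auc, 0.95)
  expect_identical(nrow(g$grid), 4L)
  expect_equal(g$best$mean_auc, max(g$grid$mean_auc))
  yperm <- sample(y)
  g0 <- run_grid(X, yperm, sel, clf, folds = 4, replications = 2, seed = 4)
  # selection-bias ceiling over a small grid on null labels
  expect_lte(g0$best$mean_auc, 0.68)
})

test_that("confusion metrics follow their definitions", {
  cm <- confusion_metrics(c(rep(1, 16), rep(0, 53)),
                          c(rep(1, 12), rep(0, 4), rep(1, 5), rep(0, 48)))
  expect_equal(cm$accuracy, 60 / 69, tolerance = 1e-12)
  expect_equal(cm$sensitivity, 12 / 17, tolerance = 1e-12)
  expect_equal(cm$specificity, 48 / 52, tolerance = 1e-12)
  all_good <- confusion_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_identical(all_good$accuracy, 1)
  all_neg <- confusion_metrics(rep(0, 5), c(1, 1, 0, 0, 0))
  expect_identical(all_neg$sensitivity, 0)
  expect_identical(all_neg$specificity, 1)
})

test_that("propensity matching balances confounded covariates with equal arms", {
  set.seed(8)
  n <- 400
  cov6 <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, default_psm_covariates()))
  y <- rbinom(n, 1, plogis(0.8 * cov6[, 1] - 0.6 * cov6[, 2] - 1.2))
  cov6[, 1] <- cov6[, 1] + 0.3 * y  # extra direct imbalance
  pm <- psm_match(cov6, y)
  expect_identical(sum(y[pm$matched_idx] == 1), sum(y[pm$matched_idx] == 0))
  expect_gt(max(abs(pm$smd$smd_before)), 0.3)
  expect_lt(max(abs(pm$smd$smd_after)), 0.2)
  # disjoint supports with a tight caliper: empty set, warned
  cov_bad <- cov6; cov_bad[, 1] <- ifelse(y == 1, 100 + rnorm(n), -100 + rnorm(n))
  expect_warning(pm2 <- psm_match(cov_bad, y, caliper = 0.001), "empty")
  expect_length(pm2$matched_idx, 0L)
})

test_that("the embedding separates planted clusters and is reproducible", {
  skip_if_not_installed("cluster")
  set.seed(9)
  X <- rbind(matrix(rnorm(40 * 5), 40, 5), matrix(rnorm(40 * 5, mean = 10), 40, 5))
  Y <- embed_features(X, perplexity = 10, seed = 2)
  expect_identical(dim(Y), c(80L, 2L))
  sil <- mean(cluster::silhouette(rep(1:2, each = 40), dist(Y))[, 3])
  expect_gt(sil, 0.5)
  expect_identical(Y, embed_features(X, perplexity = 10, seed = 2))
  expect_error(embed_features(X[1:10, ], perplexity = 10), "samples")
})

test_that("interval groups follow the [lower, upper) day convention", {
  g <- suppressMessages(group_by_interval(c(30, 91, 400, 20, 91 - 1, 365, 729, 730)))
  expect_identical(as.character(g),
                   c("A", "B", "C", NA, "A", "C", "C", NA))
})
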