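#' Area under the ROC curve
#'
#' Thin wrapper over `pROC` with a fixed score orientation (higher score =
#' positive class), so chance-level scores are not optimistically flipped.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(response = factor(labels, levels = c(0, 1)),
                                 predictor = as.numeric(scores),
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  f
}

#' Repeated stratified cross-validated AUC of a selector/classifier pair
#'
#' For each replication, a fresh stratified k-fold split is drawn; inside
#' every training fold the table is min-max normalised (ranges fitted on the
#' training rows only), the selector is fitted, and the classifier is trained
#' on the selected features — the held-out fold only ever passes through the
#' fitted transforms, so no information leaks. Per-replication AUC pools the
#' held-out scores over the folds; the confidence interval is the percentile
#' interval over replications.
#'
#' @param selector a selector registry entry (or `NULL` for no selection).
#' @param classifier a classifier registry entry.
#' @param table numeric matrix, samples x features.
#' @param labels binary 0/1 vector.
#' @param folds stratified folds (default 5).
#' @param replications independent repetitions (default 40).
#' @param seed master seed; all fold draws derive from it.
#' @param ci confidence level of the percentile interval.
#' @return object of class `evaluation_report`: `auc` (per replication),
#'   `mean_auc`, `ci`, `roc` (pooled ROC points of the first replication),
#'   `confusion` ([confusion_metrics()] of the first replication at 0.5),
#'   `n_selected` (mean selected-feature count).
#' @export
crossval_auc <- function(selector, classifier, table, labels, folds = 5,
                         replications = 40, seed = 1L, ci = 0.95) {
  x <- as.matrix(table)
  y <- as.integer(labels)
  if (folds < 2) stop("crossval_auc: folds must be >= 2")
  if (min(table(y)) < folds)
    stop("crossval_auc: a class has fewer members than folds")
  aucs <- numeric(replications)
  nsel <- numeric(replications)
  first_scores <- NULL
  for (r in seq_len(replications)) {
    fid <- stratified_folds(y, folds, derive_seed(seed, 1000L + r))
    scores <- numeric(length(y))
    nsel_f <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fid != k; te <- fid == k
      nrm <- suppressWarnings(minmax_normalize(x[tr, , drop = FALSE]))
      xtr <- nrm$values
      xte <- minmax_apply(nrm, x[te, , drop = FALSE])
      feats <- colnames(x)
      if (!is.null(selector)) {
        feats <- selector$select(xtr, y[tr], seed = derive_seed(seed, r * 100L + k))
        feats <- intersect(feats, colnames(x))
        if (!length(feats)) feats <- colnames(x)[1]
      }
      fit <- classifier$fit(xtr[, feats, drop = FALSE], y[tr])
      scores[te] <- classifier$predict(fit, xte[, feats, drop = FALSE])
      nsel_f[k] <- length(feats)
    }
    aucs[r] <- roc_auc(scores, y)
    nsel[r] <- mean(nsel_f)
    if (r == 1) first_scores <- scores
  }
  a <- (1 - ci) / 2
  roc1 <- pROC::roc(response = factor(y, levels = c(0, 1)),
                    predictor = first_scores, levels = c("0", "1"),
                    direction = "<", quiet = TRUE)
  structure(list(auc = aucs, mean_auc = mean(aucs),
                 ci = stats::quantile(aucs, c(a, 1 - a), names = FALSE),
                 roc = data.frame(fpr = 1 - roc1$specificities,
                                  tpr = roc1$sensitivities),
                 confusion = confusion_metrics(first_scores, y),
                 n_selected = mean(nsel)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("cross-validated AUC %.3f (CI %.3f-%.3f, %d replications), %.1f features\n",
              x$mean_auc, x$ci[1], x$ci[2], length(x$auc), x$n_selected))
  invisible(x)
}

#' Evaluate a selector x classifier grid by repeated cross-validated AUC
#'
#' Every combination is scored with [crossval_auc()] under a shared master
#' seed (the same fold draws for all cells); the best cell is the one with
#' the highest mean AUC. A crashing combination is recorded as a missing
#' cell, not a global failure.
#'
#' @param table,labels data as in [crossval_auc()].
#' @param selectors,classifiers registries (defaults enumerate 45 x 32).
#' @param folds,replications,seed cross-validation settings.
#' @param verbose print progress.
#' @return object of class `grid_result`: `grid` (data frame selector,
#'   classifier, mean_auc, ci_lo, ci_hi, n_selected), `best` (row of the best
#'   cell), `reports` (named list of `evaluation_report`s).
#' @export
run_grid <- function(table, labels, selectors = default_selector_registry(),
                     classifiers = default_classifier_registry(), folds = 5,
                     replications = 5, seed = 1L, verbose = FALSE) {
  combos <- enumerate_grid(selectors, classifiers)
  rows <- vector("list", nrow(combos))
  reports <- list()
  for (i in seq_len(nrow(combos))) {
    sel_nm <- combos$selector[i]; clf_nm <- combos$classifier[i]
    rep_i <- try(crossval_auc(selectors[[sel_nm]], classifiers[[clf_nm]],
                              table, labels, folds = folds,
                              replications = replications, seed = seed),
                 silent = TRUE)
    if (inherits(rep_i, "try-error")) {
      rows[[i]] <- data.frame(selector = sel_nm, classifier = clf_nm,
                              mean_auc = NA_real_, ci_lo = NA_real_,
                              ci_hi = NA_real_, n_selected = NA_real_)
    } else {
      rows[[i]] <- data.frame(selector = sel_nm, classifier = clf_nm,
                              mean_auc = rep_i$mean_auc, ci_lo = rep_i$ci[1],
                              ci_hi = rep_i$ci[2], n_selected = rep_i$n_selected)
      reports[[paste(sel_nm, clf_nm, sep = "|")]] <- rep_i
    }
    if (verbose)
      message(sprintf("[%d/%d] %s x %s: AUC %.3f", i, nrow(combos), sel_nm,
                      clf_nm, rows[[i]]$mean_auc))
  }
  grid <- do.call(rbind, rows)
  best <- grid[which.max(grid$mean_auc), , drop = FALSE]
  structure(list(grid = grid, best = best, reports = reports),
            class = "grid_result")
}

#' Confusion-matrix metrics at a score threshold
#'
#' @param predictions numeric scores (or 0/1 predictions).
#' @param labels binary 0/1 vector.
#' @param threshold score cut (default 0.5); `"youden"` picks the
#'   Youden-optimal cut on the ROC curve.
#' @return list: `matrix` (2 x 2, predicted x actual), `accuracy`,
#'   `sensitivity` (TP/(TP+FN)), `specificity` (TN/(TN+FP)), `threshold`.
#'   Metrics undefined through an empty class are `NaN` with a warning.
#' @export
confusion_metrics <- function(predictions, labels, threshold = 0.5) {
  y <- as.integer(labels)
  if (identical(threshold, "youden")) {
    r <- pROC::roc(response = factor(y, levels = c(0, 1)),
                   predictor = as.numeric(predictions), levels = c("0", "1"),
                   direction = "<", quiet = TRUE)
    threshold <- as.numeric(pROC::coords(r, "best", ret = "threshold",
                                         best.method = "youden")[1, 1])
  }
  pred <- as.integer(as.numeric(predictions) >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  if (tp + fn == 0 || tn + fp == 0)
    warning("confusion_metrics: a class is empty; some metrics are undefined")
  m <- matrix(c(tp, fp, fn, tn), 2, 2,
              dimnames = list(predicted = c("1", "0"), actual = c("1", "0")))
  list(matrix = m,
       accuracy = (tp + tn) / length(y),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       threshold = threshold)
}

#' Assign follow-up interval subgroups
#'
#' Groups subjects by the scan interval with boundary convention
#' `[lower, upper)` in days: A = [21, 91) (three weeks to three months),
#' B = [91, 365) (three months to a year), C = [365, 730) (one to two
#' years). Intervals outside all groups give `NA` (excluded with a message).
#'
#' @param interval_days numeric vector of follow-up intervals in days, or a
#'   manifest data frame with `t_baseline_days` / `t_followup_days` (or an
#'   `interval_days`) column.
#' @return factor with levels A, B, C (NA = outside all groups).
#' @export
group_by_interval <- function(interval_days) {
  if (is.data.frame(interval_days)) {
    interval_days <- if ("interval_days" %in% names(interval_days))
      interval_days$interval_days
    else interval_days$t_followup_days - interval_days$t_baseline_days
  }
  g <- cut(interval_days, breaks = c(21, 91, 365, 730), right = FALSE,
           labels = c("A", "B", "C"))
  if (anyNA(g))
    message(sum(is.na(g)), " subject(s) outside all interval groups excluded")
  g
}
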