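#' ReliefF feature weights
#'
#' Standard ReliefF for binary outcomes: for every sample, the K nearest
#' same-class neighbours (hits) decrease and the K nearest other-class
#' neighbours (misses) increase each feature's weight by its range-normalised
#' value difference, averaged over samples and neighbours. Distances are
#' Manhattan on range-normalised features.
#'
#' @param table numeric matrix, samples x features.
#' @param labels binary 0/1 vector.
#' @param K neighbours per class (default 10, the usual setting).
#' @return named numeric vector of weights (descending order = ranking).
#' @export
relieff_rank <- function(table, labels, K = 10) {
  x <- as.matrix(table)
  y <- as.integer(labels)
  n <- nrow(x)
  cls <- table(y)
  if (K >= min(cls)) stop("relieff_rank: K must be below the smallest class size")
  rng <- apply(x, 2, function(v) {
    r <- max(v) - min(v)
    if (r == 0) 1 else r
  })
  xn <- sweep(sweep(x, 2, apply(x, 2, min), `-`), 2, rng, `/`)
  D <- as.matrix(stats::dist(xn, method = "manhattan"))
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    hits <- order(d + ifelse(y == y[i], 0, Inf))[seq_len(K)]
    miss <- order(d + ifelse(y != y[i], 0, Inf))[seq_len(K)]
    dh <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ], `-`))
    dm <- abs(sweep(xn[miss, , drop = FALSE], 2, xn[i, ], `-`))
    w <- w - colSums(dh) / (n * K) + colSums(dm) / (n * K)
  }
  stats::setNames(w, colnames(x))
}

#' LASSO / elastic-net feature selection at the minimum cross-validated error
#'
#' Fits a penalised logistic model over the regularisation path
#' (`glmnet`, mixing parameter `alpha`; 0.5 gives an L1-dominant elastic
#' net), picks the penalty at the minimum cross-validated error
#' (the "MSE_min" rule; `rule = "1se"` gives the parsimonious alternative)
#' and returns the features with nonzero coefficients plus the trajectory
#' data for plotting.
#'
#' @param table numeric matrix (normalised), samples x features.
#' @param labels binary 0/1 vector.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param cv_folds cross-validation folds for the penalty choice.
#' @param rule `"min"` (default) or `"1se"`.
#' @param seed fold-assignment seed.
#' @return list: `selected` (feature names), `coefficients` (named nonzero
#'   coefficients), `lambda`, `trajectory` (data frame lambda, cvm, nonzero),
#'   `path` (the glmnet fit, for coefficient trajectories).
#' @export
lasso_select <- function(table, labels, alpha = 0.5, cv_folds = 10, rule = "min",
                         seed = 1L) {
  x <- as.matrix(table)
  y <- as.integer(labels)
  set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          type.measure = "mse", foldid = foldid)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  co <- as.matrix(coef(cv$glmnet.fit, s = lam))[-1, 1]
  sel <- names(co)[co != 0]
  if (!length(sel))
    stop("lasso_select: the selected penalty zeroes every coefficient")
  list(selected = sel, coefficients = co[co != 0], lambda = lam,
       trajectory = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                               nonzero = cv$nzero),
       path = cv$glmnet.fit)
}

# ---- internal univariate scorers (larger = more relevant) ----

score_ttest <- function(x, y) abs(vapply(seq_len(ncol(x)), function(j) {
  v <- x[, j]
  if (stats::sd(v) == 0) return(0)
  tryCatch(unname(stats::t.test(v[y == 1], v[y == 0])$statistic),
           error = function(e) 0)
}, numeric(1)))

score_wilcoxon <- function(x, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    u <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
    abs(u / (n1 * n0) - 0.5)
  }, numeric(1))
}

score_aucrank <- function(x, y) {
  vapply(seq_len(ncol(x)), function(j) abs(fast_auc(x[, j], y) - 0.5), numeric(1))
}

score_fisher <- function(x, y) {
  m1 <- colMeans(x[y == 1, , drop = FALSE]); m0 <- colMeans(x[y == 0, , drop = FALSE])
  v1 <- apply(x[y == 1, , drop = FALSE], 2, var); v0 <- apply(x[y == 0, , drop = FALSE], 2, var)
  (m1 - m0)^2 / pmax(v1 + v0, 1e-12)
}

score_mutinfo <- function(x, y, bins = 8L) {
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    br <- unique(stats::quantile(v, seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(0)
    b <- cut(v, br, include.lowest = TRUE, labels = FALSE)
    jt <- table(b, y) / length(v)
    px <- rowSums(jt); py <- colSums(jt)
    nz <- jt > 0
    sum(jt[nz] * log(jt[nz] / (outer(px, py)[nz])))
  }, numeric(1))
}

score_kruskal <- function(x, y) {
  vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) == 0) return(0)
    tryCatch(unname(stats::kruskal.test(x[, j], factor(y))$statistic),
             error = function(e) 0)
  }, numeric(1))
}

# rank-based Mann-Whitney AUC (ties handled by midranks)
fast_auc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
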