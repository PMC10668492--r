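#' Default shape/first-order covariates for propensity-score matching
#'
#' Six shape or first-order features (volume, surface area, sphericity,
#' maximum 3-D diameter, mean intensity, intensity entropy) — a documented
#' stand-in choice for covariate balancing of nodule morphology.
#'
#' @param prefix block prefix to prepend (e.g. `"classic_intra."`).
#' @return character vector of six feature names.
#' @export
default_psm_covariates <- function(prefix = "") {
  paste0(prefix, c("original_shape_VoxelVolume", "original_shape_SurfaceArea",
                   "original_shape_Sphericity", "original_shape_Maximum3DDiameter",
                   "original_firstorder_Mean", "original_firstorder_Entropy"))
}

#' Propensity-score matching of the two label groups
#'
#' Fits a logistic propensity model on the chosen covariates and performs 1:1
#' greedy nearest-neighbour matching without replacement on the propensity
#' logit, within a caliper of `caliper` standard deviations of the logit.
#' Group sizes in the matched set are equal by construction; standardised
#' mean differences before/after matching are reported.
#'
#' @param table numeric matrix or data frame containing the covariates.
#' @param labels binary 0/1 vector (1 = minority/treated group by
#'   convention, but either orientation works).
#' @param covariate_names columns used in the propensity model (default: the
#'   six shape/first-order features of [default_psm_covariates()]).
#' @param caliper caliper width in SD of the logit (default 0.2).
#' @return list of class `psm_result`: `matched_idx` (integer indices of the
#'   matched rows, both groups), `pairs` (data frame treated/control index),
#'   `smd` (data frame covariate, smd_before, smd_after), `logit`.
#' @export
psm_match <- function(table, labels, covariate_names = default_psm_covariates(),
                      caliper = 0.2) {
  x <- as.data.frame(table)
  if (!all(covariate_names %in% colnames(x)))
    stop("psm_match: missing covariates: ",
         paste(setdiff(covariate_names, colnames(x)), collapse = ", "))
  y <- as.integer(labels)
  if (!all(c(0, 1) %in% y)) stop("psm_match: both classes must be nonempty")
  cv <- scale(as.matrix(x[, covariate_names, drop = FALSE]))
  cv[is.nan(cv)] <- 0
  df <- as.data.frame(cv)
  names(df) <- paste0("v", seq_along(covariate_names))
  # separation (perfectly predictive covariates) is handled downstream via
  # the caliper, so convergence chatter from glm is silenced here
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                     family = stats::binomial()))
  p <- pmin(pmax(stats::fitted(fit), 1e-8), 1 - 1e-8)
  logit <- stats::qlogis(p)
  cal <- caliper * stats::sd(logit)
  treated <- which(y == 1); control <- which(y == 0)
  if (length(treated) > length(control)) { tmp <- treated; treated <- control; control <- tmp }
  avail <- rep(TRUE, length(logit))
  pairs <- list()
  for (i in treated[order(-logit[treated])]) {
    cand <- control[avail[control]]
    if (!length(cand)) break
    d <- abs(logit[cand] - logit[i])
    j <- cand[which.min(d)]
    if (min(d) <= cal) {
      pairs[[length(pairs) + 1]] <- c(i, j)
      avail[j] <- FALSE
    }
  }
  if (!length(pairs)) {
    warning("psm_match: no pairs within the caliper; matched set is empty")
    matched <- integer(0)
    pr <- data.frame(treated = integer(0), control = integer(0))
  } else {
    pr <- as.data.frame(do.call(rbind, pairs))
    names(pr) <- c("treated", "control")
    matched <- sort(c(pr$treated, pr$control))
  }
  smd <- function(idx) vapply(covariate_names, function(cn) {
    a <- x[intersect(idx, which(y == 1)), cn]; b <- x[intersect(idx, which(y == 0)), cn]
    if (!length(a) || !length(b)) return(NA_real_)
    den <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (!is.finite(den) || den == 0) return(0)
    (mean(a) - mean(b)) / den
  }, numeric(1))
  structure(list(matched_idx = matched, pairs = pr,
                 smd = data.frame(covariate = covariate_names,
                                  smd_before = smd(seq_along(y)),
                                  smd_after = smd(matched), row.names = NULL),
                 logit = logit),
            class = "psm_result")
}

#' 2-D embedding of a feature table (exact t-SNE)
#'
#' Unsupervised t-distributed stochastic neighbour embedding (exact
#' pairwise implementation, suitable for cohort-scale n) used to visualise
#' how feature sets separate the two classes. Deterministic for a fixed seed.
#'
#' @param table numeric matrix, samples x features.
#' @param perplexity neighbourhood size (requires `n >= 3 * perplexity + 1`).
#' @param seed RNG seed for the initial layout.
#' @param n_iter gradient-descent iterations.
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_features <- function(table, perplexity = 10, seed = 1L, n_iter = 400) {
  x <- as.matrix(table)
  n <- nrow(x)
  if (n < 3 * perplexity + 1)
    stop("embed_features: need at least 3 * perplexity + 1 samples")
  D2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  logu <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { h <- 0; p <- p * 0 } else {
        p <- p / sump
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - logu) < 1e-5) break
      if (h > logu) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  vel <- Y * 0
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    vel <- mom * vel - 100 * grad
    Y <- Y + vel
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
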