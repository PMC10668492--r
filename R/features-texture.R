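# Texture-feature formulas evaluated on matrices built by the C++ kernels.
# Conventions: co-occurrence aggregated (summed) over all 26 angles before
# feature computation; run-length matrices summed over the 13 unique
# directions; zones are 26-connected; gray levels are 1..Ng after fixed
# bin-width discretisation. Degenerate regions (a single gray level) yield
# the analytic limits (e.g. contrast 0, correlation 1).

.eps <- 2.2e-16

glcm_feature_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MCC", "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

compute_glcm_features <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  out <- stats::setNames(numeric(24), glcm_feature_names)
  if (tot == 0 || ng == 0) { out["Correlation"] <- 1; out["Imc2"] <- 0; out["MCC"] <- 1; return(out) }
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px)); sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal and cross-diagonal marginals
  k_diff <- 0:(ng - 1)
  pxmy <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxpy <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  hx <- -sum(px * log2(px + .eps)); hy <- -sum(py * log2(py + .eps))
  hxy <- -sum(p * log2(p + .eps))
  pxy_outer <- outer(px, py)
  hxy1 <- -sum(p * log2(pxy_outer + .eps))
  hxy2 <- -sum(pxy_outer * log2(pxy_outer + .eps))
  da <- sum(k_diff * pxmy)
  out["Autocorrelation"] <- sum(i * j * p)
  out["ClusterProminence"] <- sum((i + j - mux - muy)^4 * p)
  out["ClusterShade"] <- sum((i + j - mux - muy)^3 * p)
  out["ClusterTendency"] <- sum((i + j - mux - muy)^2 * p)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Correlation"] <- if (sdx * sdy > 0) (sum(i * j * p) - mux * muy) / (sdx * sdy) else 1
  out["DifferenceAverage"] <- da
  out["DifferenceEntropy"] <- -sum(pxmy * log2(pxmy + .eps))
  out["DifferenceVariance"] <- sum((k_diff - da)^2 * pxmy)
  out["Id"] <- sum(pxmy / (1 + k_diff))
  out["Idm"] <- sum(pxmy / (1 + k_diff^2))
  out["Idmn"] <- sum(pxmy / (1 + k_diff^2 / ng^2))
  out["Idn"] <- sum(pxmy / (1 + k_diff / ng))
  out["Imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  out["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out["InverseVariance"] <- if (ng > 1) sum(pxmy[-1] / k_diff[-1]^2) else 0
  out["JointAverage"] <- mux
  out["JointEnergy"] <- sum(p^2)
  out["JointEntropy"] <- hxy
  out["MCC"] <- glcm_mcc(p, px, py)
  out["MaximumProbability"] <- max(p)
  out["SumAverage"] <- sum(k_sum * pxpy)
  out["SumEntropy"] <- -sum(pxpy * log2(pxpy + .eps))
  out["SumSquares"] <- sum((i - mux)^2 * p)
  out
}

glcm_mcc <- function(p, px, py) {
  ng <- nrow(p)
  if (ng < 2) return(1)
  keep <- px > 0 & py > 0
  if (sum(keep) < 2) return(1)
  pk <- p[keep, keep, drop = FALSE]
  pxk <- px[keep]; pyk <- py[keep]
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
  w <- sweep(pk, 2, pyk, `/`)
  q <- sweep(pk %*% t(w), 1, pxk, `/`)
  ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2) return(1)
  sqrt(max(0, min(ev[2], 1)))
}

glrlm_feature_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

# shared formulas for run-length-style matrices (rows = gray level, cols =
# run length / zone size); np = number of voxels in the region
rl_style_features <- function(M, np, names_out) {
  nr <- sum(M)
  out <- stats::setNames(numeric(16), names_out)
  if (nr == 0) return(out)
  p <- M / nr
  i <- row(p); j <- col(p)
  ri <- rowSums(M); rj <- colSums(M)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pn <- p[p > 0]
  vals <- c(
    sum(ri^2) / nr,            # gray-level non-uniformity
    sum(ri^2) / nr^2,          # ... normalised
    sum((i - mu_i)^2 * p),     # gray-level variance
    sum(p * i^2),              # high gray-level emphasis
    sum(p * j^2),              # long-run / large-area emphasis
    sum(p * i^2 * j^2),
    sum(p * j^2 / i^2),
    sum(p / i^2),
    -sum(pn * log2(pn)),       # entropy
    sum(rj^2) / nr,            # run-length / size-zone non-uniformity
    sum(rj^2) / nr^2,
    nr / np,                   # run / zone percentage
    sum((j - mu_j)^2 * p),
    sum(p / j^2),              # short-run / small-area emphasis
    sum(p * i^2 / j^2),
    sum(p / (i^2 * j^2))
  )
  ord <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16)
  stats::setNames(vals[ord], names_out)
}

compute_glrlm_features <- function(R, np) {
  rl_style_features(R, np, glrlm_feature_names)
}

glszm_feature_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "ZoneEntropy", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "ZoneVariance",
  "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "SmallAreaLowGrayLevelEmphasis")

compute_glszm_features <- function(S, np) {
  rl_style_features(S, np, glszm_feature_names)
}

gldm_feature_names <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

compute_gldm_features <- function(D) {
  # columns index dependence 0..26; use j = dependence + 1 in the emphases
  nz <- sum(D)
  out <- stats::setNames(numeric(14), gldm_feature_names)
  if (nz == 0) return(out)
  p <- D / nz
  i <- row(p); j <- col(p)  # j already = dependence + 1
  di <- rowSums(D); dj <- colSums(D)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pn <- p[p > 0]
  out["DependenceEntropy"] <- -sum(pn * log2(pn))
  out["DependenceNonUniformity"] <- sum(dj^2) / nz
  out["DependenceNonUniformityNormalized"] <- sum(dj^2) / nz^2
  out["DependenceVariance"] <- sum((j - mu_j)^2 * p)
  out["GrayLevelNonUniformity"] <- sum(di^2) / nz
  out["GrayLevelVariance"] <- sum((i - mu_i)^2 * p)
  out["HighGrayLevelEmphasis"] <- sum(p * i^2)
  out["LargeDependenceEmphasis"] <- sum(p * j^2)
  out["LargeDependenceHighGrayLevelEmphasis"] <- sum(p * i^2 * j^2)
  out["LargeDependenceLowGrayLevelEmphasis"] <- sum(p * j^2 / i^2)
  out["LowGrayLevelEmphasis"] <- sum(p / i^2)
  out["SmallDependenceEmphasis"] <- sum(p / j^2)
  out["SmallDependenceHighGrayLevelEmphasis"] <- sum(p * i^2 / j^2)
  out["SmallDependenceLowGrayLevelEmphasis"] <- sum(p / (i^2 * j^2))
  out
}

ngtdm_feature_names <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")

compute_ngtdm_features <- function(M) {
  out <- stats::setNames(numeric(5), ngtdm_feature_names)
  n_i <- M[, 1]; s_i <- M[, 2]
  N <- sum(n_i)
  if (N == 0) return(out)
  p_i <- n_i / N
  lev <- seq_along(p_i)
  act <- p_i > 0
  ngp <- sum(act)
  ps <- sum(p_i * s_i)
  out["Coarseness"] <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  if (ngp > 1) {
    ii <- lev[act]; pp <- p_i[act]; ss <- s_i[act]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    out["Contrast"] <- sum(outer(pp, pp) * dif2) / (ngp * (ngp - 1)) * sum(s_i) / N
    denom <- sum(abs(outer(ii * pp, ii * pp, `-`)))
    out["Busyness"] <- if (denom > 0) ps / denom else 0
    pij_sum <- outer(pp, pp, `+`)
    out["Complexity"] <- sum(abs(outer(ii, ii, `-`)) *
                               (outer(pp * ss, pp * ss, `+`)) / pij_sum) / N
    if (sum(s_i) > 0)
      out["Strength"] <- sum(pij_sum * dif2) / sum(s_i)
  }
  out
}
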