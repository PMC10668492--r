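# First-order (intensity-histogram) statistics of a region. Entropy and
# Uniformity use the same fixed-bin-width discretisation as the texture
# matrices; all other statistics act on raw intensities.

firstorder_feature_names <- c(
  "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
  "Kurtosis", "Maximum", "MeanAbsoluteDeviation", "Mean", "Median",
  "Minimum", "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "TotalEnergy", "Uniformity", "Variance")

compute_firstorder_features <- function(values, disc, voxel_volume) {
  x <- values
  n <- length(x)
  stopifnot(n > 0)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- tabulate(disc) / n
  p <- p[p > 0]
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[5]]
  vals <- c(
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    InterquartileRange = q[4] - q[2],
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Mean = mu,
    Median = q[3],
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation = if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = voxel_volume * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2
  )
  vals[firstorder_feature_names]
}
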