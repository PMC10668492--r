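# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a quiet noiseless pair: zero growth, zero motion, zero noise, fixed texture
quiet_pair <- function() fixture("quiet_pair", function() {
  spec <- phantom_spec(growth_rates_per_day = c(0, 0, 0), texture_sd_hu = 25,
                       noise_sd_hu = 0, interval_days = 60, seed = 7)
  generate_pair(spec, label = 0)
})

# a moving, growing, noisy pair
active_pair <- function() fixture("active_pair", function() {
  spec <- phantom_spec(radii_mm = c(5, 6, 4.5),
                       growth_rates_per_day = c(0.004, 0.001, 0.002),
                       texture_sd_hu = 30, noise_sd_hu = 5, interval_days = 120,
                       motion = list(translation_mm = c(2, -1.5, 1),
                                     rotation_deg = c(0, 0, 0)),
                       seed = 21)
  generate_pair(spec, label = 1)
})

# a small feature vector extracted once (wavelet on): 851 entries
small_features <- function() fixture("small_features", function() {
  p <- active_pair()
  extract_features(p$followup_volume, region_mask(p$followup_mask, p$spacing_mm))
})

# smooth random image for registration tests (structure at blob scale)
smooth_image <- function(n = 72, seed = 2) {
  set.seed(seed)
  img <- matrix(rnorm(n * n), n, n)
  k <- outer(exp(-(-4:4)^2 / 8), exp(-(-4:4)^2 / 8))
  dualdelta:::conv2_valid(img, k / sum(k))
}

# blocky corner-rich image for keypoint tests
blocky_image <- function(n = 90, seed = 4) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (i in 1:25) {
    r <- sample(10:(n - 15), 1); cc <- sample(10:(n - 15), 1)
    img[r:(r + sample(4:9, 1)), cc:(cc + sample(4:9, 1))] <- runif(1, 0.3, 1)
  }
  img
}

# bright-rim vs flat synthetic delta images (separable by construction)
rim_image <- function(pos, size = 64L) {
  img <- matrix(runif(size * size, 0, 0.3), size, size)
  if (pos) {
    cx <- runif(1, size * 0.35, size * 0.65)
    cy <- runif(1, size * 0.35, size * 0.65)
    d <- sqrt(outer((seq_len(size) - cx)^2, rep(1, size)) +
                outer(rep(1, size), (seq_len(size) - cy)^2))
    sel <- d > size / 8 & d < size / 5
    img[sel] <- img[sel] + 0.6
  }
  pmin(img, 1)
}
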