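#' Structural similarity index between two images
#'
#' Mean SSIM with a Gaussian weighting window evaluated at all fully-valid
#' window positions (no boundary padding). The dynamic range defaults to the
#' joint intensity range of the two images; a constant pair of images scores
#' 1 by convention.
#'
#' @param a,b numeric matrices of identical shape.
#' @param window odd window side (default 11; shrunk to fit small images).
#' @param sigma Gaussian window standard deviation in pixels.
#' @param k1,k2 stabilisation constants (standard 0.01 / 0.03).
#' @param dynamic_range intensity range L; default `max(a,b) - min(a,b)`.
#' @return scalar SSIM in [-1, 1].
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 dynamic_range = NULL) {
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  if (is.null(dynamic_range)) dynamic_range <- max(a, b) - min(a, b)
  if (dynamic_range == 0) return(1)
  w <- min(window, dim(a))
  if (w %% 2 == 0) w <- w - 1L
  if (w < 1) return(1)
  g <- exp(-((seq_len(w) - (w + 1) / 2)^2) / (2 * sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  f <- function(x) conv2_valid(x, kern)
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(smap)
}

# 2-D "valid" convolution (really correlation; kernels used are symmetric)
conv2_valid <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  nr <- nrow(img) - kr + 1L; nc <- ncol(img) - kc + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr))
    for (j in seq_len(kc))
      out <- out + kern[i, j] * img[i:(i + nr - 1L), j:(j + nc - 1L)]
  out
}
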