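`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trilinear interpolation of a 3-D array at arbitrary voxel coordinates
#'
#' Coordinates are in voxel units (1-based, matching R array indexing).
#' Points outside the grid are clamped to the boundary.
#'
#' @param arr 3-D numeric array.
#' @param x,y,z numeric vectors of equal length, voxel coordinates.
#' @return numeric vector of interpolated values.
#' @keywords internal
trilinear <- function(arr, x, y, z) {
  d <- dim(arr)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2]); z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L); z0 <- pmin(floor(z), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ix <- function(a, b, cc) arr[cbind(a, b, cc)]
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  c000 <- ix(x0, y0, z0); c100 <- ix(x1, y0, z0)
  c010 <- ix(x0, y1, z0); c110 <- ix(x1, y1, z0)
  c001 <- ix(x0, y0, z1); c101 <- ix(x1, y0, z1)
  c011 <- ix(x0, y1, z1); c111 <- ix(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Bilinear interpolation of a matrix at arbitrary (row, col) coordinates
#' @keywords internal
bilinear <- function(img, r, cc) {
  d <- dim(img)
  r <- pmin(pmax(r, 1), d[1]); cc <- pmin(pmax(cc, 1), d[2])
  r0 <- pmin(floor(r), d[1] - 1L); c0 <- pmin(floor(cc), d[2] - 1L)
  if (d[1] == 1L) r0 <- rep(1, length(r))
  if (d[2] == 1L) c0 <- rep(1, length(cc))
  fr <- r - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, d[1]); c1 <- pmin(c0 + 1, d[2])
  v00 <- img[cbind(r0, c0)]; v10 <- img[cbind(r1, c0)]
  v01 <- img[cbind(r0, c1)]; v11 <- img[cbind(r1, c1)]
  (v00 * (1 - fr) + v10 * fr) * (1 - fc) + (v01 * (1 - fr) + v11 * fr) * fc
}

#' Resize a 2-D image by bilinear interpolation
#' @param img numeric matrix.
#' @param out_shape integer vector length 2.
#' @keywords internal
resize2d <- function(img, out_shape) {
  d <- dim(img)
  if (all(d == out_shape)) return(img)
  rr <- seq(1, d[1], length.out = out_shape[1])
  cc <- seq(1, d[2], length.out = out_shape[2])
  g <- expand.grid(r = rr, c = cc)
  matrix(bilinear(img, g$r, g$c), out_shape[1], out_shape[2])
}

#' Separable Gaussian smoothing of a 3-D array (reflective boundaries)
#' @keywords internal
gauss_smooth3d <- function(arr, sigma_vox = 1.5) {
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    n <- d[axis]
    for (j in seq_along(k)) {
      off <- j - half - 1L
      idx <- seq_len(n) + off
      idx[idx < 1] <- 1L - (idx[idx < 1] - 1L)  # reflect
      idx[idx > n] <- 2L * n - idx[idx > n] + 1L
      idx <- pmin(pmax(idx, 1L), n)
      sl <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
      out <- out + k[j] * sl
    }
    out
  }
  smooth_axis(smooth_axis(smooth_axis(arr, 1L), 2L), 3L)
}

# deterministic 32-bit sub-seed derived from a master seed and a stream index
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + as.double(stream) * 9973 + 1) %% 2147483647)
}

# md5 of a serialisable R object (config hashes in manifests)
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}
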