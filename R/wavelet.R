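#' One-level undecimated 3-D Haar wavelet decomposition
#'
#' Computes the eight low/high-pass sub-bands (LLL ... HHH) of a one-level
#' stationary (undecimated) 3-D discrete wavelet transform with Haar filters
#' and reflective boundaries. Sub-bands have the same shape as the input, so
#' region masks apply unchanged. Letter order is the filter applied along the
#' x, y, z array axes respectively.
#'
#' @param volume 3-D numeric array.
#' @return named list of eight arrays: `LLL`, `LLH`, `LHL`, `HLL`, `LHH`,
#'   `HLH`, `HHL`, `HHH`.
#' @export
wavelet_subbands <- function(volume) {
  stopifnot(length(dim(volume)) == 3)
  s2 <- sqrt(2)
  shift_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    idx <- c(seq_len(n)[-1], n)  # reflect last sample
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
  }
  lo <- function(a, axis) (a + shift_axis(a, axis)) / s2
  hi <- function(a, axis) (shift_axis(a, axis) - a) / s2
  bands <- list()
  for (fx in c("L", "H")) {
    ax <- if (fx == "L") lo(volume, 1L) else hi(volume, 1L)
    for (fy in c("L", "H")) {
      axy <- if (fy == "L") lo(ax, 2L) else hi(ax, 2L)
      for (fz in c("L", "H")) {
        b <- if (fz == "L") lo(axy, 3L) else hi(axy, 3L)
        bands[[paste0(fx, fy, fz)]] <- b
      }
    }
  }
  bands[c("LLL", "LLH", "LHL", "HLL", "LHH", "HLH", "HHL", "HHH")]
}
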