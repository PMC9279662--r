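# Single-level separable 3D Haar transform along one axis.
# Returns list(L, H) of half-size arrays (odd axis lengths are extended by
# replicating the final slice).
haar_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  idx_odd <- seq(1L, n, by = 2L)
  idx_even <- pmin(idx_odd + 1L, n)  # replicate-last extension for odd n
  slice <- function(i) {
    switch(axis,
           a[i, , , drop = FALSE],
           a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  x1 <- slice(idx_odd)
  x2 <- slice(idx_even)
  list(L = (x1 + x2) / sqrt(2), H = (x1 - x2) / sqrt(2))
}

upsample_axis <- function(a, axis, n) {
  m <- dim(a)[axis]
  idx <- rep(seq_len(m), each = 2L)[seq_len(n)]
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Single-level 3D Haar wavelet decomposition
#'
#' Decomposes a volume into the eight sub-bands LLL, LLH, LHL, LHH, HLL,
#' HLH, HHL, HHH of a one-level separable discrete wavelet transform with
#' the order-1 Daubechies (Haar) filters. Band labels give the filter per
#' axis in (x, y, z) order, so "HHL" is high-pass along x and y and low-pass
#' along z.
#'
#' With `align = TRUE` (the default) each half-resolution sub-band is
#' replicated back onto the input grid so the tumor mask can be applied
#' directly; with `align = FALSE` the decimated coefficients are returned,
#' for which the transform is orthogonal (energy-preserving) when all axis
#' lengths are even.
#'
#' @param volume 3D numeric array with every dimension >= 2.
#' @param align return sub-bands on the original grid (default) or the
#'   decimated coefficient arrays.
#' @return named list of eight 3D arrays.
#' @export
wavelet_decompose <- function(volume, align = TRUE) {
  volume <- as_array3(volume)
  if (any(dim(volume) < 2L)) abort("volume smaller than the wavelet filter")
  x <- haar_axis(volume, 1L)
  bands <- list()
  for (fx in c("L", "H")) {
    y <- haar_axis(x[[fx]], 2L)
    for (fy in c("L", "H")) {
      z <- haar_axis(y[[fy]], 3L)
      for (fz in c("L", "H")) {
        bands[[paste0(fx, fy, fz)]] <- z[[fz]]
      }
    }
  }
  order <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands <- bands[order]
  if (align) {
    n <- dim(volume)
    bands <- lapply(bands, function(b) {
      for (ax in 1:3) b <- upsample_axis(b, ax, n[ax])
      array(b, n)
    })
  }
  bands
}
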