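#' First-order (histogram) features of in-mask intensities
#'
#' The 14 first-order descriptors: min, mean, max, the nine deciles P10-P90,
#' Fisher skewness and excess kurtosis. Percentiles use linear interpolation
#' between order statistics (type 7). For a constant sample, skewness and
#' kurtosis are defined as 0.
#'
#' @param x numeric vector of in-mask voxel intensities (length >= 1).
#' @return named numeric vector of length 14.
#' @export
histogram_features <- function(x) {
  if (length(x) < 1L || anyNA(x)) abort("need >= 1 finite intensity")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  q <- quantile(x, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7)
  c(
    min = min(x), mean = m, max = max(x),
    setNames(q, paste0("p", seq(10, 90, by = 10))),
    skewness = skew, kurtosis = kurt
  )
}
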