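#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' standard mean-square decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with MSR/MSC/MSE the between-subject, between-rater, and residual mean
#' squares. Zero (or negative) between-subject variance returns 0 by
#' convention.
#'
#' @param ratings numeric matrix, subjects x raters, no missing cells.
#' @return ICC in [-1, 1].
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) abort("need >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) abort("missing cells are not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((sweep(sweep(ratings, 1, row_m), 2, col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  val <- (msr - mse) / denom
  if (!is.finite(val)) return(0)  # all-constant ratings: no subject variance
  val
}

#' Agreement category for an ICC value
#'
#' The interpretation bands: 0.81-1 almost perfect, 0.61-0.80 substantial,
#' 0.41-0.60 moderate, 0.21-0.40 fair, 0-0.20 poor (negative values fall in
#' "poor"). Values above 0.6 pass the reproducibility gate.
#'
#' @param x numeric ICC values.
#' @return character vector of categories.
#' @export
icc_category <- function(x) {
  cut(pmax(x, 0), breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
      labels = c("poor", "fair", "moderate", "substantial",
                 "almost perfect")) |>
    as.character()
}

# second-reader surrogate: threshold a smoothed mask indicator corrupted by
# smooth noise, moving the boundary by roughly jitter_mm
jitter_mask <- function(mask, jitter_mm, spacing_mm) {
  if (jitter_mm <= 0) return(mask)
  ind <- gaussian_smooth3(array(as.numeric(mask), dim(mask)), 0.7)
  eta <- gaussian_smooth3(array(rnorm(length(mask)), dim(mask)), 1.5)
  eta <- eta / max(sd(eta), 1e-12)
  out <- (ind + 0.35 * jitter_mm / mean(spacing_mm) * eta) > 0.5
  array(out, dim(mask))
}

#' Feature reproducibility under simulated re-segmentation
#'
#' Emulates a second reader by randomly perturbing each tumor boundary
#' (smooth noise added to a softened mask indicator, re-thresholded), then
#' re-runs mask erosion and feature extraction and reports the per-feature
#' ICC(2,1) between the two "readers" across the cohort. Patients whose
#' jittered, eroded mask empties are skipped and logged.
#'
#' @param studies list of raw (unpreprocessed) `mp_study` objects.
#' @param mask_jitter_mm boundary jitter magnitude in mm; 0 reproduces the
#'   original masks exactly.
#' @param seed integer seed.
#' @param g gray levels for quantization.
#' @param erosion_mm erosion margin passed to preprocessing.
#' @param icc_gate pass threshold (default 0.6).
#' @return an `agreement_report` tibble: `key`, `icc`, `category`, `pass`,
#'   with skipped patients in `attr(, "skipped")`.
#' @export
perturb_and_compare <- function(studies, mask_jitter_mm = 1.0, seed = 1L,
                                g = 64L, erosion_mm = 1.0, icc_gate = 0.6) {
  set.seed(child_seed(seed, "jitter"))
  f1 <- list(); f2 <- list(); skipped <- character(0)
  for (s in studies) {
    m2 <- jitter_mask(s$mask, mask_jitter_mm, s$spacing_mm)
    if (!any(m2)) { skipped <- c(skipped, s$patient_id); next }
    s2 <- try(mp_study(s$patient_id, s$channels, m2, s$spacing_mm),
              silent = TRUE)
    p1 <- try(preprocess_study(s, erosion_mm = erosion_mm), silent = TRUE)
    p2 <- if (inherits(s2, "try-error")) s2 else
      try(preprocess_study(s2, erosion_mm = erosion_mm), silent = TRUE)
    if (inherits(p1, "try-error") || inherits(p2, "try-error")) {
      skipped <- c(skipped, s$patient_id); next
    }
    f1[[length(f1) + 1L]] <- extract_features(p1, g = g)
    f2[[length(f2) + 1L]] <- extract_features(p2, g = g)
  }
  if (length(f1) < 2L) abort("fewer than 2 patients survived the jitter")
  m1 <- do.call(rbind, f1); m2 <- do.call(rbind, f2)
  iccs <- vapply(seq_len(ncol(m1)), function(j) {
    icc(cbind(m1[, j], m2[, j]))
  }, 0)
  out <- tibble(key = colnames(m1), icc = iccs,
                category = icc_category(iccs), pass = iccs > icc_gate)
  attr(out, "skipped") <- skipped
  class(out) <- c("agreement_report", class(out))
  out
}
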