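#' Preprocess a multiparametric study
#'
#' Applies the fixed conditioning pipeline to every channel: z-score
#' intensity normalization over the whole-volume support, trilinear
#' resampling to isotropic spacing (nearest-neighbour for the mask), and a
#' metric erosion of the tumor mask to shed boundary/partial-volume voxels.
#' Subtraction channels are expected to be formed from raw phases before
#' this step. Quantization happens later, per channel and per wavelet
#' sub-band, during feature extraction.
#'
#' @param study an [mp_study()].
#' @param target_spacing isotropic output spacing in mm (default 1).
#' @param erosion_mm mask erosion margin in mm (default 1).
#' @return a preprocessed `mp_study` (normalized channels, eroded mask).
#' @export
preprocess_study <- function(study, target_spacing = 1.0, erosion_mm = 1.0) {
  stopifnot(inherits(study, "mp_study"))
  mask <- study$mask
  spacing <- study$spacing_mm
  channels <- lapply(study$channels, znormalize)
  if (!all(abs(spacing - target_spacing) < 1e-12)) {
    res <- lapply(channels, resample_isotropic, mask = mask,
                  spacing_mm = spacing, target_spacing = target_spacing)
    channels <- lapply(res, `[[`, "volume")
    mask <- res[[1]]$mask
    spacing <- res[[1]]$spacing_mm
  }
  mask <- erode_mask(mask, margin_mm = erosion_mm, spacing_mm = spacing)
  mp_study(study$patient_id, channels, mask, spacing)
}
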