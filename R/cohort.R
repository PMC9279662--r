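#' Configuration for the synthetic multiparametric cohort
#'
#' Defines the study conditions the generator emulates: cohort size, target
#' 5-year OS prevalence, the magnitudes of the planted image effects, the
#' voxel grid and tumor size range, and the master seed.
#'
#' The three planted effects act on the non-survivor group's tumors:
#' \itemize{
#'   \item `texture_correlation_length`: extra Gaussian correlation length
#'     (voxels) of the in-tumor noise field, detectable by GLCM/GLRLM
#'     features;
#'   \item `histogram_skewness_shift`: weight of a standardized log-normal
#'     intensity component, shifting in-tumor skewness;
#'   \item `mean_intensity_shift`: additive in-tumor mean shift in units of
#'     the in-tumor noise SD.
#' }
#'
#' @param n_patients number of patients (>= 2).
#' @param os_fraction target 5-year OS prevalence, strictly in (0, 1);
#'   default 0.75 (the reference cohort's 123/165).
#' @param effect_sizes named list of planted-effect magnitudes; unknown
#'   names are rejected.
#' @param volume_shape voxel grid (length-3 integer).
#' @param voxel_spacing_mm voxel spacing in mm (all > 0).
#' @param tumor_radius_range_mm min/max tumor radius in mm; must fit inside
#'   the volume.
#' @param channels channel names to simulate.
#' @param seed master integer seed; all stochastic stages derive child seeds
#'   from it deterministically.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 165L,
                          os_fraction = 0.75,
                          effect_sizes = list(),
                          volume_shape = c(24L, 24L, 24L),
                          voxel_spacing_mm = c(1, 1, 1),
                          tumor_radius_range_mm = c(6, 9),
                          channels = default_channels(),
                          seed = 1L) {
  defaults <- list(texture_correlation_length = 0.5,
                   histogram_skewness_shift = 0.4,
                   mean_intensity_shift = 0.2)
  unknown <- setdiff(names(effect_sizes), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown effect_sizes key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  effects <- utils::modifyList(defaults, effect_sizes)
  if (n_patients < 2L) abort("`n_patients` must be >= 2")
  if (!(os_fraction > 0 && os_fraction < 1)) {
    abort("`os_fraction` must be strictly between 0 and 1")
  }
  if (any(voxel_spacing_mm <= 0)) abort("spacing entries must be > 0")
  if (length(volume_shape) != 3L || any(volume_shape < 4L)) {
    abort("`volume_shape` must be a length-3 grid, each axis >= 4")
  }
  max_r <- max(tumor_radius_range_mm)
  if (2 * max_r >= min(volume_shape * voxel_spacing_mm)) {
    abort("tumor radius exceeds volume extent")
  }
  structure(
    list(n_patients = as.integer(n_patients), os_fraction = os_fraction,
         effect_sizes = effects, volume_shape = as.integer(volume_shape),
         voxel_spacing_mm = as.numeric(voxel_spacing_mm),
         tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
         channels = channels, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Multiparametric study container
#'
#' One patient's named MRI channels on a common grid, the binary tumor
#' mask, and the voxel spacing.
#'
#' @param patient_id string identifier.
#' @param channels named list of 3D numeric arrays, all the same shape.
#' @param mask 3D logical array on the same grid; must be nonempty.
#' @param spacing_mm voxel spacing (mm), length 3.
#' @return an `mp_study` object.
#' @export
mp_study <- function(patient_id, channels, mask, spacing_mm = c(1, 1, 1)) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("`channels` must be a non-empty named list")
  }
  mask <- as_array3(mask, "mask") != 0
  for (ch in names(channels)) {
    v <- as_array3(channels[[ch]], ch)
    if (!identical(dim(v), dim(mask))) {
      abort(sprintf("channel '%s' grid does not match the mask", ch))
    }
  }
  if (!any(mask)) abort("mask is empty")
  structure(
    list(patient_id = as.character(patient_id), channels = channels,
         mask = mask, spacing_mm = as.numeric(spacing_mm)),
    class = "mp_study"
  )
}

#' @export
print.mp_study <- function(x, ...) {
  cat(sprintf(
    "<mp_study> %s: %d channels (%s), grid %s, %d mask voxels\n",
    x$patient_id, length(x$channels),
    paste(names(x$channels), collapse = ", "),
    paste(dim(x$mask), collapse = "x"), sum(x$mask)
  ))
  invisible(x)
}

#' Fixed digital phantom for texture oracles
#'
#' A deterministic 4 x 4 x 4 study with 4 gray values and an all-inclusive
#' mask, small enough that co-occurrences and runs can be enumerated by
#' hand. All 8 default channels hold the same pattern:
#' voxels with z <= 2 are 1 where x <= 2 and 2 elsewhere; voxels with
#' z >= 3 are 3 where y <= 2 and 4 elsewhere.
#'
#' @return an `mp_study`.
#' @export
digital_phantom <- function() {
  d <- c(4L, 4L, 4L)
  g <- expand.grid(x = 1:4, y = 1:4, z = 1:4)
  v <- ifelse(g$z <= 2, ifelse(g$x <= 2, 1, 2), ifelse(g$y <= 2, 3, 4))
  vol <- array(as.numeric(v), d)
  channels <- setNames(rep(list(vol), length(default_channels())),
                       default_channels())
  mp_study("phantom", channels, array(TRUE, d), c(1, 1, 1))
}
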