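#' Default MRI channel set
#'
#' The eight channels analyzed per patient: T1-weighted, T2-weighted, the
#' ADC map, three post-contrast dynamic phases (L2, L3, L4 at 15/60/120 s),
#' and two subtraction images (L3sub = L3 - L1, L4sub = L4 - L1, formed from
#' raw phases before normalization).
#'
#' @return character vector of 8 channel names.
#' @export
default_channels <- function() {
  c("T1w", "T2w", "ADC", "L2", "L3", "L4", "L3sub", "L4sub")
}

wavelet_subbands <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

#' Feature manifest: the fixed feature-slot layout
#'
#' Enumerates every feature slot the extractor emits, in extraction order:
#' 6 shape descriptors (once per patient), then per channel 14 histogram +
#' 7 GLRLM + 44 GLCM features on the native volume and on each of the 8
#' wavelet sub-bands. With the default 8 channels this is
#' 6 + 8 x (65 + 8 x 65) = 4,686 slots.
#'
#' @param channels character vector of channel names.
#' @return tibble with columns `channel`, `subband`, `family`, `name`,
#'   `distance` (1/2 for GLCM, NA otherwise) and the canonical `key`.
#' @export
feature_manifest <- function(channels = default_channels()) {
  cache_key <- paste(channels, collapse = "|")
  hit <- .manifest_cache[[cache_key]]
  if (!is.null(hit)) return(hit)
  hist_names <- c("min", "mean", "max", paste0("p", seq(10, 90, 10)),
                  "skewness", "kurtosis")
  rows <- list(
    tibble(channel = "shape", subband = "native", family = "morphology",
           name = c("volume", "surface_area", "circularity", "compactness",
                    "convexity", "irregularity"),
           distance = NA_integer_)
  )
  for (ch in channels) {
    for (sb in c("native", wavelet_subbands())) {
      rows[[length(rows) + 1L]] <- tibble(
        channel = ch, subband = sb, family = "histogram",
        name = hist_names, distance = NA_integer_
      )
      rows[[length(rows) + 1L]] <- tibble(
        channel = ch, subband = sb, family = "glrlm",
        name = glrlm_feature_names(), distance = NA_integer_
      )
      for (d in 1:2) {
        rows[[length(rows) + 1L]] <- tibble(
          channel = ch, subband = sb, family = "glcm",
          name = glcm_feature_names(), distance = d
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$key <- ifelse(
    is.na(out$distance),
    paste(out$channel, out$subband, out$family, out$name, sep = "."),
    paste0(paste(out$channel, out$subband, out$family, out$name, sep = "."),
           "_d", out$distance)
  )
  .manifest_cache[[cache_key]] <- out
  out
}

.manifest_cache <- new.env(parent = emptyenv())

# 65 histogram + texture features of one (channel, sub-band) ROI.
roi_features <- function(volume, mask, g, spacing_mm) {
  q <- quantize(volume, mask, g = g, spacing_mm = spacing_mm)
  c(
    histogram_features(volume[mask]),
    glrlm_features(q),
    glcm_direction_means(q, 1L),
    glcm_direction_means(q, 2L)
  )
}

#' Extract the full radiomics feature vector for one study
#'
#' Runs the complete per-patient extraction on a preprocessed study
#' (isotropic grid, eroded mask): shape features from the mask, then for
#' every channel the 65 first-order + texture features on the native volume
#' and on each of its 8 Haar wavelet sub-bands. Layout and order follow
#' [feature_manifest()].
#'
#' @param study an `mp_study` (see [mp_study()]), already preprocessed.
#' @param g gray-level count for quantization (default 64), applied per
#'   channel and per sub-band over the in-ROI min-max range.
#' @return named numeric vector (length 4,686 for 8 channels), names are
#'   manifest keys.
#' @export
extract_features <- function(study, g = 64L) {
  stopifnot(inherits(study, "mp_study"))
  mask <- study$mask
  vals <- list(morphology_features(mask, study$spacing_mm))
  for (ch in names(study$channels)) {
    vol <- study$channels[[ch]]
    native <- roi_features(vol, mask, g, study$spacing_mm)
    bands <- wavelet_decompose(vol, align = TRUE)
    vals[[length(vals) + 1L]] <- c(
      native,
      unlist(lapply(bands, roi_features, mask = mask, g = g,
                    spacing_mm = study$spacing_mm), use.names = FALSE)
    )
  }
  v <- unlist(vals, use.names = FALSE)
  man <- feature_manifest(names(study$channels))
  if (length(v) != nrow(man)) {
    abort("feature layout mismatch: extracted length != manifest")
  }
  names(v) <- man$key
  bad <- which(!is.finite(v))
  if (length(bad)) {
    abort(sprintf("non-finite feature value at key '%s'", names(v)[bad[1]]))
  }
  v
}

#' Extract a cohort feature matrix
#'
#' Applies [extract_features()] to each study and binds the results into a
#' patients-by-features tibble.
#'
#' @param studies list of preprocessed `mp_study` objects.
#' @param g gray-level count.
#' @return tibble with `patient_id` plus one column per feature key.
#' @export
extract_cohort <- function(studies, g = 64L) {
  mats <- lapply(studies, function(s) extract_features(s, g = g))
  m <- do.call(rbind, mats)
  out <- tibble(patient_id = vapply(studies, function(s) s$patient_id, ""))
  dplyr::bind_cols(out, as_tibble(m))
}
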