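#' Write a study to NIfTI files
#'
#' One NIfTI per channel plus one for the mask, with the voxel spacing
#' encoded in the header.
#'
#' @param study an `mp_study`.
#' @param dir output directory (created if needed).
#' @return invisible named list of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mp_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (ch in names(study$channels)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", study$patient_id, ch))
    img <- RNifti::asNifti(study$channels[[ch]])
    RNifti::pixdim(img) <- study$spacing_mm
    RNifti::writeNifti(img, p)
    paths[[ch]] <- p
  }
  p <- file.path(dir, sprintf("%s_mask.nii.gz", study$patient_id))
  img <- RNifti::asNifti(array(as.integer(study$mask), dim(study$mask)))
  RNifti::pixdim(img) <- study$spacing_mm
  RNifti::writeNifti(img, p)
  paths[["mask"]] <- p
  invisible(paths)
}

#' Read a study from NIfTI files
#'
#' Validates that all channels and the mask share grid and spacing and that
#' the mask is binary.
#'
#' @param channel_paths named character vector/list of channel NIfTI paths.
#' @param mask_path mask NIfTI path.
#' @param patient_id identifier (default from the mask filename).
#' @return an `mp_study`.
#' @export
read_study <- function(channel_paths, mask_path, patient_id = NULL) {
  if (is.null(names(channel_paths)) || any(!nzchar(names(channel_paths)))) {
    abort("`channel_paths` must be named by channel")
  }
  mask_img <- RNifti::readNifti(mask_path)
  mvals <- unique(as.vector(mask_img))
  if (!all(mvals %in% c(0, 1))) {
    abort(sprintf("mask '%s' is not binary (values: %s)", mask_path,
                  paste(utils::head(sort(mvals), 5), collapse = ", ")))
  }
  mdim <- dim(mask_img)
  msp <- RNifti::pixdim(mask_img)
  channels <- list()
  for (ch in names(channel_paths)) {
    img <- RNifti::readNifti(channel_paths[[ch]])
    if (!identical(dim(img), mdim)) {
      abort(sprintf(
        "channel '%s' grid %s does not match mask grid %s (%s vs %s)",
        ch, paste(dim(img), collapse = "x"), paste(mdim, collapse = "x"),
        channel_paths[[ch]], mask_path))
    }
    if (max(abs(RNifti::pixdim(img) - msp)) > 1e-5) {
      abort(sprintf("channel '%s' spacing differs from the mask", ch))
    }
    channels[[ch]] <- array(as.numeric(img), mdim)
  }
  if (is.null(patient_id)) {
    patient_id <- sub("_mask\\.nii(\\.gz)?$", "", basename(mask_path))
  }
  mp_study(patient_id, channels, array(as.vector(mask_img) != 0, mdim),
           as.numeric(msp))
}

#' Write a synthetic cohort to disk
#'
#' NIfTI volumes per patient, the clinical table as CSV, and a JSON sidecar
#' recording the generating configuration.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return invisible `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$studies) write_study(s, file.path(dir, s$patient_id))
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(
    cfg[setdiff(names(cfg), character(0))],
    file.path(dir, "cohort_config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param channels channel names to read (default [default_channels()]).
#' @return list with `studies` and `clinical`.
#' @export
read_cohort <- function(dir, channels = default_channels()) {
  clinical <- as_tibble(read.csv(file.path(dir, "clinical.csv")))
  studies <- lapply(clinical$patient_id, function(id) {
    pdir <- file.path(dir, id)
    cp <- setNames(file.path(pdir, sprintf("%s_%s.nii.gz", id, channels)),
                   channels)
    read_study(cp, file.path(pdir, sprintf("%s_mask.nii.gz", id)), id)
  })
  list(studies = studies, clinical = clinical)
}

#' Write a cohort feature matrix as CSV with a JSON manifest
#'
#' The CSV holds patients x features with manifest keys as the header; the
#' sidecar JSON records the full `FeatureKey` decomposition (channel,
#' sub-band, family, name, distance) for each column.
#'
#' @param features tibble from [extract_cohort()].
#' @param path CSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return invisible `path`.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  keys <- setdiff(names(features), "patient_id")
  man <- feature_manifest()
  man <- man[match(keys, man$key), ]
  jsonlite::write_json(man, paste0(path, ".manifest.json"), digits = NA)
  invisible(path)
}

#' Write a selection report as JSON
#'
#' Records the retained keys, the drop log of the redundancy filter, the
#' lambda path with its cross-validated deviance, and the final
#' coefficients.
#'
#' @param filter a [spearman_filter()] result.
#' @param selection a [lasso_select()] result.
#' @param path output JSON path.
#' @return invisible `path`.
#' @export
write_selection_report <- function(filter, selection, path) {
  jsonlite::write_json(
    list(
      retained = filter$retained,
      drop_log = filter$drop_log,
      lambda = selection$lambda,
      lambda_opt_unconstrained = selection$lambda_opt_unconstrained,
      path = selection$path,
      coefficients = selection$coefficients
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
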