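#' Generics for tidy model summaries
#'
#' Broom-style generics: `tidy()` returns one row per model term,
#' `glance()` one row per model.
#'
#' @param x a fitted object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Radiomics signature model
#'
#' A sigmoid-linked linear combination of selected radiomics features. The
#' term count must stay under 11 (the 10:1 events-per-variable rule for a
#' 114-patient training cohort).
#'
#' @param intercept numeric intercept.
#' @param terms tibble with columns `key` (feature manifest key) and
#'   `coefficient`.
#' @param note optional provenance/metadata string.
#' @return a `signature_model`.
#' @export
signature_model <- function(intercept, terms, note = NULL) {
  stopifnot_scalar(intercept, "intercept")
  terms <- as_tibble(terms)
  if (!all(c("key", "coefficient") %in% names(terms))) {
    abort("`terms` needs columns `key` and `coefficient`")
  }
  if (nrow(terms) >= 11L) abort("signature must have fewer than 11 terms")
  if (!all(is.finite(terms$coefficient))) abort("coefficients must be finite")
  structure(
    list(intercept = intercept,
         terms = terms[, c("key", "coefficient")], note = note),
    class = "signature_model"
  )
}

#' Reference 8-term radiomics signature
#'
#' The fixed multiparametric signature for 5-year OS in stage II-III rectal
#' cancer shipped with the package: intercept -0.664 and eight weighted
#' features spanning dynamic contrast-enhanced phases (L2, L3), anatomical
#' T1w/T2w, and the ADC map. Where its accompanying feature list and the
#' formula disagree (T1w HLH histogram max vs HLL; T2w long-run emphasis vs
#' LLL P10), the formula is authoritative; the discrepancy is recorded in
#' the model note.
#'
#' @return a `signature_model` with 8 terms.
#' @export
reference_signature <- function() {
  signature_model(
    intercept = -0.664,
    terms = tibble(
      key = c(
        "L2.native.histogram.skewness",
        "L3.HLL.histogram.max",
        "L3.native.glcm.difference_entropy_d1",
        "T1w.native.glrlm.lre",
        "T1w.HLH.histogram.max",
        "T2w.native.glrlm.lre",
        "T2w.HLH.histogram.p40",
        "ADC.native.glcm.imc1_d1"
      ),
      coefficient = c(0.106, -0.029, 0.022, 0.067, 0.05, -0.082, 0.05, -0.092)
    ),
    note = paste(
      "Reference signature; formula taken as authoritative over the",
      "accompanying feature list (conflicts: T1w HLH vs HLL histogram max;",
      "T2w long-run emphasis vs LLL P10). GLCM terms use distance 1."
    )
  )
}

#' Radiomics score
#'
#' `rad_score = sigmoid(intercept + sum(coefficient * feature))`. Higher
#' scores indicate longer expected survival.
#'
#' @param features a named numeric vector from [extract_features()], or a
#'   tibble/matrix of patients x features containing every model key.
#' @param model a [signature_model()].
#' @return numeric vector of scores, strictly in (0, 1).
#' @export
rad_score <- function(features, model) {
  stopifnot(inherits(model, "signature_model"))
  if (is.numeric(features) && !is.matrix(features)) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  } else {
    features <- as.data.frame(features)
    features$patient_id <- NULL
    features <- as.matrix(features)
  }
  missing <- setdiff(model$terms$key, colnames(features))
  if (length(missing)) {
    abort(sprintf("feature vector lacks model key '%s'", missing[1]))
  }
  eta <- model$intercept +
    drop(features[, model$terms$key, drop = FALSE] %*% model$terms$coefficient)
  sigmoid(eta)
}

# Build a signature from a LASSO selection result.
signature_from_lasso <- function(sel) {
  stopifnot(inherits(sel, "lasso_selection"))
  co <- sel$coefficients
  int <- co$estimate[co$term == "(Intercept)"]
  terms <- co[co$term != "(Intercept)", ]
  signature_model(int, tibble(key = terms$term, coefficient = terms$estimate),
                  note = sprintf("LASSO-selected at lambda = %.4g", sel$lambda))
}

#' @rdname tidy
#' @export
tidy.signature_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept),
    tibble(term = x$terms$key, estimate = x$terms$coefficient)
  )
}

#' @rdname tidy
#' @export
glance.signature_model <- function(x, ...) {
  tibble(n_terms = nrow(x$terms), intercept = x$intercept,
         score_at_zero = sigmoid(x$intercept))
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d terms, intercept %.3f\n",
              nrow(x$terms), x$intercept))
  print(x$terms)
  invisible(x)
}

#' Serialize / deserialize a signature model as JSON
#'
#' @param model a `signature_model`.
#' @param path file path.
#' @return `signature_write()` returns `path` invisibly;
#'   `signature_read()` returns the round-tripped `signature_model`.
#' @export
signature_write <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         terms = model$terms, note = model$note %||% NA_character_),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname signature_write
#' @export
signature_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  note <- if (is.null(x$note) || is.na(x$note)) NULL else x$note
  signature_model(x$intercept, as_tibble(x$terms), note = note)
}
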