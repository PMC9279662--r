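#' Reference cohort characteristics (printed counts)
#'
#' The categorical patient counts of the reference stage II-III rectal
#' cancer cohort (165 patients: primary cohort 88 five-year survivors / 26
#' non-survivors, test cohort 35 / 16), stratified by 5-year overall
#' survival. These counts drive the synthetic cohort generator's clinical
#' marginals and the published survival-rate arithmetic.
#'
#' @return tibble with columns `variable`, `level`, `primary_os`,
#'   `primary_nonos`, `test_os`, `test_nonos`.
#' @export
reference_cohort_counts <- function() {
  tribble(
    ~variable, ~level, ~primary_os, ~primary_nonos, ~test_os, ~test_nonos,
    "gender", "male",     57,  9, 23, 10,
    "gender", "female",   31, 17, 12,  6,
    "c_t", "T2",          16,  5,  8,  3,
    "c_t", "T3",          57, 17, 26, 13,
    "c_t", "T4",          15,  4,  1,  0,
    "c_n", "N0",          54, 15, 22,  8,
    "c_n", "N1",          32,  8, 11,  8,
    "c_n", "N2",           2,  3,  2,  0,
    "stage", "IIA",       34,  7, 18,  6,
    "stage", "IIB",        1,  1,  1,  0,
    "stage", "IIIA",       3,  1,  4,  1,
    "stage", "IIIB",      40,  9, 11,  8,
    "stage", "IIIC",      10,  8,  1,  1,
    "chemo", "none",      40, 16,  7,  8,
    "chemo", "Folfox",    32,  6, 18,  5,
    "chemo", "Xelox",     16,  4, 10,  3,
    "location", "low",    12,  7,  6,  2,
    "location", "mid",    42, 12, 20, 11,
    "location", "high",   34,  7,  9,  3,
    "emvi", "0",          38,  6,  1,  1,
    "emvi", "1",           2,  0,  2,  1,
    "emvi", "2",           2,  1,  1,  1,
    "emvi", "3",          36, 11,  1,  0,
    "emvi", "4",          10,  8, 30, 13,
    "y_t", "T2",           4,  3,  5,  1,
    "y_t", "T3",          79, 21, 29, 12,
    "y_t", "T4",           5,  2,  1,  3,
    "y_n", "N0",          40,  6, 19,  5,
    "y_n", "N1",          37, 14, 13,  7,
    "y_n", "N2",          11,  6,  3,  4,
    "histology", "I",     34,  9, 14,  4,
    "histology", "II",    44, 14, 16, 10,
    "histology", "III",    4,  2,  1,  0,
    "histology", "IV",     6,  1,  4,  2
  )
}

pooled_group_counts <- function(variable) {
  x <- dplyr::filter(reference_cohort_counts(), .data$variable == !!variable)
  tibble(
    level = x$level,
    os = x$primary_os + x$test_os,
    nonos = x$primary_nonos + x$test_nonos
  )
}

#' Five-year OS rate by clinical stage
#'
#' Pooled (primary + test) stage-specific 5-year overall-survival rates
#' recomputed from the reference cohort counts, in percent.
#'
#' @return tibble with `stage`, `n`, `os_rate_pct`.
#' @export
os_rate_by_stage <- function() {
  x <- pooled_group_counts("stage")
  tibble(
    stage = x$level,
    n = x$os + x$nonos,
    os_rate_pct = 100 * x$os / (x$os + x$nonos)
  )
}

#' Five-year OS rate by pathological nodal stage
#'
#' Pooled yN-specific 5-year OS rates recomputed from the reference counts,
#' in percent.
#'
#' @return tibble with `y_n`, `n`, `os_rate_pct`.
#' @export
os_rate_by_nodal_stage <- function() {
  x <- pooled_group_counts("y_n")
  tibble(
    y_n = x$level,
    n = x$os + x$nonos,
    os_rate_pct = 100 * x$os / (x$os + x$nonos)
  )
}

#' Cohort 5-year OS prevalence
#'
#' Five-year OS prevalence (percent) in the pooled, primary, and test
#' reference cohorts, from the printed group sizes 88/26 and 35/16.
#'
#' @return named numeric vector (`overall`, `primary`, `test`).
#' @export
os_prevalence <- function() {
  x <- pooled_group_counts("stage")  # any exhaustive variable carries the totals
  p_os <- sum(dplyr::filter(reference_cohort_counts(),
                            .data$variable == "stage")$primary_os)
  p_non <- sum(dplyr::filter(reference_cohort_counts(),
                             .data$variable == "stage")$primary_nonos)
  t_os <- sum(dplyr::filter(reference_cohort_counts(),
                            .data$variable == "stage")$test_os)
  t_non <- sum(dplyr::filter(reference_cohort_counts(),
                             .data$variable == "stage")$test_nonos)
  c(
    overall = 100 * (p_os + t_os) / (p_os + t_os + p_non + t_non),
    primary = 100 * p_os / (p_os + p_non),
    test = 100 * t_os / (t_os + t_non)
  )
}
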