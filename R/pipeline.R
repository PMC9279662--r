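fit_or_penalize <- function(tab, name) {
  fit <- try(fit_risk_model(tab, name), silent = TRUE)
  if (inherits(fit, "try-error")) {
    fit <- fit_risk_model(tab, name, penalized = TRUE)
  }
  fit
}

#' Evaluate the four risk models on an extracted cohort
#'
#' Runs the full statistical stage on a feature matrix + clinical table:
#' split into primary/test cohorts by index, Spearman redundancy filter and
#' repeated-CV LASSO on the primary cohort only, radiomics score for
#' everyone, the four logistic risk models (TNM staging, clinical,
#' radiomics, combined) fit on the primary cohort, and per-model
#' discrimination (AUC with stratified-bootstrap CI, C-index), calibration
#' (Hosmer-Lemeshow + curve) of the combined model, its nomogram, and
#' Kaplan-Meier stratification at the primary-cohort Youden cutoff (frozen
#' before touching the test cohort).
#'
#' @param features patients x features tibble from [extract_cohort()].
#' @param clinical clinical tibble aligned with `features` rows.
#' @param split_fraction fraction of patients forming the primary cohort
#'   (default 114/165, an index split).
#' @param selection a [selection_config()].
#' @param boot bootstrap replicates for AUC CIs.
#' @param hl_groups Hosmer-Lemeshow risk groups.
#' @param seed seed for bootstrap resampling.
#' @return an `evaluation_report`.
#' @export
evaluate_cohort <- function(features, clinical, split_fraction = 114 / 165,
                            selection = selection_config(),
                            boot = 2000L, hl_groups = 10L, seed = 1L) {
  features <- as_tibble(features)
  clinical <- as_tibble(clinical)
  stopifnot(nrow(features) == nrow(clinical))
  n <- nrow(features)
  m <- max(2L, min(n - 2L, round(split_fraction * n)))
  primary <- seq_len(m)
  test <- setdiff(seq_len(n), primary)
  y <- as.integer(clinical$os_5yr)

  fmat <- as.data.frame(features)
  fmat$patient_id <- NULL
  fmat <- as.matrix(fmat)

  filt <- spearman_filter(fmat[primary, , drop = FALSE],
                          threshold = selection$spearman_threshold)
  sel <- lasso_select(fmat[primary, filt$retained, drop = FALSE], y[primary],
                      selection)
  sig <- signature_from_lasso(sel)
  scores <- rad_score(fmat, sig)

  tab <- dplyr::mutate(clinical, rad_score = scores)
  tab_p <- tab[primary, ]
  tab_t <- tab[test, ]

  models <- lapply(setNames(nm = c("tnm", "clinical", "radiomics",
                                   "combined")),
                   function(nm) fit_or_penalize(tab_p, nm))
  perf <- dplyr::bind_rows(lapply(names(models), function(nm) {
    dplyr::bind_rows(lapply(c("primary", "test"), function(co) {
      dat <- if (co == "primary") tab_p else tab_t
      p <- predict(models[[nm]], dat)
      r <- roc_auc(p, dat$os_5yr, boot = boot, seed = seed)
      tibble(model = nm, cohort = co, auc = r$auc, ci_low = r$ci_low,
             ci_high = r$ci_high, c_index = r$auc, n = nrow(dat))
    }))
  }))

  clamp <- function(p) pmin(pmax(p, 1e-8), 1 - 1e-8)
  hl <- list(
    primary = hosmer_lemeshow(clamp(predict(models$combined, tab_p)),
                              tab_p$os_5yr, groups = hl_groups),
    test = hosmer_lemeshow(clamp(predict(models$combined, tab_t)),
                           tab_t$os_5yr, groups = hl_groups)
  )
  nomo <- if (!models$combined$penalized) build_nomogram(models$combined)
          else NULL

  cutoff <- youden_cutoff(scores[primary], y[primary])
  km_try <- function(idx) {
    out <- try(km_stratify(scores[idx], clinical$survival_months[idx],
                           y[idx], cutoff = cutoff), silent = TRUE)
    if (inherits(out, "try-error")) NULL else out  # degenerate stratification
  }
  km <- list(primary = km_try(primary), test = km_try(test))

  structure(
    list(performance = perf, models = models, hl = hl, nomogram = nomo,
         km = km, cutoff = cutoff, filter = filt, selection = sel,
         signature = sig,
         scores = tibble(
           patient_id = clinical$patient_id,
           cohort = ifelse(seq_len(n) %in% primary, "primary", "test"),
           rad_score = scores, os_5yr = clinical$os_5yr,
           survival_months = clinical$survival_months
         )),
    class = "evaluation_report"
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generate, preprocess, extract, and evaluate in one call: the end-to-end
#' twin of the study workflow, fully determined by the configuration seed.
#'
#' @param config a [cohort_config()].
#' @param selection a [selection_config()] (defaults to the config seed).
#' @param split_fraction primary-cohort fraction (default 114/165).
#' @param g gray levels for quantization.
#' @param erosion_mm mask erosion margin (mm).
#' @param target_spacing isotropic spacing (mm).
#' @param boot AUC bootstrap replicates.
#' @param hl_groups Hosmer-Lemeshow groups.
#' @return an `evaluation_report`; the extracted features and clinical
#'   table are attached as `$features` and `$clinical`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         selection = selection_config(seed = config$seed),
                         split_fraction = 114 / 165, g = 64L,
                         erosion_mm = 1.0, target_spacing = 1.0,
                         boot = 2000L, hl_groups = 10L) {
  cohort <- generate_cohort(config)
  pre <- lapply(cohort$studies, preprocess_study,
                target_spacing = target_spacing, erosion_mm = erosion_mm)
  features <- extract_cohort(pre, g = g)
  rep <- evaluate_cohort(features, cohort$clinical,
                         split_fraction = split_fraction,
                         selection = selection, boot = boot,
                         hl_groups = hl_groups, seed = config$seed)
  rep$features <- features
  rep$clinical <- cohort$clinical
  rep$config <- config
  # manifest: two runs are diffable by (config hash, seed, version)
  rep$manifest <- list(
    config_hash = rlang::hash(config),
    selection_hash = rlang::hash(selection),
    seed = config$seed,
    n_patients = config$n_patients,
    package_version = as.character(utils::packageVersion("rectomics"))
  )
  rep
}

#' @rdname tidy
#' @export
glance.evaluation_report <- function(x, ...) x$performance

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  signature: %d terms, lambda %.4g\n",
              nrow(x$signature$terms), x$selection$lambda))
  perf <- x$performance
  for (co in unique(perf$cohort)) {
    sub <- perf[perf$cohort == co, ]
    cat(sprintf("  %s cohort (n=%d): %s\n", co, sub$n[1],
                paste(sprintf("%s AUC %.2f", sub$model, sub$auc),
                      collapse = ", ")))
  }
  lrp <- function(k) if (is.null(k)) NA_real_ else k$logrank_p
  cat(sprintf("  HL p: primary %.2f, test %.2f; log-rank p: %.2g / %.2g\n",
              x$hl$primary$p_value, x$hl$test$p_value,
              lrp(x$km$primary), lrp(x$km$test)))
  invisible(x)
}
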