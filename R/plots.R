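#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_abline geom_tile labs theme_minimal scale_fill_gradient2
#'   scale_y_continuous
NULL

#' Plot a ROC curve
#'
#' @param object a `rad_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rad_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("AUC %.2f (95%% CI %.2f-%.2f)",
                         object$auc, object$ci_low, object$ci_high)) +
    theme_minimal()
}

#' Plot ROC curves for all four risk models
#'
#' @param report an `evaluation_report`.
#' @param cohort `"primary"` or `"test"`.
#' @return a ggplot.
#' @export
plot_model_roc <- function(report, cohort = "primary") {
  if (is.null(report$clinical)) {
    abort("report lacks clinical data; rerun via run_pipeline()")
  }
  tab <- dplyr::mutate(report$clinical, rad_score = report$scores$rad_score)
  tab <- tab[report$scores$cohort == cohort, ]
  dat <- dplyr::bind_rows(lapply(names(report$models), function(nm) {
    p <- predict(report$models[[nm]], tab)
    r <- roc_auc(p, tab$os_5yr, ci = FALSE)
    dplyr::mutate(r$curve, model = nm)
  }))
  ggplot(dat, aes(x = .data$fpr, y = .data$tpr, colour = .data$model)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("Risk-model ROC (%s cohort)", cohort)) +
    theme_minimal()
}

#' Plot a calibration curve
#'
#' Mean predicted probability vs observed event rate per risk group, with
#' the diagonal marking perfect calibration.
#'
#' @param hl a [hosmer_lemeshow()] result.
#' @return a ggplot.
#' @export
plot_calibration <- function(hl) {
  ggplot(hl$calibration, aes(x = .data$mean_pred, y = .data$obs_rate)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() + geom_point() +
    labs(x = "Predicted 5-year OS probability", y = "Observed rate",
         title = sprintf("Hosmer-Lemeshow chi2 = %.2f, p = %.2f",
                         hl$statistic, hl$p_value)) +
    theme_minimal()
}

#' Plot Kaplan-Meier curves for the risk strata
#'
#' @param object a `km_strata`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_strata <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$time, y = .data$surv,
                            colour = .data$group)) +
    geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Months", y = "Overall survival",
         title = sprintf("Log-rank p = %.3g", object$logrank_p)) +
    theme_minimal()
}

#' Plot a nomogram's point scales
#'
#' @param object a `nomogram`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nomogram <- function(object, ...) {
  ggplot(object$points, aes(x = .data$points, y = .data$predictor)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "Points (0-100 scale)", y = NULL,
         title = "Nomogram predictor point scales") +
    theme_minimal()
}

#' Plot the feature-clinical correlation heatmap
#'
#' Green marks positive and red negative Spearman correlation.
#'
#' @param object a `feature_clinical_cor` matrix.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.feature_clinical_cor <- function(object, ...) {
  m <- unclass(object)
  dat <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(m), feature = rownames(m)),
    -"feature", names_to = "clinical", values_to = "rho"
  )
  ggplot(dat, aes(x = .data$clinical, y = .data$feature,
                  fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "red", mid = "white", high = "green",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal()
}
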