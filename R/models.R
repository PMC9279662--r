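#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) statistic with ties averaged; the 95% CI
#' by class-stratified bootstrap.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels binary outcome (0/1 or logical); both classes required.
#' @param ci compute the bootstrap CI (default TRUE).
#' @param boot number of bootstrap replicates (default 2000).
#' @param seed seed for the bootstrap resampling.
#' @return a `rad_roc`: list with `auc`, `ci_low`, `ci_high`, `curve`
#'   (tibble `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci = TRUE, boot = 2000L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("labels contain a single class")
  if (length(scores) != length(labels)) abort("length mismatch")
  auc_rank <- function(s, y) {
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    (sum(rank(s)[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_rank(scores, labels)
  lo <- hi <- NA_real_
  if (ci) {
    set.seed(child_seed(seed, "rocboot"))
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    reps <- vapply(seq_len(boot), function(b) {
      i <- c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
             neg[sample.int(length(neg), length(neg), replace = TRUE)])
      auc_rank(scores[i], labels[i])
    }, 0)
    qs <- quantile(reps, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), 0)
  structure(
    list(auc = auc, ci_low = lo, ci_high = hi,
         curve = tibble(threshold = thr, fpr = fpr, tpr = tpr),
         n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
    class = "rad_roc"
  )
}

#' @export
print.rad_roc <- function(x, ...) {
  cat(sprintf("<rad_roc> AUC %.3f (95%% CI %.3f-%.3f), %d/%d pos/neg\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Harrell's C-index for a binary endpoint
#'
#' The concordance probability between score and outcome with tied scores
#' counted 1/2, which for a binary endpoint equals the rank-statistic AUC.
#'
#' @inheritParams roc_auc
#' @return concordance in [0, 1].
#' @export
c_index <- function(scores, labels) {
  roc_auc(scores, labels, ci = FALSE)$auc
}

#' Youden-optimal risk cutoff
#'
#' Threshold maximizing sensitivity + specificity - 1 on the ROC curve;
#' candidate cutpoints are midpoints between adjacent distinct scores. Ties
#' resolve to the lowest such cutoff.
#'
#' @inheritParams roc_auc
#' @return numeric cutoff; scores >= cutoff predict the positive class.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  j <- vapply(cand, function(t) {
    mean(scores[labels == 1L] >= t) - mean(scores[labels == 0L] >= t)
  }, 0)
  cand[which.max(j)]
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups predictions into risk deciles (quantile bins; empty or duplicate
#' bins are merged) and compares observed event counts with expected under
#' the model: `chi^2` with `groups - 2` degrees of freedom.
#'
#' @param pred predicted probabilities in (0, 1).
#' @param obs observed binary outcomes.
#' @param groups number of risk groups (default 10).
#' @return list with `statistic`, `df`, `p_value`, and `calibration`
#'   (tibble `group`, `n`, `mean_pred`, `obs_rate`).
#' @export
hosmer_lemeshow <- function(pred, obs, groups = 10L) {
  obs <- as.integer(obs)
  if (any(pred <= 0 | pred >= 1)) abort("`pred` must lie strictly in (0,1)")
  if (groups < 2L) abort("`groups` must be >= 2")
  br <- unique(quantile(pred, probs = seq(0, 1, length.out = groups + 1)))
  if (length(br) < 3L) br <- c(-Inf, mean(pred), Inf)
  g <- cut(pred, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- dplyr::summarise(
    dplyr::group_by(tibble(g = g, pred = pred, obs = obs), g),
    n = dplyr::n(), mean_pred = mean(pred), obs_rate = mean(obs),
    e1 = sum(pred), o1 = sum(obs), .groups = "drop"
  )
  chi2 <- sum((tab$o1 - tab$e1)^2 / (tab$e1 * (1 - tab$e1 / tab$n)))
  df <- max(1L, nrow(tab) - 2L)
  list(
    statistic = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE),
    calibration = tibble(group = tab$g, n = tab$n, mean_pred = tab$mean_pred,
                         obs_rate = tab$obs_rate)
  )
}

#' Fit one of the four risk models
#'
#' Maximum-likelihood logistic regression of the 5-year OS label on the
#' model's covariate set:
#' \itemize{
#'   \item `tnm`: clinical stage only;
#'   \item `clinical`: the non-radiomics clinical-histological-radiological
#'     set (age, gender, log CEA, tumor deposits, surgery, location, EMVI,
#'     yN, LNR);
#'   \item `radiomics`: the radiomics score only;
#'   \item `combined`: the radiomics score plus the strongest conventional
#'     factors (LNR, surgery, yN), i.e. the nomogram covariates.
#' }
#' Categorical covariates are one-hot encoded against their first observed
#' level. Quasi-perfect separation (fitted probabilities collapsing to 0/1)
#' raises an error unless `penalized = TRUE`, which refits with a small
#' ridge penalty.
#'
#' @param cohort_table tibble with `os_5yr` plus covariates (and `rad_score`
#'   for the radiomics/combined models).
#' @param name one of `"tnm"`, `"clinical"`, `"radiomics"`, `"combined"`.
#' @param covariates optional character vector overriding the default
#'   covariate set.
#' @param penalized use a ridge-penalized fit (for separated data).
#' @return a `risk_model`: list with `name`, `covariates`, `fit`,
#'   `train_data`.
#' @export
fit_risk_model <- function(cohort_table, name = c("tnm", "clinical",
                                                  "radiomics", "combined"),
                           covariates = NULL, penalized = FALSE) {
  name <- match.arg(name)
  tab <- as_tibble(cohort_table)
  if (is.null(covariates)) {
    covariates <- switch(
      name,
      tnm = "stage",
      clinical = c("age", "gender", "log_cea", "tumor_deposit", "surgery",
                   "location", "emvi", "y_n", "lnr"),
      radiomics = "rad_score",
      combined = c("rad_score", "lnr", "surgery", "y_n")
    )
  }
  if ("log_cea" %in% covariates && !"log_cea" %in% names(tab)) {
    tab$log_cea <- log1p(tab$cea)
  }
  missing <- setdiff(c("os_5yr", covariates), names(tab))
  if (length(missing)) {
    abort(sprintf("cohort table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.character) & dplyr::any_of(covariates), as.factor))
  y <- as.integer(tab$os_5yr)
  if (length(unique(y)) < 2L) abort("outcome has a single class")
  fml <- as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  dat <- dplyr::bind_cols(tibble(y = y), tab[covariates])
  # drop single-level factors (possible in small resamples)
  for (v in covariates) {
    if (is.factor(dat[[v]]) && nlevels(droplevels(dat[[v]])) < 2L) {
      covariates <- setdiff(covariates, v)
    }
  }
  fml <- as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  if (penalized) {
    mm <- model.matrix(fml, dat)[, -1, drop = FALSE]
    if (ncol(mm) == 1L) mm <- cbind(mm, `.null` = 0)  # glmnet needs >= 2 cols
    gfit <- muffle_small_class(
      glmnet::glmnet(mm, y, family = "binomial", alpha = 0, lambda = 1e-3)
    )
    fit <- list(glmnet = gfit, formula = fml, data = dat)
  } else {
    fit <- suppressWarnings(glm(fml, data = dat, family = binomial()))
    p <- fitted(fit)
    if (all(p < 1e-6 | p > 1 - 1e-6)) {
      abort(paste("quasi-perfect separation detected; refit with",
                  "`penalized = TRUE`"))
    }
  }
  structure(
    list(name = name, covariates = covariates, fit = fit, penalized = penalized,
         train_data = dat),
    class = "risk_model"
  )
}

#' Predict 5-year OS probability from a fitted risk model
#'
#' @param object a `risk_model`.
#' @param newdata tibble of covariates (defaults to the training data).
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.risk_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train_data
  newdata <- as_tibble(newdata)
  if ("log_cea" %in% object$covariates && !"log_cea" %in% names(newdata) &&
      "cea" %in% names(newdata)) {
    newdata$log_cea <- log1p(newdata$cea)
  }
  newdata <- dplyr::mutate(newdata, dplyr::across(
    dplyr::where(is.character) & dplyr::any_of(object$covariates), as.factor))
  # align factor levels with training; levels never seen in training carry
  # no coefficient and fall back to the reference level
  for (v in object$covariates) {
    if (is.factor(object$train_data[[v]])) {
      lv <- levels(object$train_data[[v]])
      vals <- as.character(newdata[[v]])
      vals[!vals %in% lv] <- lv[1]
      newdata[[v]] <- factor(vals, levels = lv)
    }
  }
  if (object$penalized) {
    mm <- model.matrix(object$fit$formula, dplyr::bind_cols(
      tibble(y = 0L), newdata[object$covariates]))[, -1, drop = FALSE]
    if (ncol(mm) == 1L) mm <- cbind(mm, `.null` = 0)
    drop(predict(object$fit$glmnet, mm, type = "response"))
  } else {
    unname(predict(object$fit, newdata = newdata, type = "response"))
  }
}

#' @rdname tidy
#' @export
tidy.risk_model <- function(x, ...) {
  if (x$penalized) {
    b <- coef(x$fit$glmnet)
    return(tibble(term = rownames(b), estimate = as.numeric(b)))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @rdname tidy
#' @export
glance.risk_model <- function(x, ...) {
  p <- predict(x)
  tibble(model = x$name, n = nrow(x$train_data),
         auc_train = c_index(p, x$train_data$y))
}

#' Nomogram point tables for a fitted logistic model
#'
#' Re-expresses a fitted `risk_model` on a 0-100 point scale: each
#' model-matrix predictor contributes
#' `points = 100 * (beta * value - min(beta * value)) / max_span`, where
#' `max_span` is the largest contribution range across predictors (that
#' predictor spans exactly 0-100). Total points map to probability through
#' the logistic, so the nomogram reproduces the model probability exactly
#' up to point quantization. Zero-range predictors are excluded and logged.
#'
#' @param model a `risk_model` (unpenalized).
#' @return a `nomogram`: list with `points` (tibble `predictor`, `value`,
#'   `points`), `total_to_prob` (tibble `total_points`, `probability`),
#'   `excluded`, plus internal scale constants.
#' @export
build_nomogram <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  if (model$penalized) abort("nomogram requires an unpenalized fit")
  fml <- stats::formula(model$fit)
  mm <- model.matrix(fml, model$train_data)
  beta <- coef(model$fit)
  beta[is.na(beta)] <- 0
  cols <- setdiff(colnames(mm), "(Intercept)")
  contrib_min <- contrib_max <- setNames(numeric(length(cols)), cols)
  for (k in cols) {
    v <- beta[k] * mm[, k]
    contrib_min[k] <- min(v); contrib_max[k] <- max(v)
  }
  span <- contrib_max - contrib_min
  excluded <- names(span)[span <= 0]
  cols <- setdiff(cols, excluded)
  if (!length(cols)) abort("no predictor with nonzero range")
  max_span <- max(span[cols])
  pts <- dplyr::bind_rows(lapply(cols, function(k) {
    vals <- sort(unique(mm[, k]))
    if (length(vals) > 25L) vals <- seq(min(vals), max(vals),
                                        length.out = 21)
    tibble(predictor = k, value = vals,
           points = 100 * (beta[k] * vals - contrib_min[k]) / max_span)
  }))
  base_eta <- beta["(Intercept)"] + sum(contrib_min[cols])
  total <- seq(0, sum(100 * span[cols] / max_span), length.out = 101)
  structure(
    list(points = pts,
         total_to_prob = tibble(
           total_points = total,
           probability = sigmoid(base_eta + total * max_span / 100)
         ),
         excluded = excluded, base_eta = base_eta, max_span = max_span,
         contrib_min = contrib_min[cols], beta = beta, formula = fml),
    class = "nomogram"
  )
}

#' Score a patient through the nomogram point scale
#'
#' @param nomo a `nomogram`.
#' @param model the `risk_model` it was built from.
#' @param newdata covariate tibble.
#' @return tibble with `total_points` and `probability`.
#' @export
nomogram_predict <- function(nomo, model, newdata) {
  newdata <- as_tibble(newdata)
  newdata <- dplyr::mutate(newdata, dplyr::across(
    dplyr::where(is.character), as.factor))
  for (v in model$covariates) {
    if (is.factor(model$train_data[[v]])) {
      newdata[[v]] <- factor(newdata[[v]],
                             levels = levels(model$train_data[[v]]))
    }
  }
  mm <- model.matrix(nomo$formula, dplyr::bind_cols(
    tibble(y = 0L), newdata[model$covariates]))
  cols <- names(nomo$contrib_min)
  total <- unname(rowSums(vapply(cols, function(k) {
    100 * (nomo$beta[k] * mm[, k] - nomo$contrib_min[k]) / nomo$max_span
  }, numeric(nrow(mm)))))
  tibble(total_points = total,
         probability = sigmoid(nomo$base_eta + total * nomo$max_span / 100))
}

#' Kaplan-Meier risk stratification
#'
#' Splits patients into high-/low-risk groups at a score cutoff (by default
#' the Youden-optimal threshold for the provided labels; a frozen primary
#' cohort cutoff can be re-applied to a test cohort), estimates the
#' product-limit survival curve per group, and tests the separation with
#' the log-rank test. Deaths are the non-OS patients; survivors are
#' censored at their last follow-up.
#'
#' @param scores radiomics (or model) scores; higher = better prognosis.
#' @param survival_months positive follow-up/survival times.
#' @param labels binary 5-year OS labels (used for the cutoff and as the
#'   event indicator: event = `!os_5yr`).
#' @param cutoff optional frozen cutoff; computed by [youden_cutoff()] when
#'   `NULL`.
#' @return a `km_strata`: list with `groups` (factor low/high risk),
#'   `cutoff`, `fit` (a `survival::survfit`), `logrank_chisq`, `logrank_p`
#'   (NA when inestimable), `curves` tibble.
#' @export
km_stratify <- function(scores, survival_months, labels, cutoff = NULL) {
  if (any(survival_months <= 0)) abort("survival months must be positive")
  labels <- as.integer(labels)
  if (is.null(cutoff)) cutoff <- youden_cutoff(scores, labels)
  groups <- factor(ifelse(scores >= cutoff, "low_risk", "high_risk"),
                   levels = c("low_risk", "high_risk"))
  if (min(table(groups)) < 2L) abort("cutoff leaves a group with < 2 patients")
  event <- 1L - labels
  surv <- survival::Surv(survival_months, event)
  fit <- survival::survfit(surv ~ groups)
  lr_chisq <- lr_p <- NA_real_
  if (length(unique(event)) > 1L || sum(event) > 0L) {
    sd <- try(survival::survdiff(surv ~ groups), silent = TRUE)
    if (!inherits(sd, "try-error")) {
      lr_chisq <- sd$chisq
      lr_p <- pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE)
    }
  }
  strata_names <- if (!is.null(fit$strata)) {
    rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  } else rep(levels(groups)[1], length(fit$time))
  structure(
    list(groups = groups, cutoff = cutoff, fit = fit,
         logrank_chisq = lr_chisq, logrank_p = lr_p,
         curves = tibble(group = strata_names, time = fit$time,
                         surv = fit$surv, n_risk = fit$n.risk,
                         n_event = fit$n.event)),
    class = "km_strata"
  )
}

#' Compare cohort characteristics between OS groups
#'
#' One-way ANOVA for continuous variables and Fisher's exact test for
#' categorical/logical variables, one row per variable -- the standard
#' baseline-characteristics comparison table.
#'
#' @param table cohort tibble.
#' @param group_col name of the binary grouping column (default `os_5yr`).
#' @param vars variables to test; defaults to everything except
#'   `patient_id`, the group column, and `survival_months`.
#' @return tibble with `variable`, `test`, `statistic`, `p_value`.
#' @export
cohort_compare <- function(table, group_col = "os_5yr", vars = NULL) {
  tab <- as_tibble(table)
  grp <- factor(tab[[group_col]])
  if (nlevels(droplevels(grp)) < 2L) abort("need two groups present")
  if (is.null(vars)) {
    vars <- setdiff(names(tab), c("patient_id", group_col, "survival_months"))
  }
  rows <- lapply(vars, function(v) {
    x <- tab[[v]]
    if (is.numeric(x) && length(unique(x)) > 6L) {
      if (sd(x) == 0) {
        return(tibble(variable = v, test = "anova", statistic = NA_real_,
                      p_value = NA_real_))
      }
      a <- anova(aov(x ~ grp))
      tibble(variable = v, test = "anova", statistic = a$`F value`[1],
             p_value = a$`Pr(>F)`[1])
    } else {
      ct <- table(x, grp)
      ct <- ct[rowSums(ct) > 0, , drop = FALSE]
      if (nrow(ct) < 2L) {
        return(tibble(variable = v, test = "fisher", statistic = NA_real_,
                      p_value = NA_real_))
      }
      ft <- fisher.test(ct, workspace = 2e6,
                        simulate.p.value = nrow(ct) > 5L, B = 1e4)
      tibble(variable = v, test = "fisher", statistic = NA_real_,
             p_value = ft$p.value)
    }
  })
  dplyr::bind_rows(rows)
}

#' Spearman correlation of selected features with clinical factors
#'
#' @param features tibble of selected radiomics features (patients x keys;
#'   `patient_id` ignored).
#' @param clinical clinical tibble; categorical columns are encoded as
#'   integer codes, logicals as 0/1. Constant columns give NA.
#' @param vars clinical variables to correlate (default: all encodable).
#' @return a `feature_clinical_cor` matrix (features x clinical) of
#'   Spearman rho.
#' @export
feature_clinical_heatmap <- function(features, clinical, vars = NULL) {
  f <- as.data.frame(features); f$patient_id <- NULL
  cl <- as_tibble(clinical)
  if (is.null(vars)) {
    vars <- setdiff(names(cl), c("patient_id", "survival_months", "os_5yr"))
  }
  enc <- lapply(vars, function(v) {
    x <- cl[[v]]
    if (is.numeric(x)) x
    else if (is.logical(x)) as.numeric(x)
    else as.numeric(factor(x))
  })
  names(enc) <- vars
  encm <- do.call(cbind, enc)
  m <- suppressWarnings(cor(as.matrix(f), encm, method = "spearman"))
  structure(m, class = c("feature_clinical_cor", class(m)))
}
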