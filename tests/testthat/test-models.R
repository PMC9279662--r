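test_that("AUC matches the pair-counting oracle and handles edge cases", {
  set.seed(51)
  for (r in 1:3) {
    n <- 60
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), 1)  # rounding forces ties
    r1 <- roc_auc(s, y, ci = FALSE)
    expect_equal(r1$auc, oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(c_index(s, y), r1$auc, tolerance = 1e-12)
  }
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), ci = FALSE)$auc, 1)
  # all tied
  expect_equal(c_index(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "single class")

  # independent scores sit in the null band around 0.5
  set.seed(52)
  y <- rbinom(500, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(500)
  a <- roc_auc(s, y, ci = FALSE)$auc
  se <- sqrt((sum(y == 1) + sum(y == 0) + 1) / (12 * sum(y == 1) * sum(y == 0)))
  expect_lt(abs(a - 0.5), 3 * se)

  # bootstrap CI brackets the estimate
  r2 <- roc_auc(rnorm(80) + y[1:80], y[1:80], boot = 300, seed = 4)
  expect_lte(r2$ci_low, r2$auc)
  expect_gte(r2$ci_high, r2$auc)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  y <- rbinom(100, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(100) + 0.8 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_auc(s, y, ci = FALSE)$auc, ref, tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow test calibrates as a test should", {
  # chi2 = 0 when predictions are exactly the group rates
  pred <- rep(0.5, 100)
  obs <- rep(c(0, 1), 50)
  hl <- hosmer_lemeshow(pred, obs)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)

  # calibrated-by-construction: for in-sample fitted predictions the
  # statistic is ~ chi^2 with groups - 2 df, so rejection rate ~ alpha
  set.seed(54)
  rej <- vapply(1:150, function(i) {
    x <- rnorm(600)
    o <- rbinom(600, 1, plogis(0.5 * x))
    p <- fitted(glm(o ~ x, family = binomial()))
    hosmer_lemeshow(p, o)$p_value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.05)

  # anti-calibrated predictions are rejected decisively
  set.seed(55)
  p <- runif(1000, 0.1, 0.9)
  o <- rbinom(1000, 1, 1 - p)
  expect_lt(hosmer_lemeshow(p, o)$p_value, 0.001)

  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)), "strictly")
})

test_that("logistic risk models recover closed-form 2x2 coefficients", {
  # counts: exposed 30/10, unexposed 20/40 -> log OR = log(30*40/(10*20))
  tab <- tibble::tibble(
    os_5yr = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 20, 40)),
    stage = rep(c("IIIA", "IIA"), c(40, 60))
  )
  fit <- fit_risk_model(tab, "tnm")
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "stageIIIA"],
               log(30 * 40 / (10 * 20)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # independence: coefficients shrink toward zero
  set.seed(56)
  tab2 <- tibble::tibble(
    os_5yr = rbinom(2000, 1, 0.7) == 1,
    rad_score = runif(2000)
  )
  fit2 <- fit_risk_model(tab2, "radiomics")
  expect_lt(abs(tidy(fit2)$estimate[2]), 0.5)

  expect_error(
    fit_risk_model(tibble::tibble(os_5yr = c(TRUE, TRUE), stage = c("a", "b")),
                   "tnm"),
    "single class"
  )
})

test_that("separation is detected and the penalized refit works", {
  tab <- tibble::tibble(
    os_5yr = rep(c(TRUE, FALSE), each = 20),
    rad_score = c(runif(20, 0.8, 0.9), runif(20, 0.1, 0.2))
  )
  expect_error(fit_risk_model(tab, "radiomics"), "separation")
  fit <- fit_risk_model(tab, "radiomics", penalized = TRUE)
  p <- predict(fit, tab)
  expect_gt(roc_auc(p, tab$os_5yr, ci = FALSE)$auc, 0.99)
})

test_that("the nomogram reproduces model probabilities through points", {
  set.seed(57)
  n <- 150
  tab <- tibble::tibble(
    rad_score = runif(n),
    lnr = runif(n, 0, 0.8),
    surgery = sample(c("LAR", "APR", "Hartmann"), n, TRUE),
    y_n = sample(c("N0", "N1", "N2"), n, TRUE)
  )
  eta <- -1 + 3 * tab$rad_score - 2 * tab$lnr +
    0.8 * (tab$y_n == "N2") - 0.5 * (tab$surgery == "Hartmann")
  tab$os_5yr <- rbinom(n, 1, plogis(eta)) == 1
  fit <- fit_risk_model(tab, "combined")
  nomo <- build_nomogram(fit)
  # the largest-span predictor covers exactly 0..100 points
  rng <- tapply(nomo$points$points, nomo$points$predictor,
                function(p) diff(range(p)))
  expect_equal(max(rng), 100, tolerance = 1e-9)
  expect_true(all(nomo$points$points >= -1e-9))
  # round trip: nomogram probability equals the glm probability
  np <- nomogram_predict(nomo, fit, tab)
  expect_equal(np$probability, unname(predict(fit, tab)), tolerance = 1e-9)

  # zero-range predictors are excluded with a log entry
  tab$flat <- 1
  fit2 <- fit_risk_model(tab, "combined",
                         covariates = c("rad_score", "lnr", "flat"))
  nomo2 <- build_nomogram(fit2)
  expect_false("flat" %in% unique(nomo2$points$predictor))
})

test_that("KM stratification separates groups and degrades gracefully", {
  set.seed(58)
  n <- 120
  os <- rbinom(n, 1, 0.7) == 1
  months <- ifelse(os, runif(n, 60, 120), runif(n, 5, 59))
  score <- ifelse(os, rnorm(n, 0.7, 0.15), rnorm(n, 0.3, 0.15))
  km <- km_stratify(score, months, os)
  expect_lt(km$logrank_p, 0.001)
  expect_equal(levels(km$groups), c("low_risk", "high_risk"))

  # KM equals 1 - ECDF with no censoring: score-0.2 patients are all
  # non-survivors (events) and form the high-risk group
  ev_months <- runif(40, 1, 50)
  km2 <- km_stratify(rep(c(0.2, 0.8), 20), ev_months, rep(c(0, 1), 20),
                     cutoff = 0.5)
  grp <- rep(c("high_risk", "low_risk"), 20)
  hi_times <- sort(ev_months[grp == "high_risk"])
  cur <- km2$curves[km2$curves$group == "high_risk", ]
  ecdf_vals <- 1 - seq_along(hi_times) / length(hi_times)
  expect_equal(cur$surv, ecdf_vals, tolerance = 1e-12)

  # no events at all: log-rank not applicable
  km3 <- km_stratify(runif(30), runif(30, 61, 100), rep(TRUE, 30),
                     cutoff = 0.5)
  expect_true(is.na(km3$logrank_p))
  expect_true(all(km3$curves$surv == 1))

  expect_error(km_stratify(runif(10), runif(10, 1, 10), rep(c(TRUE, FALSE), 5),
                           cutoff = 2), "group")
})

test_that("Youden cutoff maximizes sensitivity + specificity - 1", {
  s <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  cut <- youden_cutoff(s, y)
  expect_gt(cut, 0.3); expect_lt(cut, 0.6)
  j <- function(t) mean(s[y == 1] >= t) - mean(s[y == 0] >= t)
  expect_equal(j(cut), 1)
})

test_that("cohort comparison runs ANOVA/Fisher and matches enumeration", {
  # reconstruct the primary-cohort gender table: 57/31 male/female OS,
  # 9/17 non-OS
  tab <- tibble::tibble(
    os_5yr = rep(c(TRUE, FALSE), c(88, 26)),
    gender = c(rep("male", 57), rep("female", 31),
               rep("male", 9), rep("female", 17)),
    age = rnorm(114, 64, 10)
  )
  cmp <- cohort_compare(tab)
  p_gender <- cmp$p_value[cmp$variable == "gender"]
  expect_equal(round(p_gender, 2), 0.01)
  m <- matrix(c(57, 31, 9, 17), 2)
  expect_equal(p_gender, oracle_fisher_2x2(m), tolerance = 1e-9)
  expect_equal(p_gender, fisher.test(m)$p.value, tolerance = 1e-12)

  # identical group distributions: F ~ 0, p ~ 1
  tab2 <- tibble::tibble(
    os_5yr = rep(c(TRUE, FALSE), each = 50),
    x = rep(seq_len(50), 2)
  )
  cmp2 <- cohort_compare(tab2)
  expect_lt(cmp2$statistic[1], 1e-12)
  expect_gt(cmp2$p_value[1], 0.99)

  # random 2x2 tables vs hypergeometric enumeration
  set.seed(59)
  for (r in 1:5) {
    m <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(fisher.test(m)$p.value, oracle_fisher_2x2(m),
                 tolerance = 1e-9)
  }
})

test_that("feature-clinical heatmap is a proper Spearman matrix", {
  set.seed(60)
  n <- 80
  feats <- tibble::tibble(f1 = rnorm(n), f2 = rnorm(n))
  clin <- tibble::tibble(age = rnorm(n, 60, 10), cea = rexp(n),
                         gender = sample(c("male", "female"), n, TRUE))
  m <- feature_clinical_heatmap(cbind(feats, age = clin$age), clin,
                                vars = c("age", "cea"))
  expect_equal(unname(m["age", "age"]), 1)
  expect_true(all(abs(m[c("f1", "f2"), ]) < 0.35))
  # rank invariance under monotone transforms
  clin2 <- clin; clin2$cea <- exp(clin2$cea)
  m2 <- feature_clinical_heatmap(feats, clin2, vars = c("age", "cea"))
  m1 <- feature_clinical_heatmap(feats, clin, vars = c("age", "cea"))
  expect_equal(m1, m2, tolerance = 1e-12)
})
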