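test_that("spearman filter drops duplicates, negations and constants", {
  set.seed(31)
  n <- 60
  x <- tibble::tibble(
    a = rnorm(n), b = rnorm(n), cst = rep(1, n)
  )
  x$dup <- x$a
  x$neg <- -x$b
  out <- spearman_filter(x, threshold = 0.9)
  expect_setequal(out$retained, c("a", "b"))
  expect_true("cst" %in% out$drop_log$dropped)
  expect_equal(out$drop_log$culprit[out$drop_log$dropped == "dup"], "a")
  expect_equal(out$drop_log$culprit[out$drop_log$dropped == "neg"], "b")
})

test_that("independent columns survive; result ignores patient order", {
  set.seed(32)
  x <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  out <- spearman_filter(x, 0.9)
  expect_length(out$retained, 10)
  perm <- sample(200)
  out2 <- spearman_filter(x[perm, ], 0.9)
  expect_identical(out$retained, out2$retained)
})

test_that("greedy filter agrees with an all-pairs oracle scan", {
  set.seed(33)
  n <- 40
  base <- matrix(rnorm(n * 8), n, 8)
  # correlated block: noisy copies of column 1
  x <- cbind(base, base[, 1] + rnorm(n, sd = 0.05),
             base[, 2] + rnorm(n, sd = 0.02), base[, 1] + rnorm(n, sd = 2))
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  thr <- 0.9
  rho <- abs(cor(apply(x, 2, rank)))
  retained <- character(0)
  for (k in colnames(x)) {
    if (!length(retained) || all(rho[k, retained] <= thr)) {
      retained <- c(retained, k)
    }
  }
  out <- spearman_filter(x, thr)
  expect_identical(out$retained, retained)
})

test_that("LASSO recovers a planted signal and honors the cap", {
  hits <- 0
  nrep <- 10
  for (r in seq_len(nrep)) {
    set.seed(100 + r)
    n <- 300; p <- 15
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    eta <- 1.5 * x[, 1]
    y <- rbinom(n, 1, plogis(eta))
    sel <- lasso_select(x, y, selection_config(repeats = 5, seed = r))
    if ("f1" %in% sel$coefficients$term) hits <- hits + 1
    expect_lt(nrow(sel$coefficients) - 1, 11)
  }
  expect_gte(hits, 9)  # planted column selected in nearly every replicate
})

test_that("null model at the strong-penalty end matches the closed form", {
  set.seed(44)
  n <- 200
  x <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- rbinom(n, 1, 0.7)
  fit <- glmnet::glmnet(x, y, family = "binomial")
  b <- coef(fit, s = max(fit$lambda))
  expect_true(all(b[-1] == 0))
  expect_equal(b[1], qlogis(mean(y)), tolerance = 1e-6)
})

test_that("feature cap forces lambda up the path", {
  set.seed(45)
  n <- 120; p <- 30
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- rowSums(x[, 1:8]) * 0.8
  y <- rbinom(n, 1, plogis(eta))
  sel1 <- lasso_select(x, y, selection_config(repeats = 3, max_features = 2,
                                              seed = 1))
  expect_lte(nrow(sel1$coefficients) - 1, 1)
  sel2 <- lasso_select(x, y, selection_config(repeats = 3, seed = 1))
  expect_lt(nrow(sel2$coefficients) - 1, 11)
  expect_gte(sel2$lambda, sel2$lambda_opt_unconstrained - 1e-12)

  expect_error(lasso_select(x, rep(1, n), selection_config()), "single class")
})

test_that("selection is reproducible given matrix, config and seed", {
  set.seed(46)
  x <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rbinom(80, 1, 0.6)
  s1 <- lasso_select(x, y, selection_config(repeats = 4, seed = 9))
  s2 <- lasso_select(x, y, selection_config(repeats = 4, seed = 9))
  expect_identical(s1$coefficients, s2$coefficients)
  expect_identical(s1$path, s2$path)
})
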