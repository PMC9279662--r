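test_that("ICC(2,1) matches its defining cases and the ANOVA oracle", {
  set.seed(71)
  subj <- rnorm(30, sd = 2)
  identical_raters <- cbind(subj, subj, subj)
  expect_equal(icc(identical_raters), 1)

  # independent raters: estimates scatter around zero
  null_iccs <- vapply(1:5, function(i) {
    set.seed(700 + i)
    icc(matrix(rnorm(100 * 2), 100, 2))
  }, 0)
  expect_lt(abs(mean(null_iccs)), 0.15)
  expect_lt(max(abs(null_iccs)), 0.4)

  # known variance components: sigma_s^2 = 4, sigma_e^2 = 1 -> ICC 0.8
  set.seed(72)
  s <- rnorm(500, sd = 2)
  ratings <- cbind(s + rnorm(500), s + rnorm(500))
  expect_equal(icc(ratings), 0.8, tolerance = 0.05)

  # mean-squares oracle on random matrices (with rater effects)
  for (r in 1:4) {
    set.seed(80 + r)
    n <- sample(10:60, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n) * 1.5 +
      rep(rnorm(k, sd = 0.5), each = n)
    expect_equal(icc(m), oracle_icc(m), tolerance = 1e-10)
  }

  expect_equal(icc(matrix(3, 5, 2)), 0)  # no variance at all
  expect_error(icc(matrix(1:2, 1, 2)), "subjects")
})

test_that("agreement categories band [0,1] exhaustively", {
  x <- c(-0.5, 0, 0.1, 0.2, 0.21, 0.4, 0.41, 0.6, 0.61, 0.8, 0.81, 1)
  cats <- icc_category(x)
  expect_false(anyNA(cats))
  expect_equal(cats[1], "poor")
  expect_equal(cats[x == 0.6], "moderate")
  expect_equal(cats[x == 0.61], "substantial")
  expect_equal(cats[x == 1], "almost perfect")
})

test_that("re-segmentation jitter drives feature reproducibility", {
  studies <- lapply(1:5, function(i) {
    small_study(sprintf("p%d", i), channels = "T1w", dim3 = c(14, 14, 14),
                radius = 4.5 + 0.3 * i, seed = 200 + i)
  })
  # zero jitter: identical extractions, ICC 1 wherever subjects vary
  rep0 <- perturb_and_compare(studies, mask_jitter_mm = 0, seed = 1, g = 16)
  expect_true(all(rep0$icc[rep0$icc != 0] == 1))
  expect_gt(mean(rep0$icc == 1), 0.9)
  expect_true(all(rep0$pass == (rep0$icc > 0.6)))

  # strong jitter: agreement collapses for boundary-sensitive features
  rep2 <- perturb_and_compare(studies, mask_jitter_mm = 3, seed = 1, g = 16)
  shape2 <- rep2$icc[grepl("morphology", rep2$key)]
  expect_lt(median(shape2), median(rep0$icc[grepl("morphology", rep0$key)]))
  expect_lt(mean(rep2$icc), mean(rep0$icc))
})
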