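small_cfg <- function(n = 6, seed = 1, ...) {
  cohort_config(n_patients = n, volume_shape = c(16, 16, 16),
                tumor_radius_range_mm = c(4, 6),
                channels = c("T1w", "T2w"), seed = seed, ...)
}

test_that("configuration validation enforces the documented invariants", {
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(os_fraction = 1), "os_fraction")
  expect_error(cohort_config(voxel_spacing_mm = c(1, 0, 1)), "spacing")
  expect_error(cohort_config(effect_sizes = list(bogus = 1)), "bogus")
  expect_error(
    cohort_config(volume_shape = c(10, 10, 10),
                  tumor_radius_range_mm = c(4, 8)),
    "radius"
  )
})

test_that("cohorts are bit-identical for a fixed seed", {
  a <- generate_cohort(small_cfg(seed = 42))
  b <- generate_cohort(small_cfg(seed = 42))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$studies[[3]]$channels, b$studies[[3]]$channels)
  expect_identical(a$studies[[3]]$mask, b$studies[[3]]$mask)
  c_ <- generate_cohort(small_cfg(seed = 43))
  expect_false(identical(a$clinical$age, c_$clinical$age))
})

test_that("realized OS prevalence follows the configured rate", {
  # binomial 95% band at n = 100
  cfg <- cohort_config(n_patients = 100, os_fraction = 0.75, seed = 7)
  frac <- mean(!rectomics:::cohort_labels(cfg))
  expect_gt(frac, 0.75 - 1.96 * sqrt(0.75 * 0.25 / 100))
  expect_lt(frac, 0.75 + 1.96 * sqrt(0.75 * 0.25 / 100))
  # law-of-large-numbers check at n = 2000
  cfg2 <- cohort_config(n_patients = 2000, os_fraction = 0.75, seed = 8)
  expect_lt(abs(mean(!rectomics:::cohort_labels(cfg2)) - 0.75), 0.02)
})

test_that("clinical records satisfy their internal invariants", {
  co <- generate_cohort(small_cfg(n = 40, seed = 12))
  cl <- co$clinical
  expect_true(all(cl$positive_ln <= cl$total_ln))
  expect_equal(cl$lnr, cl$positive_ln / cl$total_ln)
  expect_identical(cl$os_5yr, cl$survival_months >= 60)
  expect_true(all(cl$emvi %in% 0:4))
  expect_true(all(cl$cea >= 0))
  expect_true(all(cl$age >= 19 & cl$age <= 89))
  # stage II implies clinically node-negative
  expect_true(all(cl$c_n[cl$stage %in% c("IIA", "IIB")] == "N0"))
  expect_true(all(cl$c_n[!cl$stage %in% c("IIA", "IIB")] != "N0"))
  # nodal counts consistent with pathological stage
  expect_true(all((cl$positive_ln == 0) == (cl$y_n == "N0")))
})

test_that("studies carry 8 consistent channels by default", {
  co <- generate_cohort(cohort_config(n_patients = 2, seed = 3))
  s <- co$studies[[1]]
  expect_named(s$channels, default_channels())
  expect_true(all(vapply(s$channels,
                         function(v) identical(dim(v), dim(s$mask)), TRUE)))
  expect_gt(sum(s$mask), 100)
})

test_that("with zero effects, features are exchangeable between OS groups", {
  # Kolmogorov-Smirnov screen: >= 95% of features non-significant at 0.01
  cfg <- cohort_config(
    n_patients = 60, volume_shape = c(16, 16, 16),
    tumor_radius_range_mm = c(4, 6), channels = c("T1w", "T2w"), seed = 21,
    effect_sizes = list(texture_correlation_length = 0,
                        histogram_skewness_shift = 0,
                        mean_intensity_shift = 0)
  )
  co <- generate_cohort(cfg)
  feats <- extract_cohort(lapply(co$studies, preprocess_study), g = 32)
  y <- co$clinical$os_5yr
  fm <- as.matrix(feats[, -1])
  keep <- apply(fm, 2, sd) > 0
  pvals <- apply(fm[, keep], 2, function(col) {
    suppressWarnings(stats::ks.test(col[y], col[!y])$p.value)
  })
  expect_gt(mean(pvals > 0.01), 0.95)
})
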