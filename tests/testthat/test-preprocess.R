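test_that("znormalize standardizes over the reference region", {
  v <- array(0, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4))
  v[1, 1, 1] <- 1; v[2, 1, 1] <- 3
  m[1, 1, 1] <- m[2, 1, 1] <- TRUE
  out <- znormalize(v, m)
  expect_equal(out[1, 1, 1], -1)
  expect_equal(out[2, 1, 1], 1)

  set.seed(1)
  big <- array(rnorm(1e5, 5, 2), c(100, 100, 10))
  z <- znormalize(big, array(TRUE, dim(big)))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sqrt(mean(z^2)), 1)  # unit population SD by construction
  # idempotence
  expect_equal(znormalize(z, array(TRUE, dim(z))), z, tolerance = 1e-10)

  expect_error(znormalize(array(2, c(3, 3, 3)), array(TRUE, c(3, 3, 3))),
               "zero-variance")
})

test_that("isotropic resampling preserves grids and constants", {
  set.seed(2)
  v <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  m <- array(TRUE, c(6, 5, 4))
  id <- resample_isotropic(v, m, spacing_mm = c(1, 1, 1))
  expect_identical(id$volume, v)

  # 2 mm slab upsampled to 1 mm doubles that axis
  out <- resample_isotropic(v, m, spacing_mm = c(1, 1, 2))
  expect_equal(dim(out$volume), c(6L, 5L, 8L))
  expect_equal(out$spacing_mm, c(1, 1, 1))

  cst <- resample_isotropic(array(7, c(4, 4, 4)), array(TRUE, c(4, 4, 4)),
                            spacing_mm = c(2, 2, 2))
  expect_true(all(cst$volume == 7))

  tiny <- array(FALSE, c(4, 4, 4)); tiny[2, 2, 2] <- TRUE
  expect_error(
    resample_isotropic(v[1:4, 1:4, 1:4], tiny, spacing_mm = c(0.2, 0.2, 0.2),
                       target_spacing = 3),
    "mask"
  )
})

test_that("erosion matches the voxel-wise ball oracle", {
  # solid ball: eroded result nested between the r-1 and r balls
  d <- c(15, 15, 15); ctr <- 8
  g <- expand.grid(x = 1:15, y = 1:15, z = 1:15)
  dist <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2)
  ball5 <- array(dist <= 5, d)
  ball4 <- array(dist <= 4, d)
  er <- erode_mask(ball5, 1, c(1, 1, 1))
  expect_identical(er, oracle_erode(ball5, 1, c(1, 1, 1)))
  expect_true(all(er[!ball5] == FALSE))       # subset of input
  expect_true(all(er[ball4]))                 # contains the r-1 ball

  # random masks against the oracle, several margins
  for (seed in 1:3) {
    set.seed(seed)
    m <- array(runif(10^3) < 0.75, c(10, 10, 10))
    for (margin in c(1, 1.8)) {
      got <- try(erode_mask(m, margin, c(1, 1, 1)), silent = TRUE)
      want <- oracle_erode(m, margin, c(1, 1, 1))
      if (inherits(got, "try-error")) {
        expect_false(any(want))
      } else {
        expect_identical(got, want)
      }
    }
  }

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_error(erode_mask(single, 1, c(1, 1, 1)), "too small")
  expect_identical(erode_mask(ball5, 0, c(1, 1, 1)), ball5)
})

test_that("quantization follows the fixed-bin-count rule", {
  v <- array(0, c(4, 4, 4)); v[] <- 0:63
  q <- quantize(v, array(TRUE, c(4, 4, 4)), g = 64)
  expect_equal(sort(unique(as.vector(q$levels))), 1:64)
  expect_equal(as.vector(q$levels), 1:64)

  cst <- quantize(array(3, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), g = 64)
  expect_true(all(cst$levels == 1))

  # max value lands exactly at level g; monotone in intensity
  set.seed(3)
  v2 <- array(rnorm(125), c(5, 5, 5))
  q2 <- quantize(v2, array(TRUE, c(5, 5, 5)), g = 16)
  expect_equal(q2$levels[which.max(v2)], 16L)
  ord <- order(as.vector(v2))
  expect_true(all(diff(as.vector(q2$levels)[ord]) >= 0))

  # invariance under positive affine rescaling
  q3 <- quantize(2.5 * v2 + 7, array(TRUE, c(5, 5, 5)), g = 16)
  expect_identical(q2$levels, q3$levels)
})

test_that("preprocess_study normalizes, resamples and erodes", {
  s <- small_study(dim3 = c(14, 14, 14), radius = 5)
  p <- preprocess_study(s)
  expect_s3_class(p, "mp_study")
  expect_lt(abs(mean(p$channels$T1w)), 1e-10)
  expect_true(all(p$mask[s$mask == FALSE] == FALSE))
  expect_lt(sum(p$mask), sum(s$mask))
})
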