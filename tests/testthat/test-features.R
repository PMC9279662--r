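test_that("morphology features match analytic shapes", {
  d <- c(26, 26, 26)
  g <- expand.grid(x = 1:26, y = 1:26, z = 1:26)
  dist <- sqrt((g$x - 13.5)^2 + (g$y - 13.5)^2 + (g$z - 13.5)^2)
  ball <- array(dist <= 10, d)
  m <- morphology_features(ball)
  expect_equal(m[["volume"]], sum(ball))
  expect_gte(m[["circularity"]], 0.95)
  expect_lte(m[["circularity"]], 1.0)
  expect_equal(m[["irregularity"]], 1 / m[["circularity"]])
  expect_equal(m[["surface_area"]], 4 * pi * 100, tolerance = 0.05)

  el <- array(((g$x - 13.5) / 9)^2 + ((g$y - 13.5) / 7)^2 +
                ((g$z - 13.5) / 5)^2 <= 1, d)
  expect_gte(morphology_features(el)[["convexity"]], 0.98)

  # non-convex L-shape loses convexity
  L <- array(FALSE, c(20, 20, 20))
  L[3:18, 3:8, 3:8] <- TRUE; L[3:8, 3:18, 3:8] <- TRUE
  expect_lt(morphology_features(L)[["convexity"]], 0.9)

  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  expect_equal(morphology_features(sv)[["volume"]], 1)

  # boundary-touching mask warns about the clipped surface
  touch <- array(FALSE, c(5, 5, 5)); touch[1:3, 2:4, 2:4] <- TRUE
  expect_warning(morphology_features(touch), "boundary")
})

test_that("histogram features follow the pinned conventions", {
  f <- histogram_features(1:100)
  expect_length(f, 14)
  expect_equal(f[["p50"]], 50.5)
  expect_equal(f[["min"]], 1)
  expect_equal(f[["max"]], 100)
  expect_equal(f[["mean"]], 50.5)
  expect_equal(unname(f[paste0("p", seq(10, 90, 10))]),
               unname(quantile(1:100, seq(.1, .9, .1), type = 7)))

  sym <- c(-3, -1, 0, 1, 3)
  expect_lt(abs(histogram_features(sym)[["skewness"]]), 1e-12)

  cst <- histogram_features(rep(2.5, 10))
  expect_equal(cst[["min"]], cst[["max"]])
  expect_equal(cst[["skewness"]], 0)
  expect_equal(cst[["kurtosis"]], 0)

  # invariance to voxel ordering
  set.seed(5)
  x <- rnorm(200)
  expect_identical(histogram_features(x), histogram_features(rev(x)))
})

test_that("GLCM examples match hand enumeration", {
  lev <- array(0L, c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[1, 2, 1] <- 1L
  lev[2, 1, 1] <- 2L; lev[2, 2, 1] <- 2L
  q <- structure(list(levels = lev, mask = lev > 0, g = 2L,
                      spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  m <- glcm_compute(q, 1L, c(0L, 1L, 0L))
  expect_equal(m$p[1, 1], 0.5)
  expect_equal(m$p[2, 2], 0.5)
  expect_equal(sum(m$p), 1)
  expect_equal(m$p, t(m$p))
  f <- glcm_features(m)
  expect_equal(f[["difference_entropy"]], 0)  # all pairs have |i-j| = 0
  expect_equal(f[["maximum_probability"]], 0.5)

  # uniform joint distribution: joint entropy = 2 log2 G bits
  G <- 8
  fu <- glcm_features(matrix(1 / G^2, G, G))
  expect_equal(fu[["joint_entropy"]], 2 * log2(G))

  # constant ROI conventions
  qc <- quantize(array(4, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), g = 8)
  fc <- glcm_direction_means(qc, 1L)
  expect_equal(fc[["maximum_probability"]], 1)
  expect_equal(fc[["contrast"]], 0)
  expect_equal(fc[["correlation"]], 0)
})

test_that("GLRLM examples match hand enumeration", {
  lev <- array(0L, c(4, 1, 1))
  lev[, 1, 1] <- c(1L, 1L, 1L, 2L)
  q <- structure(list(levels = lev, mask = lev > 0, g = 2L,
                      spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  m <- glrlm_compute(q, c(1L, 0L, 0L))
  expect_equal(m$counts[1, 3], 1)  # run (level 1, length 3)
  expect_equal(m$counts[2, 1], 1)  # run (level 2, length 1)
  expect_equal(sum(m$counts), 2)
  f <- glrlm_features(m)
  expect_equal(f[["sre"]], (1 / 9 + 1) / 2)
  expect_equal(f[["lre"]], 5)
  expect_equal(f[["rp"]], 0.5)

  # constant line of length L: single run
  levL <- array(1L, c(6, 1, 1))
  qL <- structure(list(levels = levL, mask = levL > 0, g = 1L,
                       spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  fL <- glrlm_features(glrlm_compute(qL, c(1L, 0L, 0L)))
  expect_equal(fL[["lre"]], 36)
  expect_equal(fL[["rp"]], 1 / 6)

  # checkerboard: all runs length 1
  chk <- array(0L, c(4, 4, 4))
  idx <- which(array(TRUE, c(4, 4, 4)), arr.ind = TRUE)
  chk[] <- ifelse((idx[, 1] + idx[, 2] + idx[, 3]) %% 2 == 0, 1L, 2L)
  qc <- structure(list(levels = chk, mask = chk > 0, g = 2L,
                       spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  expect_equal(glrlm_features(glrlm_compute(qc, c(1L, 0L, 0L)))[["sre"]], 1)
})

test_that("texture engines equal brute-force oracles on random ROIs", {
  dirs <- rectomics:::texture_directions()
  for (seed in 1:4) {
    roi <- random_roi(c(sample(6:16, 1), sample(6:16, 1), sample(6:16, 1)),
                      g = 5, seed = seed)
    np <- sum(roi$mask)
    for (dist in 1:2) {
      got <- rectomics:::glcm_direction_means(roi, dist)
      per_dir <- vapply(seq_len(nrow(dirs)), function(k) {
        cnt <- oracle_glcm_counts(roi$levels, dirs[k, ] * dist, roi$g)
        if (sum(cnt) == 0) return(rep(NA_real_, 22))
        glcm_features(cnt / sum(cnt))
      }, numeric(22))
      want <- rowMeans(per_dir, na.rm = TRUE)
      names(want) <- rectomics:::glcm_feature_names()
      expect_equal(got, want, tolerance = 1e-10)
    }
    got_rl <- glrlm_features(roi)
    want_rl <- rowMeans(vapply(seq_len(nrow(dirs)), function(k) {
      oracle_glrlm_features(
        oracle_glrlm_counts(roi$levels, dirs[k, ], roi$g,
                            max(dim(roi$levels))), np)
    }, numeric(7)))
    expect_equal(got_rl, want_rl, tolerance = 1e-10)
  }
})

test_that("level-relabeling invariance holds where formulas permit", {
  roi <- random_roi(c(8, 8, 8), g = 6, seed = 9)
  rev_roi <- roi
  rev_roi$levels[roi$mask] <- roi$g + 1L - roi$levels[roi$mask]
  f1 <- rectomics:::glcm_direction_means(roi, 1L)
  f2 <- rectomics:::glcm_direction_means(rev_roi, 1L)
  for (nm in c("joint_entropy", "difference_entropy", "sum_entropy",
               "energy", "maximum_probability", "contrast")) {
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-10, info = nm)
  }
  r1 <- glrlm_features(roi)
  r2 <- glrlm_features(rev_roi)
  expect_equal(r1[["sre"]], r2[["sre"]], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(r1[["lgre"]], r2[["lgre"]])))
  expect_false(isTRUE(all.equal(r1[["hgre"]], r2[["hgre"]])))
})

test_that("extraction emits the exact feature layout", {
  ph <- digital_phantom()
  f <- suppressWarnings(extract_features(ph))
  expect_length(f, 4686)
  expect_true(all(is.finite(f)))
  man <- feature_manifest()
  expect_equal(nrow(man), 4686)
  expect_identical(names(f), man$key)
  expect_equal(sum(man$family == "morphology"), 6)
  expect_equal(sum(man$channel == "T2w"), 585)
  expect_equal(sum(man$channel == "T2w" & man$subband != "native"), 520)

  # single-channel layout: 6 + 585
  s1 <- small_study(channels = "T1w", seed = 2)
  f1 <- extract_features(preprocess_study(s1))
  expect_length(f1, 591)

  # identical channels give identical per-channel blocks; repeat runs are
  # bit-stable
  s2 <- small_study(channels = c("A", "B"), seed = 3)
  s2$channels$B <- s2$channels$A
  p2 <- preprocess_study(s2)
  f2 <- extract_features(p2)
  a_block <- f2[grepl("^A\\.", names(f2))]
  b_block <- f2[grepl("^B\\.", names(f2))]
  expect_equal(unname(a_block), unname(b_block))
  expect_identical(f2, extract_features(p2))
})

test_that("the digital phantom has hand-checkable structure", {
  ph <- digital_phantom()
  expect_equal(sum(ph$mask), 64)
  v <- ph$channels$T1w
  q <- quantize(v, ph$mask, g = 4)
  # by construction values 1..4 occupy 16 voxels each
  expect_equal(unname(table(q$levels)), rep(16L, 4), ignore_attr = TRUE)
  # runs along x at z = 1: each line is 1,1,2,2
  m <- glrlm_compute(q, c(1L, 0L, 0L))
  # 8 lines of (1,1,2,2) in z<=2 -> 8 runs of level 1 len 2, 8 of level 2;
  # z>=3: lines constant in x: level 3 where y<=2 (4 lines), 4 elsewhere
  expect_equal(m$counts[1, 2], 8)
  expect_equal(m$counts[2, 2], 8)
  expect_equal(m$counts[3, 4], 4)
  expect_equal(m$counts[4, 4], 4)
})
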