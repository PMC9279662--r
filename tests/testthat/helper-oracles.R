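# Brute-force oracles, written independently of the package internals:
# plain R loops over voxels/pairs/runs, used to pin down the engines.

# co-occurrence counts by explicit pair enumeration (levels: 3D integer
# array, 0 outside the ROI)
oracle_glcm_counts <- function(levels, offset, g) {
  d <- dim(levels)
  counts <- matrix(0, g, g)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l1 <- levels[x, y, z]
    if (l1 == 0) next
    x2 <- x + offset[1]; y2 <- y + offset[2]; z2 <- z + offset[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    l2 <- levels[x2, y2, z2]
    if (l2 == 0) next
    counts[l1, l2] <- counts[l1, l2] + 1
    counts[l2, l1] <- counts[l2, l1] + 1
  }
  counts
}

# run-length counts by walking every maximal run
oracle_glrlm_counts <- function(levels, dir, g, lmax) {
  d <- dim(levels)
  counts <- matrix(0, g, lmax)
  inb <- function(x, y, z) {
    x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3]
  }
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- levels[x, y, z]
    if (l == 0) next
    xp <- x - dir[1]; yp <- y - dir[2]; zp <- z - dir[3]
    if (inb(xp, yp, zp) && levels[xp, yp, zp] == l) next
    len <- 1
    xn <- x + dir[1]; yn <- y + dir[2]; zn <- z + dir[3]
    while (inb(xn, yn, zn) && levels[xn, yn, zn] == l) {
      len <- len + 1
      xn <- xn + dir[1]; yn <- yn + dir[2]; zn <- zn + dir[3]
    }
    counts[l, len] <- counts[l, len] + 1
  }
  counts
}

# Galloway features from a run-length count matrix, written out directly
oracle_glrlm_features <- function(counts, np) {
  nr <- sum(counts)
  g <- nrow(counts); lmax <- ncol(counts)
  sre <- lre <- gln <- rln <- lgre <- hgre <- 0
  for (i in seq_len(g)) {
    ri <- sum(counts[i, ])
    gln <- gln + ri^2
    lgre <- lgre + ri / i^2
    hgre <- hgre + ri * i^2
  }
  for (j in seq_len(lmax)) {
    rj <- sum(counts[, j])
    rln <- rln + rj^2
    sre <- sre + rj / j^2
    lre <- lre + rj * j^2
  }
  c(sre = sre / nr, lre = lre / nr, gln = gln / nr, rln = rln / nr,
    rp = nr / np, lgre = lgre / nr, hgre = hgre / nr)
}

# voxel-wise ball-test erosion
oracle_erode <- function(mask, margin_mm, spacing) {
  d <- dim(mask)
  out <- array(FALSE, d)
  offs <- expand.grid(
    dx = -ceiling(margin_mm):ceiling(margin_mm),
    dy = -ceiling(margin_mm):ceiling(margin_mm),
    dz = -ceiling(margin_mm):ceiling(margin_mm)
  )
  keep <- sqrt((offs$dx * spacing[1])^2 + (offs$dy * spacing[2])^2 +
                 (offs$dz * spacing[3])^2) <= margin_mm + 1e-9
  offs <- offs[keep, ]
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      x2 <- x + offs$dx[k]; y2 <- y + offs$dy[k]; z2 <- z + offs$dz[k]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3] || !mask[x2, y2, z2]) { ok <- FALSE; break }
    }
    out[x, y, z] <- ok
  }
  out
}

# O(n^2) concordance enumeration with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
oracle_fisher_2x2 <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  probs <- vapply(0:min(rs[1], cs[1]), function(a) {
    dhyper(a, cs[1], cs[2], rs[1])
  }, 0)
  p_obs <- dhyper(m[1, 1], cs[1], cs[2], rs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ICC(2,1) from the two-way ANOVA table fitted by aov()
oracle_icc <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(
    y = as.vector(ratings),
    subj = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- anova(aov(y ~ subj + rater, data = df))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# random quantized ROI for texture oracle checks
random_roi <- function(dim3, g, seed, p_mask = 0.7) {
  set.seed(seed)
  lev <- array(0L, dim3)
  m <- array(runif(prod(dim3)) < p_mask, dim3)
  lev[m] <- sample.int(g, sum(m), replace = TRUE)
  structure(list(levels = lev, mask = m, g = g, spacing_mm = c(1, 1, 1)),
            class = "quantized_roi")
}

# small random study for IO / reproducibility tests
small_study <- function(id = "s1", channels = c("T1w", "T2w"),
                        dim3 = c(14, 14, 14), radius = 4.5, seed = 1) {
  set.seed(seed)
  ctr <- dim3 / 2 + 0.5
  g <- expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                   z = seq_len(dim3[3]))
  mask <- array(sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 +
                       (g$z - ctr[3])^2) <= radius, dim3)
  chans <- lapply(setNames(nm = channels), function(ch) {
    v <- array(rnorm(prod(dim3)), dim3)
    v[mask] <- v[mask] + 2
    v
  })
  mp_study(id, chans, mask, c(1, 1, 1))
}
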