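#' Gray-level co-occurrence matrix for one offset
#'
#' Accumulates symmetric co-occurrences of in-ROI voxel pairs separated by
#' `distance * direction` and normalizes to a joint probability matrix.
#'
#' @param q a [quantize()] result (`quantized_roi`).
#' @param distance offset multiplier in voxels (1 or 2).
#' @param direction integer length-3 offset, one of the 13 unique 3D
#'   directions (see `texture_directions()`).
#' @return a `glcmatrix`: list with `counts`, `p` (G x G, sums to 1 when any
#'   pair exists), `distance`, `direction`.
#' @export
glcm_compute <- function(q, distance = 1L, direction = c(1L, 0L, 0L)) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!distance %in% c(1L, 2L)) abort("`distance` must be 1 or 2")
  off <- matrix(as.integer(direction * distance), nrow = 1)
  cnt <- cpp_glcm_counts(as.integer(q$levels), dim(q$levels), off, q$g)
  counts <- matrix(cnt[, 1], q$g, q$g)
  tot <- sum(counts)
  p <- if (tot > 0) counts / tot else counts
  structure(
    list(counts = counts, p = p, distance = distance, direction = direction),
    class = "glcmatrix"
  )
}

# names of the canonical 22-feature GLCM set (x 2 distances = 44 per ROI)
glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "dissimilarity", "energy",
    "joint_entropy", "homogeneity", "imc1", "imc2", "inverse_difference",
    "maximum_probability", "sum_average", "sum_entropy", "sum_variance",
    "variance", "inverse_variance")
}

# All 22 features for each column of P (G^2 x K probability matrices,
# one column per direction). Vectorized across directions; log base 2 with
# the 0*log(0) = 0 convention. Returns 22 x K.
glcm_features_batch <- function(P, G) {
  i <- rep(seq_len(G), times = G)   # row level of cell
  j <- rep(seq_len(G), each = G)    # col level of cell
  K <- ncol(P)
  # column-wise sum of P rows grouped by grp; every group 1..nlev occurs on
  # the full (i, j) grid, so rowsum returns rows in order 1..nlev
  csum <- function(x, grp, nlev) rowsum(x, grp)
  px <- csum(P, i, G)                       # marginal over rows
  diffk <- abs(i - j)                       # 0..G-1
  sumk <- i + j                             # 2..2G
  pdiff <- csum(P, diffk + 1L, G)           # index 1 = k 0
  psum <- csum(P, sumk - 1L, 2L * G - 1L)   # index 1 = k 2
  kd <- 0:(G - 1)
  ks <- 2:(2 * G)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  colS <- function(M) .colSums(M, nrow(M), ncol(M))

  mu <- colS(px * seq_len(G))
  sig2 <- colS(px * (seq_len(G))^2) - mu^2
  ij <- i * j
  ac <- colS(P * ij)
  ipj <- i + j
  dev <- sweep(matrix(ipj, G * G, K), 2, 2 * mu)  # (i + j - 2 mu)
  cl2 <- colS(P * dev^2)
  cl3 <- colS(P * dev^3)
  cl4 <- colS(P * dev^4)
  contrast <- colS(P * (i - j)^2)
  correlation <- ifelse(sig2 > 1e-14, (ac - mu^2) / sig2, 0)
  da <- colS(pdiff * kd)
  de <- -colS(pdiff * lg(pdiff))
  dv <- colS(pdiff * sweep(matrix(kd, G, K), 2, da)^2)
  dissim <- colS(P * abs(i - j))
  energy <- colS(P^2)
  je <- -colS(P * lg(P))
  homog <- colS(P / (1 + (i - j)^2))
  invdiff <- colS(P / (1 + abs(i - j)))
  maxp <- apply(P, 2, max)
  sa <- colS(psum * ks)
  se <- -colS(psum * lg(psum))
  sv <- colS(psum * sweep(matrix(ks, 2 * G - 1, K), 2, sa)^2)
  jointvar <- colS(P * sweep(matrix(i, G * G, K), 2, mu)^2)
  offdiag <- diffk > 0
  invvar <- colS(P[offdiag, , drop = FALSE] /
                   (diffk[offdiag])^2)
  # informational measures of correlation
  pxi <- px[i, , drop = FALSE]  # px expanded to cells (rows)
  pyj <- px[j, , drop = FALSE]  # symmetric matrix: py = px
  hx <- -colS(px * lg(px))
  hxy1 <- -colS(P * lg(pxi * pyj))
  hxy2 <- -colS(pxi * pyj * lg(pxi * pyj))
  imc1 <- ifelse(hx > 1e-14, (je - hxy1) / hx, 0)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - je))))

  out <- rbind(ac, cl4, cl3, cl2, contrast, correlation, da, de, dv,
               dissim, energy, je, homog, imc1, imc2, invdiff, maxp,
               sa, se, sv, jointvar, invvar)
  rownames(out) <- glcm_feature_names()
  out
}

#' GLCM texture features
#'
#' Computes the canonical 22-feature co-occurrence set from one normalized
#' GLCM. In the extraction pipeline these are evaluated per direction and
#' averaged over the 13 directions, separately for distances 1 and 2 (44
#' co-occurrence features per ROI).
#'
#' @param m a `glcmatrix` from [glcm_compute()], or a normalized G x G
#'   probability matrix.
#' @return named numeric vector of 22 features.
#' @export
glcm_features <- function(m) {
  p <- if (inherits(m, "glcmatrix")) m$p else as.matrix(m)
  G <- nrow(p)
  if (ncol(p) != G) abort("GLCM must be square")
  drop(glcm_features_batch(matrix(as.numeric(p), ncol = 1), G))
}

# Mean over 13 directions of the 22 features, for one distance.
# Degenerate directions (no valid pair) are excluded from the average;
# if no direction has pairs the constant-ROI convention applies.
glcm_direction_means <- function(q, distance) {
  dirs <- texture_directions() * distance
  f <- cpp_glcm_dirmean(as.integer(q$levels), dim(q$levels), dirs, q$g)
  if (!anyNA(f)) {
    return(setNames(as.numeric(f), glcm_feature_names()))
  }
  # constant/degenerate ROI: entropy- and contrast-type features 0,
  # correlation-type 0, maximum probability and energy 1
  f <- setNames(numeric(22), glcm_feature_names())
  f["maximum_probability"] <- 1
  f["energy"] <- 1
  mu <- if (any(q$levels > 0)) as.numeric(q$levels[q$levels > 0][1]) else 1
  f["autocorrelation"] <- mu^2
  f["sum_average"] <- 2 * mu
  f["homogeneity"] <- 1
  f["inverse_difference"] <- 1
  f
}
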