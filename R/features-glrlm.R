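#' Gray-level run-length matrix for one direction
#'
#' Counts maximal collinear runs of equal gray level along a direction.
#'
#' @param q a [quantize()] result.
#' @param direction integer length-3 direction vector.
#' @return a `glrlmatrix`: list with `counts` (G x Lmax run counts),
#'   `direction`, `np` (number of in-mask voxels).
#' @export
glrlm_compute <- function(q, direction = c(1L, 0L, 0L)) {
  stopifnot(inherits(q, "quantized_roi"))
  lmax <- max(dim(q$levels))
  cnt <- cpp_glrlm_counts(as.integer(q$levels), dim(q$levels),
                          matrix(as.integer(direction), nrow = 1), q$g, lmax)
  structure(
    list(counts = matrix(cnt[, 1], q$g, lmax), direction = direction,
         np = sum(q$mask)),
    class = "glrlmatrix"
  )
}

glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre")
}

# Galloway features from one run-length count matrix.
glrlm_features_one <- function(r, np) {
  G <- nrow(r); L <- ncol(r)
  nr <- sum(r)
  if (nr == 0) return(setNames(rep(0, 7), glrlm_feature_names()))
  js <- seq_len(L)
  is <- seq_len(G)
  rj <- .colSums(r, G, L)   # runs per length
  ri <- .rowSums(r, G, L)   # runs per level
  c(
    sre  = sum(rj / js^2) / nr,
    lre  = sum(rj * js^2) / nr,
    gln  = sum(ri^2) / nr,
    rln  = sum(rj^2) / nr,
    rp   = nr / np,
    lgre = sum(ri / is^2) / nr,
    hgre = sum(ri * is^2) / nr
  )
}

#' GLRLM texture features
#'
#' The seven Galloway run-length descriptors (SRE, LRE, GLN, RLN, RP, LGRE,
#' HGRE), each computed per direction and averaged over the 13 unique 3D
#' directions.
#'
#' @param q a [quantize()] result, or a single `glrlmatrix` (then no
#'   direction averaging is performed).
#' @return named numeric vector of 7 features.
#' @export
glrlm_features <- function(q) {
  if (inherits(q, "glrlmatrix")) {
    return(glrlm_features_one(q$counts, q$np))
  }
  stopifnot(inherits(q, "quantized_roi"))
  f <- cpp_glrlm_dirmean(as.integer(q$levels), dim(q$levels),
                         texture_directions(), q$g, sum(q$mask))
  setNames(as.numeric(f), glrlm_feature_names())
}
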