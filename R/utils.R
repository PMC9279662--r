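#' Logistic (sigmoid) link
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, the link used by the radiomics score and
#' all logistic risk models.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @export
sigmoid <- function(x) plogis(x)

# The 13 unique 3D offsets (half of the 26-neighbourhood, opposite offsets
# identified). Shared by GLCM and GLRLM engines.
texture_directions <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# Integer offsets inside a ball of radius r (in mm) at the given spacing.
ball_offsets <- function(radius_mm, spacing) {
  rmax <- pmax(0L, as.integer(floor(radius_mm / spacing)))
  g <- expand.grid(
    dx = -rmax[1]:rmax[1], dy = -rmax[2]:rmax[2], dz = -rmax[3]:rmax[3]
  )
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

# Deterministic child seed derived from a parent seed and a stream label.
# Keeps every stochastic stage independently reproducible from one integer.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 1117) %% 2147483629)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

as_array3 <- function(x, name = "volume") {
  if (!(is.array(x) && length(dim(x)) == 3L)) {
    abort(sprintf("`%s` must be a 3D array.", name))
  }
  x
}
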