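#' Z-score intensity normalization
#'
#' Standardizes a volume to mean 0 and standard deviation 1 over a reference
#' region. By default the reference region is the whole-volume nonzero
#' support, so that in-tumor intensity statistics remain informative and are
#' captured later by the histogram features.
#'
#' @param volume 3D numeric array.
#' @param region_mask optional 3D logical array selecting the voxels whose
#'   statistics define the standardization; defaults to `volume != 0`, or the
#'   full volume when everything is zero-free.
#' @return 3D numeric array with mean 0 and sd 1 over `region_mask`.
#' @export
znormalize <- function(volume, region_mask = NULL) {
  volume <- as_array3(volume)
  if (is.null(region_mask)) {
    region_mask <- volume != 0
    if (!any(region_mask)) region_mask <- array(TRUE, dim(volume))
  }
  region_mask <- as_array3(region_mask, "region_mask")
  if (!identical(dim(volume), dim(region_mask))) {
    abort("`volume` and `region_mask` must share dimensions.")
  }
  vals <- volume[region_mask]
  if (length(vals) < 2L) abort("normalization region needs at least 2 voxels")
  mu <- mean(vals)
  s <- sqrt(mean((vals - mu)^2))  # population SD: {1,3} maps to {-1,+1}
  if (!is.finite(s) || s == 0) {
    abort("zero-variance normalization region: degenerate input")
  }
  (volume - mu) / s
}

#' Resample a volume and mask to isotropic spacing
#'
#' Intensities are interpolated trilinearly; the mask is resampled by
#' nearest-neighbour lookup and re-binarized. Output grid size along each
#' axis is `ceiling(extent / target)` so the physical field of view is
#' preserved; sample points sit at voxel centers.
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array on the same grid.
#' @param spacing_mm numeric length-3, input voxel spacing in mm.
#' @param target_spacing target isotropic spacing in mm (default 1).
#' @return list with `volume`, `mask`, and `spacing_mm = rep(target, 3)`.
#' @export
resample_isotropic <- function(volume, mask, spacing_mm, target_spacing = 1.0) {
  volume <- as_array3(volume)
  mask <- as_array3(mask, "mask")
  if (!identical(dim(volume), dim(mask))) abort("volume/mask grid mismatch")
  if (any(spacing_mm <= 0) || target_spacing <= 0) abort("spacing must be positive")
  d <- dim(volume)
  if (all(abs(spacing_mm - target_spacing) < 1e-12)) {
    return(list(volume = volume, mask = mask != 0,
                spacing_mm = rep(target_spacing, 3)))
  }
  out_dim <- pmax(1L, as.integer(ceiling(d * spacing_mm / target_spacing)))
  # voxel-center coordinates of the output grid, in input voxel index units
  coord <- function(ax) {
    ((seq_len(out_dim[ax]) - 0.5) * target_spacing) / spacing_mm[ax] + 0.5
  }
  cx <- coord(1); cy <- coord(2); cz <- coord(3)

  g <- expand.grid(x = cx, y = cy, z = cz)
  x0 <- pmin(pmax(floor(g$x), 1), d[1]); x1 <- pmin(x0 + 1, d[1])
  y0 <- pmin(pmax(floor(g$y), 1), d[2]); y1 <- pmin(y0 + 1, d[2])
  z0 <- pmin(pmax(floor(g$z), 1), d[3]); z1 <- pmin(z0 + 1, d[3])
  fx <- pmin(pmax(g$x - x0, 0), 1)
  fy <- pmin(pmax(g$y - y0, 0), 1)
  fz <- pmin(pmax(g$z - z0, 0), 1)
  at <- function(ix, iy, iz) volume[cbind(ix, iy, iz)]
  vout <-
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    at(x1, y1, z0) * fx       * fy       * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx       * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy       * fz +
    at(x1, y1, z1) * fx       * fy       * fz
  xn <- pmin(pmax(round(g$x), 1), d[1])
  yn <- pmin(pmax(round(g$y), 1), d[2])
  zn <- pmin(pmax(round(g$z), 1), d[3])
  mout <- mask[cbind(xn, yn, zn)] != 0
  if (!any(mout)) abort("resampling emptied the mask")
  list(volume = array(vout, out_dim), mask = array(mout, out_dim),
       spacing_mm = rep(target_spacing, 3))
}

#' Erode a binary mask by a metric margin
#'
#' Morphological erosion with a discrete ball: a voxel survives when every
#' voxel whose center lies within `margin_mm` of it (at the given spacing)
#' belongs to the mask; the volume border counts as background.
#'
#' @param mask 3D logical array.
#' @param margin_mm erosion margin in mm (default 1, matching a 1-mm pullback
#'   from the segmented border).
#' @param spacing_mm voxel spacing, numeric length-3.
#' @return eroded logical array, a subset of `mask`.
#' @export
erode_mask <- function(mask, margin_mm = 1.0, spacing_mm = c(1, 1, 1)) {
  mask <- as_array3(mask, "mask") != 0
  if (margin_mm < 0) abort("`margin_mm` must be >= 0")
  if (margin_mm == 0) return(mask)
  off <- ball_offsets(margin_mm, spacing_mm)
  out <- cpp_erode(as.logical(mask), dim(mask), off)
  out <- array(out, dim(mask))
  if (!any(out)) abort("tumor too small for the erosion margin")
  out
}

#' Quantize in-mask intensities to G gray levels
#'
#' Fixed-bin-count quantization over the in-mask intensity range:
#' `level = min(G, floor(G * (x - min) / (max - min)) + 1)`. A constant
#' region maps to level 1. Levels are 0 outside the mask.
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array.
#' @param g number of gray levels (default 64).
#' @param spacing_mm isotropic voxel spacing carried along for texture
#'   bookkeeping.
#' @return a `quantized_roi` object: list with `levels` (3D integer array),
#'   `mask`, `g`, `spacing_mm`.
#' @export
quantize <- function(volume, mask, g = 64L, spacing_mm = c(1, 1, 1)) {
  volume <- as_array3(volume)
  mask <- as_array3(mask, "mask") != 0
  if (!identical(dim(volume), dim(mask))) abort("volume/mask grid mismatch")
  if (!any(mask)) abort("empty mask")
  g <- as.integer(g)
  if (g < 2L) abort("`g` must be >= 2")
  vals <- volume[mask]
  lo <- min(vals); hi <- max(vals)
  lev <- array(0L, dim(volume))
  if (hi - lo <= 0) {
    lev[mask] <- 1L
  } else {
    lev[mask] <- pmin(g, as.integer(floor(g * (vals - lo) / (hi - lo))) + 1L)
  }
  structure(
    list(levels = lev, mask = mask, g = g, spacing_mm = spacing_mm),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf(
    "<quantized_roi> %s grid, %d gray levels, %d ROI voxels\n",
    paste(dim(x$levels), collapse = "x"), x$g, sum(x$mask)
  ))
  invisible(x)
}
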