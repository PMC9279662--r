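#' Shape (morphology) features of a tumor mask
#'
#' Six 3D shape descriptors computed once per patient from the (eroded)
#' tumor mask:
#' \itemize{
#'   \item `volume`: voxel count times voxel volume (mm^3);
#'   \item `surface_area`: area of the 0.5-isosurface mesh obtained by
#'     marching tetrahedra (mm^2);
#'   \item `circularity` (sphericity): `pi^(1/3) * (6 V)^(2/3) / A`, 1 for a
#'     perfect sphere;
#'   \item `compactness`: `V / (sqrt(pi) * A^(3/2))`;
#'   \item `convexity`: `V / V_hull`, with the convex hull taken over the
#'     corners of the boundary voxels (so convexity <= 1);
#'   \item `irregularity`: `A / A_sphere`, the surface area relative to the
#'     sphere of equal volume (the reciprocal of sphericity).
#' }
#'
#' @param mask 3D logical array.
#' @param spacing_mm isotropic voxel spacing (mm).
#' @return named numeric vector of 6 features.
#' @export
morphology_features <- function(mask, spacing_mm = c(1, 1, 1)) {
  mask <- as_array3(mask, "mask") != 0
  if (!any(mask)) abort("empty mask")
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (any(idx[, 1] %in% c(1L, d[1])) || any(idx[, 2] %in% c(1L, d[2])) ||
      any(idx[, 3] %in% c(1L, d[3]))) {
    warn("mask touches the volume boundary; surface estimate is clipped")
  }
  voxvol <- prod(spacing_mm)
  V <- sum(mask) * voxvol
  # mesh the 0.5-level set of the lightly smoothed indicator: linear
  # interpolation then gives a sub-voxel surface instead of a blocky one
  field <- gaussian_smooth3(array(as.numeric(mask), d), 1.0)
  mesh <- cpp_surface_mesh(as.numeric(field), d, as.numeric(spacing_mm), 0.5)
  if (mesh[1] <= 0) {  # mask too small to survive smoothing: mesh it raw
    mesh <- cpp_surface_mesh(as.numeric(mask), d, as.numeric(spacing_mm), 0.5)
  }
  A <- mesh[1]
  Vm <- mesh[2]
  # boundary voxels: any face-neighbour missing
  bnd <- mask & !array(cpp_erode(as.logical(mask), d,
                                 rbind(c(1,0,0), c(-1,0,0), c(0,1,0),
                                       c(0,-1,0), c(0,0,1), c(0,0,-1))), d)
  if (!any(bnd)) bnd <- mask
  bidx <- which(bnd, arr.ind = TRUE)
  pts <- cbind(bidx[, 1] * spacing_mm[1], bidx[, 2] * spacing_mm[2],
               bidx[, 3] * spacing_mm[3])
  # discrete convexity: fraction of voxel centers inside the convex hull of
  # the (boundary) voxel centers that belong to the mask -- exactly 1 for a
  # digitized convex body, < 1 when the hull covers non-mask voxels
  bb <- apply(idx, 2, range)
  grid <- as.matrix(expand.grid(x = bb[1, 1]:bb[2, 1],
                                y = bb[1, 2]:bb[2, 2],
                                z = bb[1, 3]:bb[2, 3]))
  gpts <- sweep(grid, 2, spacing_mm, "*")
  inhull <- cpp_hull_contains(pts, gpts)
  n_hull <- sum(inhull)
  sphericity <- pi^(1 / 3) * (6 * Vm)^(2 / 3) / A
  c(
    volume = V,
    surface_area = A,
    circularity = sphericity,
    compactness = Vm / (sqrt(pi) * A^1.5),
    convexity = if (n_hull > 0) sum(mask) / n_hull else 1,
    irregularity = 1 / sphericity
  )
}
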