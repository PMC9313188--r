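#' Analysis grids: voxel lattice, affine, and brain mask
#'
#' A `brain_grid` couples a 3D lattice shape, a 4x4 affine mapping 0-based
#' voxel indices (i,j,k,1) to RAS millimetre coordinates (x,y,z,1), and a
#' logical mask selecting the in-brain voxels on which all maps live.
#'
#' @param shape integer vector of length 3, lattice dimensions.
#' @param affine numeric 4x4 matrix; must be invertible with non-zero
#'   spatial determinant.
#' @param mask logical array of dimension `shape` with at least one `TRUE`.
#' @return An object of class `brain_grid` with elements `shape`, `affine`,
#'   `mask`, and `voxel_volume_mm3`.
#' @export
brain_grid <- function(shape, affine, mask) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_cbma("grid shape must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop_cbma("affine must be a 4x4 matrix")
  detsp <- det(affine[1:3, 1:3])
  if (!is.finite(detsp) || abs(detsp) < .Machine$double.eps)
    stop_cbma("affine is not invertible")
  if (!is.logical(mask) || !identical(dim(mask), shape))
    stop_cbma("mask must be a logical array of the grid shape")
  if (!any(mask)) stop_cbma("mask is empty")
  structure(
    list(shape = shape, affine = affine, mask = mask,
         voxel_volume_mm3 = abs(detsp)),
    class = "brain_grid")
}

#' @export
print.brain_grid <- function(x, ...) {
  cat(sprintf("brain_grid: %d x %d x %d, %.3g mm^3/voxel, %d in-mask voxels\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_volume_mm3,
              sum(x$mask)))
  invisible(x)
}

#' Map voxel indices to millimetre coordinates and back
#'
#' Indices are 0-based, following the NIfTI convention the affine is
#' defined on. `mm_to_voxel` rounds to the nearest voxel half-up per axis.
#'
#' @param grid a `brain_grid`.
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @param xyz numeric matrix (n x 3) of mm coordinates.
#' @return An n x 3 matrix.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  out <- cbind(ijk, 1) %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  ijk <- cbind(xyz, 1) %*% t(solve(grid$affine))
  round_half_up(ijk[, 1:3, drop = FALSE])
}

# 1-based linear index into the lattice array from 0-based ijk rows;
# NA for indices off the lattice.
ijk_to_linear <- function(grid, ijk) {
  d <- grid$shape
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
        ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
  out <- rep(NA_integer_, nrow(ijk))
  out[ok] <- 1L + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])
  out
}

linear_to_ijk <- function(grid, lin) {
  d <- grid$shape
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i = i, j = j, k = k)
}

# mm coordinates of in-mask voxel centres (rows align with which(grid$mask))
mask_mm_coords <- function(grid) {
  lin <- which(grid$mask)
  voxel_to_mm(grid, linear_to_ijk(grid, lin))
}

#' Build or load the analysis grid
#'
#' Either reads a NIfTI-1 mask volume (non-zero voxels are in-mask) or
#' builds a synthetic MNI-like grid with an ellipsoidal brain mask, so the
#' package runs with no atlas download. The synthetic default emulates the
#' MNI152 2 mm lattice: shape 91 x 109 x 91, 2 mm isotropic spacing,
#' RAS affine with origin at (-90, -126, -72).
#'
#' @param source path to a NIfTI-1 mask file, or `NULL` to build the
#'   synthetic mask from `shape`, `spacing_mm`, `center_mm`, `radii_mm`.
#' @param shape,spacing_mm,center_mm,radii_mm synthetic-mask parameters:
#'   lattice shape, isotropic voxel size in mm, ellipsoid centre (mm) and
#'   semi-axes (mm).
#' @return A [brain_grid()].
#' @export
load_or_make_grid <- function(source = NULL,
                              shape = c(91L, 109L, 91L),
                              spacing_mm = 2,
                              center_mm = c(0, -17, 8),
                              radii_mm = c(72, 86, 78)) {
  if (!is.null(source)) {
    if (!file.exists(source)) stop_cbma("mask file not found: %s", source)
    img <- RNifti::readNifti(source)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop_cbma("mask volume must be 3D")
    affine <- unclass(RNifti::xform(img))
    attributes(affine) <- list(dim = c(4L, 4L))
    return(brain_grid(dim(arr), affine, arr != 0))
  }
  shape <- as.integer(shape)
  affine <- diag(c(rep(spacing_mm, 3), 1))
  # centre the lattice so mm (0,0,0) falls on a voxel centre
  affine[1:3, 4] <- -spacing_mm * floor(shape / 2)
  g0 <- list(shape = shape, affine = affine)
  class(g0) <- "brain_grid"
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  mm <- voxel_to_mm(g0, idx)
  u <- sweep(mm, 2, center_mm)
  u <- sweep(u, 2, radii_mm, "/")
  mask <- array(rowSums(u^2) <= 1, dim = shape)
  brain_grid(shape, affine, mask)
}

#' Write a value lattice as a NIfTI-1 volume
#'
#' Values outside the grid mask are written as 0.
#'
#' @param values numeric array matching the grid shape.
#' @param grid a [brain_grid()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path) {
  if (!identical(dim(values), grid$shape) &&
      !identical(as.integer(dim(values)), grid$shape))
    stop_cbma("values shape does not match grid shape")
  out <- array(0, dim = grid$shape)
  out[grid$mask] <- values[grid$mask]
  img <- RNifti::asNifti(out)
  sp <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- sp
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write the grid mask itself as a NIfTI-1 volume
#' @inheritParams write_volume
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  write_volume(array(as.numeric(grid$mask), dim = grid$shape), grid, path)
}

#' Resample a grid to a coarser isotropic spacing
#'
#' Builds a new lattice over the same mm bounding box with the requested
#' spacing; the mask is carried over by nearest-neighbour lookup at the new
#' voxel centres. Used to build the LDA vocabulary grid (default 4 mm).
#'
#' @param grid a [brain_grid()] with axis-aligned affine.
#' @param spacing_mm new isotropic voxel size in mm.
#' @return A [brain_grid()].
#' @export
resample_grid <- function(grid, spacing_mm) {
  old_sp <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  f <- spacing_mm / old_sp
  shape <- pmax(1L, as.integer(ceiling(grid$shape / f)))
  affine <- grid$affine
  affine[1:3, 1:3] <- affine[1:3, 1:3] %*% diag(f)
  g0 <- list(shape = shape, affine = affine)
  class(g0) <- "brain_grid"
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  mm <- voxel_to_mm(g0, idx)
  old_ijk <- mm_to_voxel(grid, mm)
  lin <- ijk_to_linear(grid, old_ijk)
  inmask <- !is.na(lin) & grid$mask[ifelse(is.na(lin), 1L, lin)]
  brain_grid(shape, affine, array(inmask, dim = shape))
}
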