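#' Read a NIfTI-1 volume
#'
#' Thin wrapper around [RNifti::readNifti()] returning a `voxel_grid`: the
#' voxel array plus voxel spacing (mm) and the qform/sform affine, which are
#' required downstream for physical-distance and volume computations.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask Logical; if `TRUE` the volume is validated as a binary mask
#'   (values strictly in \{0, 1\}).
#' @return A `voxel_grid` object: list with `data` (numeric array), `spacing`
#'   (mm per voxel along each axis) and `affine` (4x4 matrix).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) {
    stop("volume file does not exist: ", path)
  }
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < length(dim(img)) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("voxel spacing metadata absent or invalid in ", path,
         "; refusing distance/volume computations")
  }
  grid <- voxel_grid(as.array(img), spacing = spacing[seq_along(dim(img))],
                     affine = structure(RNifti::xform(img), code = NULL))
  if (mask) validate_mask(grid)
  grid
}

#' Write a voxel grid to a NIfTI-1 file
#'
#' @param grid A `voxel_grid` (or bare array, assumed 1 mm isotropic).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_volume <- function(grid, path) {
  if (is.array(grid) && !inherits(grid, "voxel_grid")) {
    grid <- voxel_grid(grid)
  }
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a voxel grid container
#'
#' @param data Numeric array (2-D or 3-D).
#' @param spacing Voxel edge lengths in mm, one per array dimension.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(data, spacing = rep(1, length(dim(data))),
                       affine = NULL) {
  stopifnot(is.array(data))
  if (length(spacing) != length(dim(data))) {
    stop("spacing must supply one value per array dimension")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be strictly positive")
  }
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Validate that a grid is a binary mask
#'
#' @param grid A `voxel_grid`.
#' @return The grid, invisibly; errors if any voxel is outside \{0, 1\}.
#' @export
validate_mask <- function(grid) {
  vals <- unique(as.vector(grid$data))
  if (!all(vals %in% c(0, 1))) {
    stop("mask declared binary but contains values other than {0, 1}: ",
         paste(utils::head(setdiff(vals, c(0, 1)), 5), collapse = ", "))
  }
  invisible(grid)
}

#' Voxel volume in cubic millimetres
#' @param grid A `voxel_grid`.
#' @return Scalar product of the voxel spacings (mm^3 for 3-D grids).
#' @export
voxel_volume <- function(grid) prod(grid$spacing)
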