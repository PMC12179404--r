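#' Define a diffusivity-volume set with ALPS ROI placement
#'
#' Bundles co-registered directional diffusivity maps (apparent diffusivity
#' along the scanner x, y and z axes, mm^2/s) with the per-hemisphere ROI
#' specification used by the perivascular-space diffusivity index. Each ROI
#' is a square of in-plane voxels (default 3 x 3, i.e. nine voxels) on a
#' single slice, placed on the projection-fibre and association-fibre
#' regions at the level of the deep medullary veins.
#'
#' @param dx,dy,dz `voxel_grid`s (or arrays) of directional diffusivity;
#'   identical shape and spacing.
#' @param rois Named list with elements `left` and `right`; each a list with
#'   elements `proj` and `assoc`, each an integer matrix of 1-based voxel
#'   indices (rows = voxels, 3 columns) as produced by [square_roi()].
#' @return A `diffusivity_volumes` object.
#' @export
diffusivity_volumes <- function(dx, dy, dz, rois) {
  to_grid <- function(g) if (inherits(g, "voxel_grid")) g else voxel_grid(g)
  dx <- to_grid(dx); dy <- to_grid(dy); dz <- to_grid(dz)
  if (!identical(dim(dx$data), dim(dy$data)) ||
      !identical(dim(dx$data), dim(dz$data))) {
    stop("dx, dy, dz maps must share a common shape")
  }
  if (min(dx$data, dy$data, dz$data) < 0) {
    stop("diffusivities must be non-negative")
  }
  for (side in c("left", "right")) {
    if (is.null(rois[[side]]) || is.null(rois[[side]]$proj) ||
        is.null(rois[[side]]$assoc)) {
      stop("ROI specification must provide proj and assoc for side '", side, "'")
    }
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    if (length(intersect(key(rois[[side]]$proj), key(rois[[side]]$assoc)))) {
      stop("projection and association ROIs overlap on side '", side, "'")
    }
  }
  structure(list(dx = dx, dy = dy, dz = dz, rois = rois),
            class = "diffusivity_volumes")
}

#' Build a square in-plane ROI voxel set
#'
#' @param center Integer vector (i, j, k): 1-based voxel index of the ROI
#'   centre.
#' @param half_width Integer; the ROI spans `2*half_width + 1` voxels per
#'   in-plane axis (default 1, a 3 x 3 = nine-voxel square).
#' @return Integer matrix of voxel indices, one row per ROI voxel.
#' @export
square_roi <- function(center, half_width = 1L) {
  stopifnot(length(center) == 3)
  offs <- seq.int(-half_width, half_width)
  as.matrix(expand.grid(i = center[1] + offs, j = center[2] + offs,
                        k = center[3]))
}

#' Extract the four ROI diffusivity means for one hemisphere
#'
#' Arithmetic means of the required directional maps over the projection and
#' association ROIs: Dx and Dy over the projection-fibre ROI, Dx and Dz over
#' the association-fibre ROI.
#'
#' @param vols A `diffusivity_volumes` object.
#' @param side `"left"` or `"right"`.
#' @return Named list: `dx_proj`, `dy_proj`, `dx_assoc`, `dz_assoc`,
#'   `n_voxels`.
#' @export
extract_roi_diffusivities <- function(vols, side = c("left", "right")) {
  side <- match.arg(side)
  roi <- vols$rois[[side]]
  shp <- dim(vols$dx$data)
  roi_mean <- function(map, vox) {
    if (any(vox < 1) || any(vox[, 1] > shp[1]) || any(vox[, 2] > shp[2]) ||
        any(vox[, 3] > shp[3])) {
      stop("ROI extends outside the volume on side '", side, "'")
    }
    mean(map[vox])
  }
  list(dx_proj  = roi_mean(vols$dx$data, roi$proj),
       dy_proj  = roi_mean(vols$dy$data, roi$proj),
       dx_assoc = roi_mean(vols$dx$data, roi$assoc),
       dz_assoc = roi_mean(vols$dz$data, roi$assoc),
       n_voxels = c(proj = nrow(roi$proj), assoc = nrow(roi$assoc)))
}

#' Compute the DTI-ALPS index
#'
#' Per hemisphere, the index is the ratio
#' `(Dx_proj + Dx_assoc) / (Dy_proj + Dz_assoc)` of mean diffusivities
#' perpendicular-to-fibre-but-along-perivascular-space (numerator) to
#' perpendicular-to-both (denominator). Values near 1 indicate isotropic
#' diffusion; lower values are read as impaired perivascular transport.
#'
#' @param vols A `diffusivity_volumes` object with both hemisphere ROIs.
#' @return An `alps_result`: list with `left`, `right`, `bilateral_avg`, and
#'   `roi_means` (per-hemisphere list of the four means).
#' @export
alps <- function(vols) {
  res <- lapply(c(left = "left", right = "right"), function(side) {
    m <- extract_roi_diffusivities(vols, side)
    den <- m$dy_proj + m$dz_assoc
    idx <- if (den <= 0) NA_real_ else (m$dx_proj + m$dx_assoc) / den
    list(index = idx, means = m, degenerate = den <= 0)
  })
  if (res$left$degenerate || res$right$degenerate) {
    warning("zero denominator: ALPS index undefined for at least one hemisphere")
  }
  structure(list(left = res$left$index, right = res$right$index,
                 bilateral_avg = mean(c(res$left$index, res$right$index)),
                 roi_means = list(left = res$left$means,
                                  right = res$right$means)),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("ALPS index: left %.4f, right %.4f, bilateral average %.4f\n",
              x$left, x$right, x$bilateral_avg))
  invisible(x)
}
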