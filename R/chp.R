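#' Choroid plexus volumetric ratios
#'
#' Volumes are voxel counts times voxel volume; the inflow-side markers are
#' the ratios of choroid plexus volume to lateral-ventricle volume and to
#' intracranial volume.
#'
#' @param chp_mask,latvent_mask Binary `voxel_grid`s with common spacing.
#' @param icv Intracranial volume in mm^3.
#' @param subtract_chp Logical; subtract ChP voxels from the
#'   lateral-ventricle volume before forming the ratio (default `FALSE`).
#' @return List: `chp_volume`, `latvent_volume`, `icv`, `chp_latvent`,
#'   `chp_icv` (volumes in mm^3).
#' @export
chp_ratios <- function(chp_mask, latvent_mask, icv, subtract_chp = FALSE) {
  to_grid <- function(g) if (inherits(g, "voxel_grid")) g else voxel_grid(g)
  chp_mask <- to_grid(chp_mask); latvent_mask <- to_grid(latvent_mask)
  validate_mask(chp_mask); validate_mask(latvent_mask)
  if (!isTRUE(all.equal(chp_mask$spacing, latvent_mask$spacing))) {
    stop("ChP and lateral-ventricle masks must share a voxel spacing")
  }
  if (icv <= 0) stop("intracranial volume must be positive")
  vv <- voxel_volume(chp_mask)
  chp_v <- sum(chp_mask$data) * vv
  lat_v <- sum(latvent_mask$data) * vv
  if (subtract_chp) {
    lat_v <- lat_v - sum(chp_mask$data * latvent_mask$data) * vv
  }
  if (lat_v <= 0) stop("lateral-ventricle volume is zero; ratio undefined")
  list(chp_volume = chp_v, latvent_volume = lat_v, icv = icv,
       chp_latvent = chp_v / lat_v, chp_icv = chp_v / icv)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed model, single measure, absolute agreement
#' (McGraw and Wong's ICC(A,1)):
#' `(MS_rows - MS_err) / (MS_rows + (k-1) MS_err + (k/n)(MS_cols - MS_err))`
#' from the two-way ANOVA decomposition of an `n x k` ratings matrix
#' (targets x raters/methods).
#'
#' @param ratings Numeric matrix, `n >= 2` targets by `k >= 2` raters,
#'   complete.
#' @return List: `icc`, `ms_rows`, `ms_cols`, `ms_err`, `n`, `k`.
#' @export
icc_a1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings))) stop("ratings matrix must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ss_tot < 1e-300) stop("constant ratings matrix: ICC undefined")
  denom <- ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err)
  list(icc = (ms_rows - ms_err) / denom,
       ms_rows = ms_rows, ms_cols = ms_cols, ms_err = ms_err, n = n, k = k)
}

#' Bilateral ChP permeability summary
#'
#' Arithmetic means of semiquantitative and kinetic permeability indices
#' over the left and right choroid plexus.
#'
#' @param left,right Named lists (or vectors) holding `wash_in`, `auc`,
#'   `ktrans` for one side each.
#' @return Named list of bilateral means.
#' @export
chp_permeability <- function(left, right) {
  lapply(stats::setNames(nm = c("wash_in", "auc", "ktrans")), function(f) {
    mean(c(left[[f]], right[[f]]))
  })
}
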