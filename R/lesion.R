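#' Bundle lesion and ventricle masks into a scene
#'
#' @param lesion_mask,ventricle_mask Binary `voxel_grid`s (or arrays) of
#'   identical shape and spacing.
#' @return A `lesion_scene` object.
#' @export
lesion_scene <- function(lesion_mask, ventricle_mask) {
  to_grid <- function(g) if (inherits(g, "voxel_grid")) g else voxel_grid(g)
  lesion_mask <- to_grid(lesion_mask); ventricle_mask <- to_grid(ventricle_mask)
  validate_mask(lesion_mask); validate_mask(ventricle_mask)
  if (!identical(dim(lesion_mask$data), dim(ventricle_mask$data))) {
    stop("lesion and ventricle masks must share a common shape")
  }
  if (!isTRUE(all.equal(lesion_mask$spacing, ventricle_mask$spacing))) {
    stop("lesion and ventricle masks must share a common voxel spacing")
  }
  structure(list(lesion = lesion_mask, ventricle = ventricle_mask,
                 spacing = lesion_mask$spacing),
            class = "lesion_scene")
}

# 26-connectivity flood fill over a binary array; returns an integer label
# array (0 = background). Labels are provisional (discovery order).
label_array_26 <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  lab <- array(0L, dims)
  fg <- which(mask != 0)
  if (!length(fg)) return(lab)
  inmask <- array(FALSE, dims); inmask[fg] <- TRUE
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      ci <- arrayInd(frontier, dims)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o) {
        sweep(ci, 2, offs[o, ], "+")
      }))
      keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
              nb[, 2] >= 1 & nb[, 2] <= dims[2] &
              nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- unique(nb[, 1] + dims[1] * (nb[, 2] - 1L) +
                    dims[1] * dims[2] * (nb[, 3] - 1L))
      lin <- lin[inmask[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}

#' Label connected white-matter-hyperintensity components
#'
#' Components are found under 26-connectivity (face, edge and corner
#' neighbours) and relabelled by descending volume, ties broken by
#' lexicographic centroid order.
#'
#' @param scene A `lesion_scene`.
#' @return List with `labels` (integer array) and `lesions`, a data frame
#'   (one row per component: `label`, `voxels`, `volume` in mm^3) to be
#'   completed by [morphometry()].
#' @export
label_components <- function(scene) {
  lab <- label_array_26(scene$lesion$data)
  n <- max(lab)
  if (n == 0) {
    return(list(labels = lab,
                lesions = data.frame(label = integer(0), voxels = integer(0),
                                     volume = numeric(0))))
  }
  vv <- voxel_volume(scene$lesion)
  info <- lapply(seq_len(n), function(l) {
    idx <- which(lab == l)
    ci <- arrayInd(idx, dim(lab))
    cen <- colMeans(ci)
    list(voxels = length(idx), centroid = cen)
  })
  vox <- vapply(info, `[[`, integer(1), "voxels")
  cent <- do.call(rbind, lapply(info, `[[`, "centroid"))
  ord <- order(-vox, cent[, 1], cent[, 2], cent[, 3])
  relab <- integer(n); relab[ord] <- seq_len(n)
  lab[lab > 0] <- relab[lab[lab > 0]]
  list(labels = lab,
       lesions = data.frame(label = seq_len(n), voxels = vox[ord],
                            volume = vox[ord] * vv))
}

# Felzenszwalb-Huttenlocher 1-D squared distance transform with sample
# spacing h. f is the squared-distance column; Inf is represented by BIG.
dt1d <- function(f, h) {
  n <- length(f)
  if (n == 1) return(f)
  BIG <- 1e30
  f <- pmin(f, BIG)
  x <- (seq_len(n) - 1) * h
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1] < x[q]) j <- j + 1L
    p <- v[j]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

#' Euclidean distance transform of a binary mask
#'
#' Exact Euclidean distance (mm) from every voxel centre to the nearest
#' foreground voxel centre, honouring anisotropic voxel spacing, via the
#' separable lower-envelope algorithm.
#'
#' @param grid Binary `voxel_grid` (foreground = 1).
#' @return Numeric array of distances in mm (0 inside the foreground).
#' @export
distance_transform <- function(grid) {
  mask <- grid$data
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  if (!any(mask != 0)) stop("distance transform of an empty mask is undefined")
  d2 <- array(ifelse(mask != 0, 0, 1e30), dims)
  for (ax in 1:3) {
    h <- grid$spacing[ax]
    d2 <- apply(d2, setdiff(1:3, ax), dt1d, h = h)
    # apply() returns the transformed axis first; restore original order
    perm <- order(c(ax, setdiff(1:3, ax)))
    d2 <- aperm(array(d2, dim = c(dims[ax], dims[setdiff(1:3, ax)])), perm)
  }
  sqrt(d2)
}

#' Compute per-lesion morphometry
#'
#' Fills, for every labelled lesion: centre of mass (mm, 0-based voxel-centre
#' convention), minimum Euclidean distance from any lesion voxel to the
#' ventricular system (mm, via the distance transform of the ventricle mask),
#' and the three principal axis lengths (mm, descending) of the
#' moment-equivalent ellipsoid, i.e. `2 * sqrt(5 * lambda)` for the
#' eigenvalues `lambda` of the voxel-coordinate covariance, which recovers
#' the full axis lengths of a solid ellipsoid exactly in the continuum limit.
#'
#' @param labelled Output of [label_components()].
#' @param scene The `lesion_scene` the labels came from.
#' @return Data frame: `label`, `voxels`, `volume`, `centroid_x/y/z`,
#'   `min_distance`, `axis1/2/3`.
#' @export
morphometry <- function(labelled, scene) {
  if (!any(scene$ventricle$data != 0)) {
    stop("empty ventricle mask: distances to the ventricular system undefined")
  }
  les <- labelled$lesions
  if (nrow(les) == 0) {
    les[c("centroid_x", "centroid_y", "centroid_z", "min_distance",
          "axis1", "axis2", "axis3")] <- numeric(0)
    return(les)
  }
  dt <- distance_transform(scene$ventricle)
  sp <- scene$spacing
  geo <- lapply(les$label, function(l) {
    idx <- which(labelled$labels == l)
    ci <- arrayInd(idx, dim(labelled$labels))
    # voxel centre of 1-based index i sits at (i - 1) * spacing
    xyz <- sweep(ci - 1, 2, sp, "*")
    cen <- colMeans(xyz)
    cv <- stats::cov(xyz) * (nrow(xyz) - 1) / nrow(xyz)  # population moments
    if (nrow(xyz) == 1) cv <- matrix(0, 3, 3)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
    c(cen, min(dt[idx]), 2 * sqrt(5 * ev))
  })
  geo <- do.call(rbind, geo)
  les$centroid_x <- geo[, 1]; les$centroid_y <- geo[, 2]; les$centroid_z <- geo[, 3]
  les$min_distance <- geo[, 4]
  les$axis1 <- geo[, 5]; les$axis2 <- geo[, 6]; les$axis3 <- geo[, 7]
  les
}

#' Partition lesions into periventricular and deep classes
#'
#' Lesions whose minimum distance to the ventricular system is within the
#' threshold (inclusive) are periventricular; the rest are deep.
#'
#' @param lesions Morphometry data frame from [morphometry()].
#' @param threshold_mm Distance threshold in mm (default 8).
#' @return List with `lesions` (input plus a `class` column) and `volumes`
#'   (named: `pwmh`, `dwmh`, `total`, in mm^3).
#' @export
classify_lesions <- function(lesions, threshold_mm = 8) {
  stopifnot(threshold_mm > 0)
  cls <- ifelse(lesions$min_distance <= threshold_mm, "periventricular", "deep")
  lesions$class <- factor(cls, levels = c("periventricular", "deep"))
  pv <- sum(lesions$volume[lesions$class == "periventricular"])
  dp <- sum(lesions$volume[lesions$class == "deep"])
  list(lesions = lesions,
       volumes = c(pwmh = pv, dwmh = dp, total = pv + dp))
}

#' Map Fazekas scores to severity groups
#'
#' The periventricular and deep scores (0-3 each) are summed; total 0 is
#' `HC`, 1-3 `mild`, 4-6 `severe`.
#'
#' @param pwmh_score,dwmh_score Integer vectors in 0-3.
#' @param total Optional precomputed total (0-6); overrides the scores.
#' @return Factor with levels `HC`, `mild`, `severe`.
#' @export
fazekas_group <- function(pwmh_score = NULL, dwmh_score = NULL, total = NULL) {
  if (is.null(total)) {
    if (any(pwmh_score < 0 | pwmh_score > 3, na.rm = TRUE) ||
        any(dwmh_score < 0 | dwmh_score > 3, na.rm = TRUE)) {
      stop("Fazekas sub-scores must lie in 0-3")
    }
    total <- pwmh_score + dwmh_score
  }
  if (any(total < 0 | total > 6, na.rm = TRUE)) {
    stop("total Fazekas score must lie in 0-6")
  }
  factor(ifelse(total == 0, "HC", ifelse(total <= 3, "mild", "severe")),
         levels = c("HC", "mild", "severe"))
}
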