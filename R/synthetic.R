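#' Ground-truth parameter set for the synthetic study
#'
#' Collects every generator's planted truth in one object. The defaults are
#' the study conditions the pipeline is meant to emulate: ALPS ROI
#' diffusivities in the healthy 1.5-1.6 index range, a direct BOLD-CSF
#' coupling of -0.227 at +2 s lag, dorsal extended-Tofts kinetics
#' (Ktrans 0.05 /min, kep 0.5 /min, vp 0.01, hence Ve 0.1), and a
#' standardized four-latent covariance structure whose anchor loadings are
#' 0.646 (ChP/LatVent on Inflow) and 0.712 (ALPS on Outflow) and whose
#' structural paths are Outflow -> WMH = -0.572 and WMH -> Cognition =
#' -0.705, with a small negative Inflow -> WMH path and Inflow-Outflow
#' correlation 0.4.
#'
#' @param alps List: `dxproj`, `dyproj`, `dxassoc`, `dzassoc` (mm^2/s),
#'   `background`, `noise_sd`.
#' @param coupling List: `strength` (signed peak correlation), `lag`
#'   (seconds), `mode` (`"direct"` or `"derivative"`).
#' @param tofts List: `ktrans`, `kep` (1/min), `vp` (fraction).
#' @param sem List: `loadings` (named, one per indicator), `latent_cor`,
#'   `paths` (named: `wmh~inflow`, `wmh~outflow`, `cognition~wmh`).
#' @return A `sim_truth` object.
#' @export
sim_truth <- function(
    alps = list(dxproj = 1.2e-3, dyproj = 0.8e-3, dxassoc = 1.0e-3,
                dzassoc = 0.6e-3, background = 0.7e-3, noise_sd = 0),
    coupling = list(strength = -0.227, lag = 2, mode = "direct"),
    tofts = list(ktrans = 0.05, kep = 0.5, vp = 0.01),
    sem = list(
      loadings = c(chp_latvent = 0.646, coupling_max = -0.45,
                   alps_avg = 0.712, dorsal_ttp = -0.55, dorsal_auc = 0.60,
                   dorsal_kep = 0.55, pwmh_volume = 0.85,
                   dwmh_volume = 0.80, fazekas_total = 0.90,
                   mmse = 0.80, moca = 0.85),
      latent_cor = 0.4,
      paths = c(`wmh~inflow` = -0.20, `wmh~outflow` = -0.572,
                `cognition~wmh` = -0.705))) {
  if (abs(coupling$strength) > 1) stop("|coupling strength| must be <= 1")
  if (any(unlist(alps[c("dxproj", "dyproj", "dxassoc", "dzassoc",
                        "background")]) < 0)) {
    stop("requested diffusivities must be non-negative")
  }
  if (any(unlist(tofts) < 0)) stop("kinetic parameters must be >= 0")
  structure(list(alps = alps, coupling = coupling, tofts = tofts, sem = sem),
            class = "sim_truth")
}

#' Generate directional diffusivity volumes with planted ROI means
#'
#' Builds Dx/Dy/Dz maps at a constant background diffusivity, plants the
#' requested means inside 3x3-voxel projection- and association-fibre ROIs
#' in each hemisphere, and adds optional Gaussian noise. Without noise the
#' downstream ROI means equal the planted values exactly.
#'
#' @param truth A [sim_truth()] (its `alps` element is used).
#' @param shape Volume dimensions in voxels (default `c(24, 24, 12)`).
#' @param spacing Voxel spacing in mm (default 1.8 isotropic).
#' @param seed Optional integer seed for the noise draw.
#' @return A `diffusivity_volumes` object; the planted values are attached
#'   as attribute `truth`.
#' @export
gen_diffusivity_field <- function(truth = sim_truth(),
                                  shape = c(24L, 24L, 12L),
                                  spacing = rep(1.8, 3), seed = NULL) {
  p <- truth$alps
  if (any(shape < 8)) stop("shape too small to hold two 3x3 ROIs per hemisphere")
  if (!is.null(seed)) set.seed(seed)
  mk <- function() array(p$background, shape)
  dx <- mk(); dy <- mk(); dz <- mk()
  kz <- max(1L, shape[3] %/% 2L)
  centers <- list(
    left = list(proj = c(round(shape[1] / 4), round(shape[2] / 3), kz),
                assoc = c(round(shape[1] / 4), round(2 * shape[2] / 3), kz)),
    right = list(proj = c(round(3 * shape[1] / 4), round(shape[2] / 3), kz),
                 assoc = c(round(3 * shape[1] / 4), round(2 * shape[2] / 3), kz)))
  rois <- lapply(centers, function(side) {
    lapply(side, square_roi)
  })
  all_vox <- do.call(rbind, unlist(rois, recursive = FALSE))
  if (anyDuplicated(all_vox)) stop("generated ROIs overlap; enlarge shape")
  for (side in rois) {
    dx[side$proj] <- p$dxproj
    dy[side$proj] <- p$dyproj
    dx[side$assoc] <- p$dxassoc
    dz[side$assoc] <- p$dzassoc
  }
  if (p$noise_sd > 0) {
    nz <- function(a) pmax(a + stats::rnorm(length(a), sd = p$noise_sd), 0)
    dx <- array(nz(dx), shape); dy <- array(nz(dy), shape)
    dz <- array(nz(dz), shape)
  }
  vols <- diffusivity_volumes(voxel_grid(dx, spacing),
                              voxel_grid(dy, spacing),
                              voxel_grid(dz, spacing), rois)
  attr(vols, "truth") <- p
  vols
}

# Band-limited Gaussian series: zero-phase band-passed white noise,
# standardized, generated with padding so edges carry no filter transient.
band_limited_noise <- function(n, tr, band = c(0.01, 0.1), pad = 60L) {
  fs <- 1 / tr
  bw <- signal::butter(2, band / (fs / 2), type = "pass")
  z <- as.numeric(signal::filtfilt(bw, stats::rnorm(n + 2 * pad)))
  z <- z[(pad + 1):(pad + n)]
  as.numeric(scale(z))
}

#' Generate a coupled raw BOLD/CSF series pair
#'
#' BOLD is a band-limited (0.01-0.1 Hz) stochastic oscillation. The CSF
#' series mixes a lagged reference - the lagged BOLD itself
#' (`mode = "direct"`) or its negative temporal derivative
#' (`mode = "derivative"`) - with independent band-limited noise, weighted
#' so the planted peak cross-correlation of the corresponding profile
#' equals `strength` (in expectation) at lag `lag`. Positive lag means BOLD
#' leads CSF. Both series are returned raw (arbitrary positive units,
#' pre-normalization), ready for [preprocess_pair()].
#'
#' @param truth A [sim_truth()] (its `coupling` element is used).
#' @param n_volumes Series length (default 250).
#' @param tr Repetition time, seconds (default 2).
#' @param seed Optional integer seed.
#' @return A raw `timeseries_pair` with attribute `truth`.
#' @export
gen_bold_csf <- function(truth = sim_truth(), n_volumes = 250L, tr = 2,
                         seed = NULL) {
  cp <- truth$coupling
  if (abs(cp$strength) > 1) stop("|coupling strength| must be <= 1")
  k <- cp$lag / tr
  if (abs(k - round(k)) > 1e-9) {
    warning("lag is not a multiple of TR; rounding to the nearest volume")
  }
  k <- as.integer(round(k))
  if (n_volumes <= 10 + abs(k) + 20) stop("n_volumes too short for the lag window")
  if (!is.null(seed)) set.seed(seed)
  pad <- 40L
  m <- n_volumes + 2 * pad
  bold_z <- band_limited_noise(m, tr)
  ref <- if (identical(cp$mode, "derivative")) -central_diff(bold_z, tr) else bold_z
  # csf[i] tracks ref[i - k]: BOLD leads CSF by k volumes when k > 0
  ref_lag <- if (k >= 0) c(rep(NA, k), ref[seq_len(m - k)]) else
    c(ref[(1 - k):m], rep(NA, -k))
  noise <- band_limited_noise(m, tr)
  s <- cp$strength
  csf_z <- s * as.numeric(scale(ref_lag)) + sqrt(1 - s^2) * noise
  csf_z[is.na(csf_z)] <- noise[is.na(csf_z)]
  keep <- (pad + 1):(pad + n_volumes)
  pair <- timeseries_pair(1000 * (1 + 0.02 * bold_z[keep]),
                          500 * (1 + 0.03 * csf_z[keep]), tr = tr)
  attr(pair, "truth") <- cp
  pair
}

#' Generate a DCE time-intensity curve from extended-Tofts truth
#'
#' Samples the forward model `S(t) = S0 * (1 + e(t))` on the acquisition
#' grid, where `e(t)` is the analytic extended-Tofts enhancement for the
#' bi-exponential population AIF, with optional Gaussian or Rician noise on
#' the signal.
#'
#' @param truth A [sim_truth()] (its `tofts` element is used).
#' @param grid Sampling grid from [dce_grid()].
#' @param aif AIF from [biexp_aif()]; its arrival time must match the grid
#'   injection time.
#' @param s0 Baseline signal (a.u., default 100).
#' @param noise_sd Noise standard deviation in signal units (default 0).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param region Region label for the curve.
#' @param seed Optional integer seed.
#' @return A `time_intensity_curve` with attribute `truth` (including
#'   `ve = ktrans / kep`).
#' @export
gen_dce_curve <- function(truth = sim_truth(), grid = dce_grid(),
                          aif = biexp_aif(t0 = grid$injection_time),
                          s0 = 100, noise_sd = 0,
                          noise_model = c("gaussian", "rician"),
                          region = "dorsal_mlv", seed = NULL) {
  noise_model <- match.arg(noise_model)
  tp <- truth$tofts
  if (any(unlist(tp) < 0)) stop("kinetic parameters must be >= 0")
  if (tp$kep == 0 && tp$ktrans > 0) {
    stop("kep = 0 with nonzero Ktrans leaves Ve undefined")
  }
  e <- tofts_forward(grid$t, tp$ktrans, tp$kep, tp$vp, aif)
  sig <- s0 * (1 + e)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    if (noise_model == "gaussian") {
      sig <- sig + stats::rnorm(length(sig), sd = noise_sd)
    } else {
      sig <- sqrt((sig + stats::rnorm(length(sig), sd = noise_sd))^2 +
                  stats::rnorm(length(sig), sd = noise_sd)^2)
    }
  }
  curve <- time_intensity_curve(grid$t, sig, grid$baseline_window,
                                grid$injection_time, region = region)
  attr(curve, "truth") <- list(ktrans = tp$ktrans, kep = tp$kep,
                               ve = if (tp$kep > 0) tp$ktrans / tp$kep else 0,
                               vp = tp$vp, s0 = s0, noise_sd = noise_sd)
  curve
}

#' Generate a lesion scene with analytic class truth
#'
#' The ventricular system is a central slab along the first (x) axis
#' spanning the full extent of the other axes; lesions are axis-aligned
#' solid ellipsoids. Because the geometry is analytic, each lesion's
#' intended periventricular/deep class follows from its surface-to-slab gap
#' `|cx - nearest slab face| - ax`, and the realized voxel-centre distance
#' is also recorded by brute force for cross-checking the distance
#' transform.
#'
#' @param lesion_specs Data frame with columns `cx, cy, cz` (centre, mm),
#'   `ax, ay, az` (semi-axes, mm).
#' @param shape Volume dimensions in voxels.
#' @param spacing Voxel spacing in mm.
#' @param ventricle_halfwidth Half-thickness of the ventricular slab in mm
#'   (default 5).
#' @param threshold_mm Class threshold used for the intended labels
#'   (default 8).
#' @return A `lesion_scene` with attribute `truth`: data frame of specs
#'   plus `analytic_gap`, `realized_distance`, `intended_class`, and
#'   `analytic_volume` (mm^3).
#' @export
gen_lesion_scene <- function(lesion_specs, shape = c(64L, 32L, 32L),
                             spacing = rep(1, 3), ventricle_halfwidth = 5,
                             threshold_mm = 8) {
  stopifnot(all(c("cx", "cy", "cz", "ax", "ay", "az") %in% names(lesion_specs)))
  if (any(lesion_specs[c("ax", "ay", "az")] <= 0)) {
    stop("ellipsoid semi-axes must be positive")
  }
  ext <- (shape - 1) * spacing
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3]
  x_mid <- ext[1] / 2
  vent <- array(0L, shape)
  vent[abs(xs - x_mid) <= ventricle_halfwidth, , ] <- 1L
  vent_faces <- c(max(xs[abs(xs - x_mid) <= ventricle_halfwidth]),
                  min(xs[abs(xs - x_mid) <= ventricle_halfwidth]))

  lesion <- array(0L, shape)
  info <- lesion_specs
  info$analytic_gap <- NA_real_
  info$realized_distance <- NA_real_
  info$analytic_volume <- NA_real_
  # the slab spans the full y-z extent, so the nearest ventricle voxel to
  # any outside point lies on one of the two slab faces: restricting the
  # brute-force search to face slices is exact
  face_x <- range(which(abs(xs - x_mid) <= ventricle_halfwidth))
  vent_idx <- which(array(seq_len(shape[1]), shape) %in% face_x & vent == 1L)
  vent_xyz <- sweep(arrayInd(vent_idx, shape) - 1, 2, spacing, "*")
  for (r in seq_len(nrow(info))) {
    cc <- as.numeric(info[r, c("cx", "cy", "cz")])
    aa <- as.numeric(info[r, c("ax", "ay", "az")])
    if (any(cc - aa < 0) || any(cc + aa > ext)) {
      stop("lesion ", r, " intersects the volume boundary")
    }
    inside <- outer(((xs - cc[1]) / aa[1])^2, ((ys - cc[2]) / aa[2])^2, "+")
    inside <- outer(inside, ((zs - cc[3]) / aa[3])^2, "+") <= 1
    if (!any(inside)) stop("lesion ", r, " contains no voxel centre; enlarge it")
    if (any(lesion[inside] == 1L)) stop("lesions overlap; adjust the specs")
    lesion[inside] <- 1L
    # surface gap to the slab along x (slab spans full y-z extent)
    gap <- if (cc[1] > x_mid) cc[1] - vent_faces[1] - aa[1] else
      vent_faces[2] - cc[1] - aa[1]
    info$analytic_gap[r] <- max(0, gap)
    les_xyz <- sweep(arrayInd(which(inside), shape) - 1, 2, spacing, "*")
    if (any(abs(les_xyz[, 1] - x_mid) <= ventricle_halfwidth)) {
      info$realized_distance[r] <- 0     # lesion voxel inside the slab
    } else {
      d2 <- outer(rowSums(les_xyz^2), rowSums(vent_xyz^2), "+") -
        2 * les_xyz %*% t(vent_xyz)
      info$realized_distance[r] <- sqrt(max(0, min(d2)))
    }
    info$analytic_volume[r] <- 4 / 3 * pi * prod(aa)
  }
  info$intended_class <- factor(
    ifelse(info$analytic_gap <= threshold_mm, "periventricular", "deep"),
    levels = c("periventricular", "deep"))
  scene <- lesion_scene(voxel_grid(lesion, spacing), voxel_grid(vent, spacing))
  attr(scene, "truth") <- info
  scene
}

#' Analytic implied covariance of the latent-variable cohort structure
#'
#' Standardized implied covariance of the 11 indicators under the
#' generative model: Inflow and Outflow standard latents with correlation
#' `latent_cor`; `WMH = g1 * Inflow + g2 * Outflow + zeta1`;
#' `Cognition = b * WMH + zeta2`; indicator `i = loading_i * latent +
#' sqrt(1 - loading_i^2) * noise`, so every indicator has unit variance.
#'
#' @param sem The `sem` element of a [sim_truth()].
#' @return An 11 x 11 covariance (= correlation) matrix with dimnames.
#' @export
sem_implied_cov <- function(sem = sim_truth()$sem) {
  lam <- sem$loadings
  phi <- sem$latent_cor
  g1 <- sem$paths[["wmh~inflow"]]; g2 <- sem$paths[["wmh~outflow"]]
  b <- sem$paths[["cognition~wmh"]]
  var_wmh <- g1^2 + g2^2 + 2 * g1 * g2 * phi
  if (var_wmh >= 1) stop("structural paths imply WMH variance >= 1; not admissible")
  if (abs(b) >= 1) stop("|cognition path| must be < 1 in the standardized metric")
  # latent covariance (inflow, outflow, wmh, cognition), all unit variance
  Phi <- diag(4)
  Phi[1, 2] <- Phi[2, 1] <- phi
  Phi[1, 3] <- Phi[3, 1] <- g1 + g2 * phi
  Phi[2, 3] <- Phi[3, 2] <- g2 + g1 * phi
  Phi[1, 4] <- Phi[4, 1] <- b * Phi[1, 3]
  Phi[2, 4] <- Phi[4, 2] <- b * Phi[2, 3]
  Phi[3, 4] <- Phi[4, 3] <- b
  blocks <- c(inflow = 2L, outflow = 4L, wmh = 3L, cognition = 2L)
  latent_of <- rep(1:4, times = blocks)
  L <- matrix(0, 11, 4)
  for (i in 1:11) L[i, latent_of[i]] <- lam[i]
  Sigma <- L %*% Phi %*% t(L) + diag(1 - lam^2)
  dimnames(Sigma) <- list(names(lam), names(lam))
  if (inherits(tryCatch(chol(Sigma), error = function(e) e), "error")) {
    stop("implied indicator covariance is not positive definite")
  }
  Sigma
}

# Observed-unit rescaling targets for the cohort indicators (approximate
# whole-cohort moments of the study population).
cohort_scales <- function() {
  data.frame(
    column = c("chp_latvent", "coupling_max", "alps_avg", "dorsal_ttp",
               "dorsal_auc", "dorsal_kep", "pwmh_volume", "dwmh_volume",
               "mmse", "moca"),
    mean = c(0.065, -0.21, 1.50, 1.12, 0.065, 0.45, 4000, 4400, 26, 24),
    sd = c(0.022, 0.125, 0.19, 0.30, 0.023, 0.16, 1000, 1100, 1.5, 2.5))
}

#' Generate a cohort table from the latent-variable truth
#'
#' Draws standardized latents (Inflow, Outflow correlated; WMH and
#' Cognition structural), maps them to the 11 indicators by the truth
#' loadings, rescales the indicators affinely to plausible observed units,
#' converts the continuous Fazekas indicator into integer 0-6 totals by
#' fixed normal quantile cuts (split into periventricular and deep 0-3
#' sub-scores), and adds demographic columns with configurable linear
#' confounding into the standardized indicators (default none).
#'
#' @param truth A [sim_truth()].
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @param confound Named numeric vector (subset of `age`, `sex`,
#'   `education`) of linear coefficients applied uniformly to all
#'   standardized indicators; default all 0.
#' @param ordinal_fazekas Cut the Fazekas indicator to integers
#'   (default `TRUE`; `FALSE` keeps the continuous score, useful for exact
#'   covariance checks).
#' @return A `cohort_table`; the truth is attached as attribute `truth`.
#' @export
gen_cohort <- function(truth = sim_truth(), n = 117L, seed = NULL,
                       confound = c(age = 0, sex = 0, education = 0),
                       ordinal_fazekas = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sem <- truth$sem
  lam <- sem$loadings
  phi <- sem$latent_cor
  g1 <- sem$paths[["wmh~inflow"]]; g2 <- sem$paths[["wmh~outflow"]]
  b <- sem$paths[["cognition~wmh"]]
  var_z1 <- 1 - (g1^2 + g2^2 + 2 * g1 * g2 * phi)
  var_z2 <- 1 - b^2
  if (var_z1 <= 0 || var_z2 <= 0) {
    stop("structural paths are not admissible in the standardized metric")
  }
  sem_implied_cov(sem)   # validates positive definiteness

  io <- MASS::mvrnorm(n, mu = c(0, 0),
                      Sigma = matrix(c(1, phi, phi, 1), 2))
  inflow <- io[, 1]; outflow <- io[, 2]
  wmh <- g1 * inflow + g2 * outflow + stats::rnorm(n, sd = sqrt(var_z1))
  cognition <- b * wmh + stats::rnorm(n, sd = sqrt(var_z2))
  latent <- cbind(inflow, outflow, wmh, cognition)
  latent_of <- rep(1:4, times = c(2, 4, 3, 2))

  # demographics (independent of the latents unless confounded below)
  age <- stats::rnorm(n, 48, 13.5)
  sex <- factor(ifelse(stats::runif(n) < 0.47, "M", "F"), levels = c("M", "F"))
  education <- pmax(0, stats::rnorm(n, 8.9, 3.5))
  conf <- confound[c("age", "sex", "education")]
  conf[is.na(conf)] <- 0
  conf_term <- conf[["age"]] * as.numeric(scale(age)) +
    conf[["sex"]] * (as.integer(sex) - 1.5) * 2 +
    conf[["education"]] * as.numeric(scale(education))

  Z <- vapply(seq_along(lam), function(i) {
    lam[i] * latent[, latent_of[i]] +
      sqrt(1 - lam[i]^2) * stats::rnorm(n) + conf_term
  }, numeric(n))
  colnames(Z) <- names(lam)

  sc <- cohort_scales()
  obs <- Z
  for (r in seq_len(nrow(sc))) {
    obs[, sc$column[r]] <- Z[, sc$column[r]] * sc$sd[r] + sc$mean[r]
  }
  obs[, "chp_latvent"] <- pmax(1e-4, obs[, "chp_latvent"])
  obs[, "pwmh_volume"] <- pmax(0, obs[, "pwmh_volume"])
  obs[, "dwmh_volume"] <- pmax(0, obs[, "dwmh_volume"])
  obs[, "mmse"] <- pmin(30, pmax(0, obs[, "mmse"]))
  obs[, "moca"] <- pmin(30, pmax(0, obs[, "moca"]))

  # integer Fazekas totals from the continuous severity indicator, cut at
  # fixed standard-normal quantiles chosen to emulate the cohort's
  # HC/mild/severe composition (~35/34/31%)
  cum <- c(0.35, 0.47, 0.58, 0.69, 0.80, 0.90)
  cuts <- stats::qnorm(cum)
  fz_cont <- Z[, "fazekas_total"]
  fz_total <- if (ordinal_fazekas) {
    findInterval(fz_cont, cuts)
  } else fz_cont
  fz_pwmh <- if (ordinal_fazekas) ceiling(fz_total / 2) else NA
  fz_dwmh <- if (ordinal_fazekas) floor(fz_total / 2) else NA

  latvent <- pmax(5000, stats::rnorm(n, 16000, 4000))
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, education = education,
    bmi = stats::rnorm(n, 22.8, 2.5),
    hypertension = stats::runif(n) < 0.22,
    icv = stats::rnorm(n, 1.45e6, 1.3e5),
    latvent_volume = latvent,
    obs[, setdiff(colnames(obs), "fazekas_total"), drop = FALSE],
    fazekas_total = fz_total,
    check.names = FALSE)
  df$chp_volume <- df$chp_latvent * df$latvent_volume
  df$total_wmh_volume <- df$pwmh_volume + df$dwmh_volume
  df$chp_icv <- df$chp_volume / df$icv
  # permeability columns outside the latent structure: plausible observed
  # moments, with the kinetic identity ktrans = ve * kep enforced
  df$dorsal_wash_in <- pmax(0.005, stats::rnorm(n, 0.080, 0.027))
  df$dorsal_ve <- pmax(0.02, stats::rnorm(n, 0.13, 0.05))
  df$dorsal_ktrans <- df$dorsal_ve * pmax(df$dorsal_kep, 0.05)
  for (side in c("left", "right")) {
    kep_s <- pmax(0.05, stats::rnorm(n, 0.58, 0.15))
    ve_s <- pmax(0.02, stats::rnorm(n, 0.12, 0.05))
    df[[paste0("basal_", side, "_wash_in")]] <- pmax(0.005, stats::rnorm(n, 0.11, 0.06))
    df[[paste0("basal_", side, "_ttp")]] <- pmax(0.2, stats::rnorm(n, 0.97, 0.26))
    df[[paste0("basal_", side, "_auc")]] <- pmax(0.005, stats::rnorm(n, 0.091, 0.045))
    df[[paste0("basal_", side, "_kep")]] <- kep_s
    df[[paste0("basal_", side, "_ve")]] <- ve_s
    df[[paste0("basal_", side, "_ktrans")]] <- ve_s * kep_s
  }
  if (ordinal_fazekas) {
    df$fazekas_pwmh <- fz_pwmh
    df$fazekas_dwmh <- fz_dwmh
    df$group <- fazekas_group(total = df$fazekas_total)
    out <- as_cohort_table(df)
  } else {
    # continuous severity scores skip the integer-score validation
    out <- df
    class(out) <- c("cohort_table", "data.frame")
  }
  attr(out, "truth") <- truth
  out
}
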