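#' Specify the four-latent glymphatic structural equation model
#'
#' Measurement model: an Inflow latent (ChP/lateral-ventricle ratio, maximum
#' BOLD-CSF coupling strength), an Outflow latent (bilateral-average ALPS,
#' dorsal TTP, dorsal AUC, dorsal kep), a WMH latent (periventricular
#' volume, deep volume, total Fazekas score) and a Cognition latent (MMSE,
#' MoCA). Structural part: WMH regressed on Outflow (and optionally
#' Inflow), Cognition regressed on WMH; Inflow and Outflow covary.
#' Identification is by the marker-variable method: the first loading of
#' each latent is fixed to 1.
#'
#' @param indicators Named list mapping latent names to indicator column
#'   names; the default is the standard roster above.
#' @param inflow_to_wmh Include the Inflow -> WMH structural path
#'   (default `TRUE`).
#' @return A `sem_model_spec` object.
#' @export
sem_model_spec <- function(indicators = list(
                             inflow = c("chp_latvent", "coupling_max"),
                             outflow = c("alps_avg", "dorsal_ttp",
                                         "dorsal_auc", "dorsal_kep"),
                             wmh = c("pwmh_volume", "dwmh_volume",
                                     "fazekas_total"),
                             cognition = c("mmse", "moca")),
                           inflow_to_wmh = TRUE) {
  stopifnot(setequal(names(indicators),
                     c("inflow", "outflow", "wmh", "cognition")))
  obs <- unlist(indicators, use.names = FALSE)
  if (anyDuplicated(obs)) stop("each indicator may load on exactly one latent")
  structure(list(indicators = indicators, observed = obs,
                 latents = c("inflow", "outflow", "wmh", "cognition"),
                 inflow_to_wmh = inflow_to_wmh),
            class = "sem_model_spec")
}

# Internal bookkeeping: parameter table for the RAM matrices.
# Variables are ordered observed (p) then latent (4). Free parameters:
# non-marker loadings, structural paths, log residual variances (observed
# and latent endogenous), log exogenous latent variances, atanh inflow-
# outflow correlation.
sem_param_table <- function(spec) {
  p <- length(spec$observed)
  lat_idx <- stats::setNames(p + seq_along(spec$latents), spec$latents)
  rows <- list()
  add <- function(kind, i, j, name) {
    rows[[length(rows) + 1]] <<- data.frame(kind = kind, i = i, j = j,
                                            name = name)
  }
  off <- 0
  for (lat in names(spec$indicators)) {
    ind <- spec$indicators[[lat]]
    for (k in seq_along(ind)) {
      if (k > 1) add("loading", off + k, lat_idx[[lat]],
                     paste0("lambda_", ind[k]))
    }
    off <- off + length(ind)
  }
  if (spec$inflow_to_wmh) {
    add("path", lat_idx[["wmh"]], lat_idx[["inflow"]], "wmh~inflow")
  }
  add("path", lat_idx[["wmh"]], lat_idx[["outflow"]], "wmh~outflow")
  add("path", lat_idx[["cognition"]], lat_idx[["wmh"]], "cognition~wmh")
  for (k in seq_len(p)) {
    add("logvar", k, k, paste0("theta_", spec$observed[k]))
  }
  add("logvar", lat_idx[["inflow"]], lat_idx[["inflow"]], "var_inflow")
  add("logvar", lat_idx[["outflow"]], lat_idx[["outflow"]], "var_outflow")
  add("logvar", lat_idx[["wmh"]], lat_idx[["wmh"]], "zeta_wmh")
  add("logvar", lat_idx[["cognition"]], lat_idx[["cognition"]], "zeta_cognition")
  add("atanh_cor", lat_idx[["inflow"]], lat_idx[["outflow"]], "cov_inflow_outflow")
  do.call(rbind, rows)
}

# Build RAM matrices A (directed) and S2 (symmetric) from theta.
sem_ram <- function(theta, spec, ptab) {
  p <- length(spec$observed)
  nv <- p + 4
  A <- matrix(0, nv, nv)
  S2 <- matrix(0, nv, nv)
  lat_idx <- stats::setNames(p + seq_along(spec$latents), spec$latents)
  off <- 0
  for (lat in names(spec$indicators)) {
    ind <- spec$indicators[[lat]]
    A[off + 1, lat_idx[[lat]]] <- 1       # marker loading
    off <- off + length(ind)
  }
  vars <- numeric(nv)
  cor_io <- 0
  for (r in seq_len(nrow(ptab))) {
    v <- theta[r]
    switch(as.character(ptab$kind[r]),
           loading = , path = { A[ptab$i[r], ptab$j[r]] <- v },
           logvar = { vars[ptab$i[r]] <- exp(v) },
           atanh_cor = { cor_io <- tanh(v) })
  }
  diag(S2) <- vars
  iin <- lat_idx[["inflow"]]; iout <- lat_idx[["outflow"]]
  S2[iin, iout] <- S2[iout, iin] <- cor_io * sqrt(vars[iin] * vars[iout])
  list(A = A, S2 = S2)
}

# Total-effects matrix B = (I - A)^-1; A is nilpotent with path length <= 3.
sem_total <- function(A) {
  A2 <- A %*% A
  diag(nrow(A)) + A + A2 + A2 %*% A
}

sem_implied_full <- function(theta, spec, ptab) {
  ram <- sem_ram(theta, spec, ptab)
  B <- sem_total(ram$A)
  B %*% ram$S2 %*% t(B)
}

# Precompile the parameter table into index vectors for fast objective and
# analytic-gradient evaluation.
sem_compile <- function(spec, ptab) {
  p <- length(spec$observed)
  nv <- p + 4
  A0 <- matrix(0, nv, nv)
  lat_idx <- stats::setNames(p + seq_along(spec$latents), spec$latents)
  off <- 0
  for (lat in names(spec$indicators)) {
    A0[off + 1, lat_idx[[lat]]] <- 1
    off <- off + length(spec$indicators[[lat]])
  }
  isA <- ptab$kind %in% c("loading", "path")
  isV <- ptab$kind == "logvar"
  list(p = p, nv = nv, A0 = A0,
       th_A = which(isA),
       A_lin = ptab$i[isA] + nv * (ptab$j[isA] - 1L),
       A_ij = cbind(ptab$i[isA], ptab$j[isA]),
       th_V = which(isV), V_var = ptab$i[isV],
       th_cor = which(ptab$kind == "atanh_cor"),
       iin = lat_idx[["inflow"]], iout = lat_idx[["outflow"]])
}

# Implied full covariance plus intermediates, from compiled indices.
sem_eval <- function(theta, comp) {
  A <- comp$A0
  A[comp$A_lin] <- theta[comp$th_A]
  vars <- exp(theta[comp$th_V])
  rho <- tanh(theta[comp$th_cor])
  S2 <- matrix(0, comp$nv, comp$nv)
  S2[cbind(comp$V_var, comp$V_var)] <- vars
  vio <- sqrt(S2[comp$iin, comp$iin] * S2[comp$iout, comp$iout])
  S2[comp$iin, comp$iout] <- S2[comp$iout, comp$iin] <- rho * vio
  A2 <- A %*% A
  B <- diag(comp$nv) + A + A2 + A2 %*% A
  V <- B %*% S2 %*% t(B)
  list(A = A, S2 = S2, B = B, V = V, vars = vars, rho = rho, vio = vio)
}

sem_objective_fast <- function(theta, S, comp, logdet_S) {
  ev <- sem_eval(theta, comp)
  Sigma <- ev$V[seq_len(comp$p), seq_len(comp$p)]
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  val <- 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) - logdet_S - comp$p
  if (!is.finite(val)) 1e10 else val
}

# Analytic gradient of the ML discrepancy: dF = tr(W dSigma) with
# W = Sigma^-1 - Sigma^-1 S Sigma^-1, propagated through the RAM structure.
sem_gradient_fast <- function(theta, S, comp, logdet_S) {
  ev <- sem_eval(theta, comp)
  p <- comp$p
  Sigma <- ev$V[seq_len(p), seq_len(p)]
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(numeric(length(theta)))
  Sinv <- chol2inv(ch)
  W <- Sinv - Sinv %*% S %*% Sinv
  Wt <- matrix(0, comp$nv, comp$nv)
  Wt[seq_len(p), seq_len(p)] <- W
  G <- t(ev$B) %*% Wt
  P <- G %*% ev$V          # dF/dA_ij = 2 * P[i, j]
  Q <- G %*% ev$B          # dF/dS2 via quadratic form
  g <- numeric(length(theta))
  g[comp$th_A] <- 2 * P[comp$A_ij]
  # diagonal variances (log scale), plus the chain through the latent
  # covariance term for the two exogenous latents
  qdiag <- diag(Q)[comp$V_var]
  g[comp$th_V] <- qdiag * ev$vars
  cov_io <- ev$rho * ev$vio
  q_io <- Q[comp$iin, comp$iout] + Q[comp$iout, comp$iin]
  for (which_i in c(comp$iin, comp$iout)) {
    j <- which(comp$V_var == which_i)
    g[comp$th_V[j]] <- g[comp$th_V[j]] + q_io * 0.5 * cov_io
  }
  g[comp$th_cor] <- q_io * ev$vio * (1 - ev$rho^2)
  g
}

#' Fit a structural equation model by maximum likelihood
#'
#' Normal-theory ML on the sample covariance matrix of the (internally
#' standardized) indicators, using a RAM parameterization and quasi-Newton
#' optimization with seeded multi-start. Residual variances are
#' log-parameterized, so improper negative variances cannot occur; a
#' residual variance collapsing to ~0 is flagged as a boundary (Heywood)
#' case. Reports the standardized solution and the usual fit statistics:
#' chi-squared `(n - 1) * F_ML`, CFI against the uncorrelated-indicator
#' baseline, GFI from the ML discrepancy, and RMSEA.
#'
#' @param data Data frame containing the indicator columns (listwise
#'   deletion is applied).
#' @param spec A [sem_model_spec()].
#' @param n_starts Number of optimizer starts (first is deterministic).
#' @param seed Seed for start jitter.
#' @param start Optional full start vector on the internal parameter scale
#'   (used for warm-started refits; overrides multi-start).
#' @return A `sem_fit`: list with `loadings` and `paths` (standardized,
#'   named), `latent_cor`, `chi2`, `df`, `chi2_df_ratio`, `cfi`, `gfi`,
#'   `rmsea`, `n`, `converged`, `heywood`, `theta` (internal), `fmin`.
#' @export
fit_sem <- function(data, spec = sem_model_spec(), n_starts = 3L, seed = 1L,
                    start = NULL) {
  d <- data[spec$observed]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  ptab <- sem_param_table(spec)
  if (n <= nrow(ptab)) stop("n must exceed the number of free parameters")
  Z <- scale(as.matrix(d))
  S <- stats::cov(Z)
  if (any(!is.finite(S))) stop("constant indicator column")
  if (inherits(tryCatch(chol(S), error = function(e) e), "error")) {
    stop("sample covariance is not positive definite")
  }
  p <- ncol(S)

  default_start <- function() {
    th <- numeric(nrow(ptab))
    th[ptab$kind == "loading"] <- 0.8
    th[ptab$kind == "path"] <- 0
    th[ptab$kind == "logvar"] <- log(0.5)
    th[ptab$kind == "atanh_cor"] <- atanh(0.3)
    th
  }
  comp <- sem_compile(spec, ptab)
  logdet_S <- determinant(S, logarithm = TRUE)$modulus[1]
  obj <- function(th) sem_objective_fast(th, S, comp, logdet_S)
  grd <- function(th) sem_gradient_fast(th, S, comp, logdet_S)
  run <- function(th0) {
    stats::optim(th0, obj, grd, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-11))
  }
  if (!is.null(start)) {
    best <- run(start)
  } else {
    set.seed(seed)
    best <- NULL
    for (s in seq_len(n_starts)) {
      th0 <- default_start()
      if (s > 1) th0 <- th0 + stats::rnorm(length(th0), sd = 0.3)
      fit <- run(th0)
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  theta <- best$par
  converged <- best$convergence == 0 && best$value < 1e9

  ram <- sem_ram(theta, spec, ptab)
  V <- sem_implied_full(theta, spec, ptab)
  sdv <- sqrt(diag(V))
  std_coef <- function(i, j) ram$A[i, j] * sdv[j] / sdv[i]
  loadings <- c()
  lat_idx <- stats::setNames(p + seq_along(spec$latents), spec$latents)
  off <- 0
  for (lat in names(spec$indicators)) {
    ind <- spec$indicators[[lat]]
    for (k in seq_along(ind)) {
      loadings[ind[k]] <- std_coef(off + k, lat_idx[[lat]])
    }
    off <- off + length(ind)
  }
  paths <- c()
  if (spec$inflow_to_wmh) {
    paths["wmh~inflow"] <- std_coef(lat_idx[["wmh"]], lat_idx[["inflow"]])
  }
  paths["wmh~outflow"] <- std_coef(lat_idx[["wmh"]], lat_idx[["outflow"]])
  paths["cognition~wmh"] <- std_coef(lat_idx[["cognition"]], lat_idx[["wmh"]])
  latent_cor <- V[lat_idx[["inflow"]], lat_idx[["outflow"]]] /
    (sdv[lat_idx[["inflow"]]] * sdv[lat_idx[["outflow"]]])
  heywood <- any(exp(theta[ptab$kind == "logvar"]) < 1e-5)
  if (heywood) warning("boundary (Heywood-type) residual variance detected")

  fmin <- best$value
  chi2 <- (n - 1) * fmin
  df <- p * (p + 1) / 2 - nrow(ptab)
  chi2_b <- -(n - 1) * determinant(stats::cov2cor(S), logarithm = TRUE)$modulus[1]
  df_b <- p * (p - 1) / 2
  cfi_den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (cfi_den == 0) 1 else 1 - max(chi2 - df, 0) / cfi_den
  Sigma <- V[seq_len(p), seq_len(p)]
  W <- solve(Sigma, S)
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) / sum(diag(W %*% W))
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else NA_real_
  ratio <- if (df > 0) chi2 / df else NA_real_

  structure(list(loadings = loadings, paths = paths, latent_cor = latent_cor,
                 chi2 = chi2, df = df, chi2_df_ratio = ratio, cfi = cfi,
                 gfi = gfi, rmsea = rmsea, n = n, converged = converged,
                 heywood = heywood, theta = theta, fmin = fmin, spec = spec),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("SEM fit: chi2 = %.3f, df = %d, chi2/df = %.3f, CFI = %.3f, GFI = %.3f, RMSEA = %.3f (n = %d)\n",
              x$chi2, x$df, x$chi2_df_ratio, x$cfi, x$gfi, x$rmsea, x$n))
  cat("Standardized paths:\n")
  print(round(x$paths, 3))
  invisible(x)
}

#' Bootstrap confidence intervals for SEM structural paths
#'
#' Percentile intervals over row-resampled refits, warm-started at the
#' full-sample solution. Aborts if more than 5 percent of resamples fail to
#' converge.
#'
#' @param data Data frame of indicators.
#' @param spec A [sem_model_spec()].
#' @param n_boot Number of bootstrap resamples (> 0).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `ci` (matrix: paths x lower/upper), `estimates`
#'   (full-sample standardized paths), `n_failed`, `boot_paths` (matrix of
#'   resample estimates).
#' @export
boot_sem <- function(data, spec = sem_model_spec(), n_boot = 2000L, seed = 1L,
                     level = 0.95) {
  if (n_boot < 1) stop("n_boot must be a positive integer")
  full <- fit_sem(data, spec)
  d <- data[spec$observed]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  set.seed(seed)
  rows <- lapply(seq_len(n_boot), function(b) sample.int(n, n, replace = TRUE))
  est <- matrix(NA_real_, n_boot, length(full$paths),
                dimnames = list(NULL, names(full$paths)))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    fit <- tryCatch(suppressWarnings(
      fit_sem(d[rows[[b]], , drop = FALSE], spec, start = full$theta)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- failed + 1L; next }
    est[b, ] <- fit$paths
  }
  if (failed > 0.05 * n_boot) {
    stop("bootstrap aborted: ", failed, "/", n_boot,
         " resamples failed to converge")
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(est, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = full$paths, n_failed = failed, boot_paths = est)
}
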