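#' Bootstrap mediation analysis
#'
#' Standard three-regression mediation on internally standardized
#' variables: `m ~ x + covariates` (path a), `y ~ x + m + covariates`
#' (paths b and c'), `y ~ x + covariates` (total effect c). The indirect
#' effect `a * b` gets a percentile bootstrap confidence interval by
#' resampling rows. Partial mediation is declared when the indirect CI
#' excludes 0 while the direct effect remains significant at `alpha`; full
#' mediation when the indirect CI excludes 0 but the direct effect does
#' not differ from 0.
#'
#' @param data Data frame.
#' @param x,m,y Column names of exposure, mediator and outcome.
#' @param covariates Character vector of covariate column names.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @param alpha Significance level (default 0.05).
#' @return A `mediation_result`: list with `a`, `b`, `c_total`, `c_prime`,
#'   `indirect`, `boot_ci`, `p_indirect` (bootstrap two-sided), `mediation`
#'   (`"none"`, `"partial"`, `"full"`), `n`, `n_boot`, `n_degenerate`.
#' @export
mediate <- function(data, x, m, y, covariates = character(), n_boot = 5000L,
                    seed = 1L, alpha = 0.05) {
  if (x == m || m == y || x == y) stop("x, m and y must be distinct columns")
  vars <- c(x, m, y, covariates)
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n < 30) stop("need at least 30 complete cases")
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) as.numeric(scale(v)))
  if (stats::cor(d[[x]], d[[m]])^2 > 1 - 1e-10) {
    stop("mediator is numerically identical to the exposure")
  }

  C <- if (length(covariates)) {
    stats::model.matrix(~ ., data = d[, covariates, drop = FALSE])
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  fit_paths <- function(dd, CC) {
    xm <- cbind(CC, x = dd[[x]])
    a <- stats::lm.fit(xm, dd[[m]])$coefficients["x"]
    xym <- cbind(CC, x = dd[[x]], m = dd[[m]])
    cf <- stats::lm.fit(xym, dd[[y]])$coefficients
    c(a = unname(a), b = unname(cf["m"]), c_prime = unname(cf["x"]))
  }
  est <- fit_paths(d, C)
  c_total <- stats::lm.fit(cbind(C, x = d[[x]]), d[[y]])$coefficients["x"]

  set.seed(seed)
  boot_ind <- rep(NA_real_, n_boot)
  boot_cprime <- rep(NA_real_, n_boot)
  degenerate <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    dd <- d[idx, , drop = FALSE]
    CC <- C[idx, , drop = FALSE]
    pb <- tryCatch(fit_paths(dd, CC), error = function(e) NULL)
    if (is.null(pb) || any(is.na(pb))) { degenerate <- degenerate + 1L; next }
    boot_ind[b] <- pb["a"] * pb["b"]
    boot_cprime[b] <- pb["c_prime"]
  }
  ok <- !is.na(boot_ind)
  ci <- stats::quantile(boot_ind[ok], c(alpha / 2, 1 - alpha / 2))
  # two-sided bootstrap p: smallest level at which the percentile CI
  # excludes zero
  p_ind <- 2 * min(mean(boot_ind[ok] <= 0), mean(boot_ind[ok] >= 0))
  ci_cp <- stats::quantile(boot_cprime[ok], c(alpha / 2, 1 - alpha / 2))
  indirect_sig <- ci[1] > 0 || ci[2] < 0
  direct_sig <- ci_cp[1] > 0 || ci_cp[2] < 0
  mediation <- if (!indirect_sig) "none" else if (direct_sig) "partial" else "full"

  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c_total = unname(c_total), c_prime = unname(est["c_prime"]),
                 indirect = unname(est["a"] * est["b"]),
                 boot_ci = unname(ci), p_indirect = p_ind,
                 direct_ci = unname(ci_cp), mediation = mediation,
                 covariates = covariates, n = n, n_boot = n_boot,
                 n_degenerate = degenerate, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Mediation: a = %.3f, b = %.3f, c = %.3f, c' = %.3f\nindirect = %.3f, 95%% boot CI [%.3f, %.3f], p = %.3f (%s mediation)\n",
    x$a, x$b, x$c_total, x$c_prime, x$indirect, x$boot_ci[1], x$boot_ci[2],
    x$p_indirect, x$mediation))
  invisible(x)
}
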