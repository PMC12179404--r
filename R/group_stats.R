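#' Omnibus group comparison with Tukey post hoc contrasts
#'
#' One-way ANOVA (continuous outcomes) or a chi-squared test of independence
#' (categorical outcomes) across the severity groups, with Tukey
#' HSD-adjusted pairwise comparisons for the ANOVA case.
#'
#' @param outcome Numeric vector (anova) or factor/character (chi2).
#' @param group Grouping factor.
#' @param kind `"anova"` or `"chi2"`.
#' @param correct Continuity correction for 2x2 chi-squared tables
#'   (default `FALSE`).
#' @return List with `statistic`, `df`, `p`, and for ANOVA `tukey` (data
#'   frame of pairwise contrasts: `contrast`, `diff`, `p_adj`).
#' @export
group_compare <- function(outcome, group, kind = c("anova", "chi2"),
                          correct = FALSE) {
  kind <- match.arg(kind)
  if (kind == "anova") {
    group <- droplevels(as.factor(group))
    if (nlevels(group) < 2) stop("need at least two groups")
    keep <- is.finite(outcome) & !is.na(group)
    outcome <- outcome[keep]; group <- droplevels(group[keep])
    vars <- tapply(outcome, group, stats::var)
    if (any(vars < 1e-300, na.rm = TRUE)) {
      warning("at least one group has zero variance")
    }
    fit <- stats::aov(outcome ~ group)
    tab <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    list(statistic = tab[1, "F value"],
         df = unname(tab[["Df"]]),
         p = tab[1, "Pr(>F)"],
         tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL))
  } else {
    tab <- if (is.matrix(outcome)) outcome else table(outcome, group)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) warning("expected cell count below 1 in chi2 table")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, tukey = NULL)
  }
}

#' Covariate-adjusted group comparison (ANCOVA / rank ANCOVA)
#'
#' Fits `outcome ~ group + covariates` (optionally plus a second factor for
#' two-way main-effect checks), tests the group effect by a partial F-test,
#' and reports Bonferroni-adjusted pairwise contrasts of the
#' covariate-adjusted group means (via estimated marginal means). With
#' `ranked = TRUE` the outcome is rank-transformed first, giving a rank
#' ANCOVA that is invariant to monotone transforms of the outcome.
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column.
#' @param group Name of the grouping column (factor).
#' @param covariates Character vector of covariate columns (default
#'   `c("age", "sex", "education")`).
#' @param ranked Rank-transform the outcome first.
#' @param second_factor Optional name of a second factor whose main effect
#'   is also tested.
#' @return List with `f`, `df`, `p` for the group effect, `pairwise` (data
#'   frame: contrast, estimate, p_raw, p_bonferroni, cohen_d, effect_r),
#'   and `second_factor` (`f`, `df`, `p`) when requested.
#' @export
ancova <- function(data, outcome, group, covariates = c("age", "sex", "education"),
                   ranked = FALSE, second_factor = NULL) {
  vars <- c(outcome, group, covariates, second_factor)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  d[[group]] <- droplevels(as.factor(d[[group]]))
  if (ranked) d[[outcome]] <- rank(d[[outcome]])
  num_cov <- covariates[vapply(d[covariates], is.numeric, logical(1))]
  if (length(num_cov) > 1) {
    kappa_x <- kappa(scale(d[num_cov]), exact = TRUE)
    if (!is.finite(kappa_x) || kappa_x > 1e8) stop("covariates are collinear")
  }
  rhs <- paste(c(group, second_factor, covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = d)
  drop_term <- function(term) {
    reduced <- stats::update(full, stats::as.formula(paste(". ~ . -", term)))
    a <- stats::anova(reduced, full)
    list(f = a$F[2], df = c(a$Df[2], a$Res.Df[2]), p = a$`Pr(>F)`[2])
  }
  grp_test <- drop_term(group)

  emm <- emmeans::emmeans(full, specs = group)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  m <- nrow(prs)
  pairwise <- data.frame(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    p_raw = prs$p.value,
    p_bonferroni = pmin(1, prs$p.value * m))
  # unadjusted-scale effect sizes per contrast
  lv <- levels(d[[group]])
  dd <- t(utils::combn(lv, 2, function(pair) {
    x <- d[[outcome]][d[[group]] == pair[1]]
    y <- d[[outcome]][d[[group]] == pair[2]]
    dv <- cohens_d(x, y)
    c(dv, d_to_r(dv))
  }))
  pairwise$cohen_d <- dd[, 1]
  pairwise$effect_r <- dd[, 2]

  out <- list(f = grp_test$f, df = grp_test$df, p = grp_test$p,
              pairwise = pairwise, n = nrow(d))
  if (!is.null(second_factor)) out$second_factor <- drop_term(second_factor)
  out
}

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean(x) - mean(y)) / s_p`, with `s_p` the df-weighted pooled
#' standard deviation.
#'
#' @param x,y Numeric samples with `n >= 2` each.
#' @return Scalar effect size.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs n >= 2")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 < 1e-300) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Convert Cohen's d to the effect-size correlation r
#'
#' `r = d / sqrt(d^2 + 4)` (equal-n two-group conversion); odd, strictly
#' increasing, bounded in (-1, 1).
#'
#' @param d Effect size(s).
#' @return Effect-size correlation(s).
#' @export
d_to_r <- function(d) d / sqrt(d^2 + 4)

#' Pearson or Spearman correlation with two-sided p value
#'
#' @param x,y Numeric vectors (`n >= 3` complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' RANSAC robust regression with control-variable residualization
#'
#' Age/sex/education-style control variables are first residualized out of
#' both the predictors and the outcome by ordinary least squares. RANSAC
#' then repeatedly fits minimal samples of the residualized data, scores
#' inliers by absolute residual against a threshold (default 1.5 x the MAD
#' of the full-OLS residuals), and refits the largest consensus set by
#' least squares.
#'
#' @param X Numeric matrix or data frame of predictors.
#' @param y Numeric outcome.
#' @param controls Optional matrix/data frame of control variables.
#' @param iterations Number of minimal-sample draws (default 1000).
#' @param inlier_threshold Absolute-residual threshold; `NULL` for the MAD
#'   default.
#' @param min_consensus Minimum consensus-set size (default `p + 2`).
#' @param seed Integer seed.
#' @return A `ransac_fit`: list with `coefficients` (named, incl.
#'   intercept), `inliers` (logical), `n_inliers`, `threshold`.
#' @export
ransac_fit <- function(X, y, controls = NULL, iterations = 1000L,
                       inlier_threshold = NULL, min_consensus = NULL,
                       seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y sizes disagree")
  if (!is.null(controls)) {
    C <- stats::model.matrix(~ ., data = as.data.frame(controls))
    resid_on <- function(v) stats::lm.fit(C, v)$residuals
    y <- resid_on(y)
    X <- apply(X, 2, resid_on)
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  m <- p + 2                       # minimal sample: exact fit + 1 dof
  if (n <= m) stop("too few observations for RANSAC")
  if (is.null(min_consensus)) min_consensus <- p + 2
  ols <- stats::lm.fit(Xi, y)
  if (is.null(inlier_threshold)) {
    inlier_threshold <- 1.5 * stats::mad(ols$residuals)
    if (inlier_threshold < 1e-12) inlier_threshold <- 1e-12
  }
  set.seed(seed)
  best <- NULL
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, m)
    cf <- tryCatch(stats::lm.fit(Xi[idx, , drop = FALSE], y[idx])$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || any(is.na(cf))) next
    res <- abs(y - Xi %*% cf)
    inl <- res <= inlier_threshold
    score <- sum(inl)
    if (is.null(best) || score > best$score) {
      best <- list(score = score, inliers = inl)
    }
  }
  if (is.null(best) || best$score < min_consensus) {
    stop("no consensus set of at least ", min_consensus, " points found")
  }
  inl <- as.vector(best$inliers)
  refit <- stats::lm.fit(Xi[inl, , drop = FALSE], y[inl])
  dfree <- sum(inl) - ncol(Xi)
  sigma2_t <- sum(refit$residuals^2) / max(dfree, 1)
  # the consensus set trims residuals beyond the threshold, so the naive
  # variance is biased low; rescale by the normal truncation factor
  # (fixed-point in the standardized cutoff) to keep CIs near nominal
  trunc_factor <- function(cc) {
    if (!is.finite(cc) || cc > 8) return(1)
    z <- 2 * stats::pnorm(cc) - 1
    if (z < 1e-12) return(1e-12)
    max(1e-12, 1 - 2 * cc * stats::dnorm(cc) / z)
  }
  sigma2 <- sigma2_t
  for (it in 1:8) {
    sigma2 <- sigma2_t / trunc_factor(inlier_threshold / sqrt(sigma2))
  }
  covb <- sigma2 * chol2inv(qr.R(refit$qr))
  se <- sqrt(diag(covb))[order(refit$qr$pivot)]
  names(se) <- names(refit$coefficients)
  structure(list(coefficients = refit$coefficients, se = se, df = dfree,
                 inliers = inl, n_inliers = sum(inl),
                 threshold = inlier_threshold,
                 controls_residualized = !is.null(controls)),
            class = "ransac_fit")
}
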