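test_that("omnibus tests match closed-form cases", {
  g <- factor(rep(c("HC", "mild", "severe"), each = 10))
  y <- rep(c(1, 2, 3), each = 10) * 0 + rep(1:10, 3)   # identical groups
  res <- expect_warning(group_compare(y, g), NA)
  expect_lt(res$statistic, 1e-20)
  expect_gt(res$p, 0.999)

  tab <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  chi <- group_compare(tab, NULL, kind = "chi2", correct = FALSE)
  expect_equal(unname(chi$statistic), 20)
  expect_equal(unname(chi$df), 1)
})

test_that("Tukey post hoc flags the separated group", {
  set.seed(7)
  g <- factor(rep(c("HC", "mild", "severe"), each = 30))
  y <- rnorm(90) + rep(c(0, 0, 2), each = 30)
  res <- group_compare(y, g)
  tk <- res$tukey
  expect_equal(nrow(tk), 3)
  expect_lt(tk$p_adj[tk$contrast == "severe-HC"], 0.001)
  expect_gt(tk$p_adj[tk$contrast == "mild-HC"], 0.05)
})

test_that("ANCOVA removes confounding that acts purely through covariates", {
  set.seed(8)
  n <- 90
  g <- factor(rep(c("HC", "mild", "severe"), each = n / 3))
  age <- c(rnorm(30, 40, 5), rnorm(30, 50, 5), rnorm(30, 60, 5))
  sex <- factor(sample(c("M", "F"), n, TRUE))
  edu <- rnorm(n, 9, 3)
  y <- 0.5 * age + rnorm(n, sd = 1)   # group enters only through age
  d <- data.frame(y = y, group = g, age = age, sex = sex, education = edu)
  res <- ancova(d, "y", "group")
  expect_gt(res$p, 0.01)
  expect_lt(max(abs(res$pairwise$estimate)), 1.5)
  # unadjusted comparison is grossly significant
  raw <- group_compare(y, g)
  expect_lt(raw$p, 1e-10)
})

test_that("Bonferroni adjustment multiplies and caps pairwise p values", {
  set.seed(9)
  d <- data.frame(y = rnorm(60), group = factor(rep(c("a", "b", "c"), 20)),
                  age = rnorm(60, 50, 10),
                  sex = factor(sample(c("M", "F"), 60, TRUE)),
                  education = rnorm(60, 9, 3))
  res <- ancova(d, "y", "group")
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p_raw * 3))
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p_raw))
})

test_that("rank ANCOVA is invariant to monotone outcome transforms", {
  set.seed(10)
  d <- data.frame(y = rlnorm(60), group = factor(rep(c("a", "b", "c"), 20)),
                  age = rnorm(60, 50, 10),
                  sex = factor(sample(c("M", "F"), 60, TRUE)),
                  education = rnorm(60, 9, 3))
  r1 <- ancova(d, "y", "group", ranked = TRUE)
  d2 <- d; d2$y <- log(d2$y)          # strictly monotone transform
  r2 <- ancova(d2, "y", "group", ranked = TRUE)
  expect_equal(r1$f, r2$f, tolerance = 1e-12)
  expect_equal(r1$pairwise$p_raw, r2$pairwise$p_raw, tolerance = 1e-12)
})

test_that("a second factor yields two-way main-effect tests", {
  set.seed(11)
  d <- data.frame(y = rnorm(80), group = factor(rep(c("a", "b"), 40)),
                  hyper = factor(rep(c("no", "yes"), each = 40)),
                  age = rnorm(80, 50, 10),
                  sex = factor(sample(c("M", "F"), 80, TRUE)),
                  education = rnorm(80, 9, 3))
  res <- ancova(d, "y", "group", second_factor = "hyper")
  expect_true(is.finite(res$second_factor$f))
  expect_true(res$second_factor$p > 0 && res$second_factor$p <= 1)
})

test_that("effect-size conversion is exact and well behaved", {
  x <- c(10, 12, 14, 16); y <- c(8, 9, 10, 11)
  d <- cohens_d(x, y)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(d, (13 - 9.5) / sp)
  expect_equal(d_to_r(0), 0)
  grid <- seq(-6, 6, by = 0.25)
  r <- d_to_r(grid)
  expect_true(all(diff(r) > 0))
  expect_true(all(abs(r) < 1))
  expect_equal(d_to_r(-grid), -r)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("correlation handles linear and monotone relationships", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  cub <- correlate(x - 10.5, (x - 10.5)^3)
  expect_equal(correlate(x - 10.5, (x - 10.5)^3, "spearman")$r, 1)
  expect_lt(cub$r, 1)
  expect_error(correlate(x, rep(1, 20)), "constant")
})

test_that("RANSAC equals OLS on clean data and resists gross outliers", {
  set.seed(12)
  n <- 150
  X <- matrix(rnorm(n), ncol = 1)
  y <- 1 + 2 * X[, 1] + rnorm(n, sd = 0.2)
  rf <- ransac_fit(X, y, seed = 1)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(rf$coefficients), unname(ols), tolerance = 0.05)
  # the 1.5-sigma default threshold keeps ~87% of clean normal residuals
  expect_gt(rf$n_inliers, 0.8 * n)

  y2 <- y; y2[1:30] <- y2[1:30] + 10    # 20% gross outliers
  rf2 <- ransac_fit(X, y2, seed = 1)
  expect_lt(abs(rf2$coefficients["x1"] - 2) / 2, 0.05)
  expect_lt(rf2$n_inliers, n)
})

test_that("RANSAC nulls are covered and controls are residualized out", {
  set.seed(13)
  cover <- vapply(1:50, function(s) {
    X <- matrix(rnorm(60), ncol = 1)
    y <- rnorm(60)
    rf <- ransac_fit(X, y, seed = s, iterations = 200)
    ci <- rf$coefficients["x1"] + c(-1, 1) * qt(0.975, rf$df) * rf$se["x1"]
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # a predictor that only proxies a control carries no signal afterwards
  set.seed(14)
  age <- rnorm(200, 50, 10)
  X <- matrix(age + rnorm(200, sd = 0.5), ncol = 1)
  y <- 0.5 * age + rnorm(200, sd = 0.5)
  rf <- ransac_fit(X, y, controls = data.frame(age = age), seed = 2)
  expect_lt(abs(rf$coefficients["x1"]), 0.2)   # confounded slope would be ~0.5
})
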