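test_that("enhancement normalizes against the baseline mean", {
  g <- dce_grid()
  flat <- time_intensity_curve(g$t, rep(100, 23), g$baseline_window,
                               g$injection_time)
  expect_equal(enhancement(flat), rep(0, 23))
  s <- rep(100, 23); s[10] <- 150
  curve <- time_intensity_curve(g$t, s, g$baseline_window, g$injection_time)
  expect_equal(max(enhancement(curve)), 0.5)
  bad <- time_intensity_curve(g$t, c(-100, -100, rep(10, 21)),
                              g$baseline_window, g$injection_time)
  expect_error(enhancement(bad), "S0")
})

test_that("semiquantitative metrics match analytic curves", {
  # linear ramp at 0.01/s for 60 s after injection, then flat
  t <- seq(0, 300, by = 10)
  t_inj <- 40
  e <- pmin(pmax(t - t_inj, 0), 60) * 0.01
  curve <- time_intensity_curve(t, 100 * (1 + e), which(t < t_inj), t_inj)
  sq <- semiquant(curve)
  expect_equal(sq$wash_in, 0.01, tolerance = 1e-9)
  expect_equal(sq$ttp, 1.0)   # peak first reached at t_inj + 60 s
  expect_false(sq$degenerate)

  # symmetric triangle: analytic area over the window
  e2 <- pmax(0, 1 - abs(t - (t_inj + 60)) / 60) * 0.2
  curve2 <- time_intensity_curve(t, 100 * (1 + e2), which(t < t_inj), t_inj)
  sq2 <- semiquant(curve2, auc_window = 120)
  expect_equal(sq2$auc, 0.2 * 60 / 120, tolerance = 1e-9)

  # flat curve: degenerate flag with zeroed descriptors
  sq0 <- semiquant(time_intensity_curve(t, rep(100, length(t)),
                                        which(t < t_inj), t_inj))
  expect_true(sq0$degenerate)
  expect_equal(sq0$wash_in, 0)
  expect_equal(sq0$auc, 0)
  expect_error(semiquant(curve, auc_window = 1000), "window")
})

test_that("AUC and wash-in are linear in curve scale while TTP is invariant", {
  g <- dce_grid()
  tr <- sim_truth(tofts = list(ktrans = 0.05, kep = 0.5, vp = 0.01))
  c1 <- gen_dce_curve(tr, g)
  e1 <- enhancement(c1)
  c3 <- time_intensity_curve(g$t, 100 * (1 + 3 * e1), g$baseline_window,
                             g$injection_time)
  s1 <- semiquant(c1); s3 <- semiquant(c3)
  expect_equal(s3$auc, 3 * s1$auc, tolerance = 1e-9)
  expect_equal(s3$wash_in, 3 * s1$wash_in, tolerance = 1e-9)
  expect_equal(s3$ttp, s1$ttp)
})

test_that("noiseless extended-Tofts fits recover the generator truth", {
  g <- dce_grid()
  aif <- biexp_aif(t0 = g$injection_time)
  tr <- sim_truth(tofts = list(ktrans = 0.05, kep = 0.5, vp = 0.01))
  fit <- fit_extended_tofts(gen_dce_curve(tr, g, aif), aif)
  expect_lt(abs(fit$ktrans - 0.05) / 0.05, 0.01)
  expect_lt(abs(fit$kep - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$vp - 0.01) / 0.01, 0.01)
  expect_equal(fit$ve * fit$kep, fit$ktrans, tolerance = 1e-12)
  expect_equal(fit$ve, 0.1, tolerance = 1e-2)
  expect_lt(fit$fit_deviation, 1e-6)

  # null kinetics: Ktrans pinned at zero, Ve reported as 0, bound flagged
  tr0 <- sim_truth(tofts = list(ktrans = 0, kep = 0.5, vp = 0.02))
  fit0 <- fit_extended_tofts(gen_dce_curve(tr0, g, aif), aif)
  expect_lte(fit0$ktrans, 1e-4)
  expect_true(fit0$at_bound)
})

test_that("parameter error grows monotonically with noise", {
  g <- dce_grid()
  aif <- biexp_aif(t0 = g$injection_time)
  tr <- sim_truth(tofts = list(ktrans = 0.05, kep = 0.5, vp = 0.01))
  err_at <- function(sd) {
    errs <- vapply(1:25, function(s) {
      fit <- fit_extended_tofts(gen_dce_curve(tr, g, aif, noise_sd = sd,
                                              seed = s), aif, seed = s)
      abs(fit$ktrans - 0.05) / 0.05
    }, numeric(1))
    stats::median(errs)
  }
  errs <- c(err_at(0.05), err_at(0.5), err_at(2.5))
  expect_true(all(diff(errs) > 0))
})

test_that("the QC filter applies the strict deviation threshold", {
  mk <- function(dev) structure(list(fit_deviation = dev, region = "dorsal_mlv"),
                                class = "tofts_fit")
  res <- qc_filter(lapply(c(0.01, 0.049, 0.05, 0.2), mk))
  expect_length(res$retained, 2)
  expect_equal(res$exclusion_log$retained, c(TRUE, TRUE, FALSE, FALSE))
  g <- dce_grid(); aif <- biexp_aif(t0 = g$injection_time)
  clean <- lapply(1:3, function(i) {
    tr <- sim_truth(tofts = list(ktrans = 0.02 * i, kep = 0.3 + 0.1 * i,
                                 vp = 0.01))
    fit_extended_tofts(gen_dce_curve(tr, g, aif), aif)
  })
  expect_length(qc_filter(clean)$retained, 3)
  expect_warning(qc_filter(list(mk(0.3))), "every fit")
})
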