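test_that("percent-change preprocessing zeroes constant series and guards length", {
  const_pair <- timeseries_pair(rep(50, 200), rep(3, 200) + rnorm(200))
  pp <- preprocess_pair(const_pair)
  expect_lt(max(abs(pp$bold)), 1e-10)
  expect_error(preprocess_pair(timeseries_pair(rnorm(12) + 10, rnorm(12) + 10)),
               "too short")
})

test_that("a 0.05 Hz oscillation passes the band-pass nearly unattenuated", {
  t <- seq_len(400) * 2
  s <- 100 + 5 * sin(2 * pi * 0.05 * t)
  pair <- timeseries_pair(s, s)
  pp <- preprocess_pair(pair)
  mid <- pp$bold[100:300]   # away from filter edges
  in_amp <- 5 / 100 * 100   # percent-change amplitude
  expect_gt(max(abs(mid)) / in_amp, 0.9)
})

test_that("cross-correlation identities hold exactly", {
  set.seed(3)
  b <- as.numeric(scale(stats::filter(rnorm(260), rep(1, 8), sides = 1)[9:248]))
  pair <- timeseries_pair(b, b)
  prof <- xcorr_profile(pair, "bold")
  expect_equal(prof$r[prof$lag == 0], 1)
  # csf equal to the negative derivative: derivative-mode peak exactly 1 at 0
  d <- -glymphr:::central_diff(b, 2)
  pair2 <- timeseries_pair(b, d)
  prof2 <- xcorr_profile(pair2, "negderiv")
  expect_equal(prof2$r[prof2$lag == 0], 1)
  expect_equal(max(abs(prof2$r)), 1)
})

test_that("correlations are invariant to affine rescaling of either series", {
  pair <- gen_bold_csf(seed = 5)
  pp <- preprocess_pair(pair)
  m1 <- coupling_metrics(xcorr_profile(pp, "bold"), xcorr_profile(pp, "negderiv"))
  pair2 <- timeseries_pair(3.7 * pair$bold + 11, 0.2 * pair$csf + 5, tr = pair$tr)
  pp2 <- preprocess_pair(pair2)
  m2 <- coupling_metrics(xcorr_profile(pp2, "bold"), xcorr_profile(pp2, "negderiv"))
  expect_equal(m1$max_strength, m2$max_strength, tolerance = 1e-9)
  expect_equal(m1$r_at_plus2s, m2$r_at_plus2s, tolerance = 1e-9)
})

test_that("swapping the series mirrors the lag axis", {
  pair <- preprocess_pair(gen_bold_csf(seed = 6))
  prof <- xcorr_profile(pair, "bold")
  swapped <- timeseries_pair(pair$csf, pair$bold, tr = pair$tr)
  prof_sw <- xcorr_profile(swapped, "bold")
  expect_equal(prof$r, rev(prof_sw$r), tolerance = 1e-12)
})

test_that("planted coupling strength and lag are recovered", {
  tr <- sim_truth(coupling = list(strength = -0.227, lag = 2, mode = "direct"))
  vals <- numeric(40)
  maxs <- numeric(40)
  for (s in seq_len(40)) {
    pp <- preprocess_pair(gen_bold_csf(tr, seed = 100 + s))
    m <- coupling_metrics(xcorr_profile(pp, "bold"),
                          xcorr_profile(pp, "negderiv"))
    vals[s] <- m$r_at_plus2s
    maxs[s] <- m$max_strength
  }
  # the profile value at the planted lag is an unbiased read of the plant;
  # the max-|r| statistic is magnitude-inflated by selection at this SNR
  expect_lt(abs(mean(vals) - (-0.227)), 0.05)
  expect_lt(mean(maxs), 0)             # sign preserved by the extremum
  expect_gte(mean(abs(maxs)), mean(abs(vals)))

  trd <- sim_truth(coupling = list(strength = 0.9, lag = 4, mode = "derivative"))
  lags <- vapply(seq_len(40), function(s) {
    pp <- preprocess_pair(gen_bold_csf(trd, seed = 200 + s))
    prof <- xcorr_profile(pp, "negderiv")
    prof$lag[which.max(abs(prof$r))]
  }, numeric(1))
  expect_lt(abs(mean(lags) - 4), 2)   # within one TR on average
})

test_that("coupling metrics read fixed lags and break ties toward zero", {
  prof <- data.frame(lag = seq(-20, 20, by = 2),
                     r = rep(0.1, 21))
  prof$r[prof$lag == 2] <- -0.3
  class(prof) <- c("coupling_profile", "data.frame")
  profd <- data.frame(lag = seq(-20, 20, by = 2), r = rep(0.05, 21))
  class(profd) <- c("coupling_profile", "data.frame")
  m <- coupling_metrics(prof, profd)
  expect_equal(m$max_strength, -0.3)
  expect_equal(m$max_lag, 2)
  expect_equal(m$r_at_minus6s, 0.1)
  # tie between +4 and -4: the magnitude ties break toward |lag| nearest 0,
  # and between equal |lag| the earlier (negative) grid entry wins
  prof$r[] <- 0.1; prof$r[abs(prof$lag) == 4] <- 0.4
  m2 <- coupling_metrics(prof, profd)
  expect_equal(abs(m2$max_lag), 4)
  # off-grid lag requests error rather than interpolate
  prof3 <- data.frame(lag = seq(-18, 18, by = 3), r = rep(0.1, 13))
  class(prof3) <- c("coupling_profile", "data.frame")
  expect_error(coupling_metrics(prof3, profd), "grid")
})

test_that("independent series stay inside the null band", {
  set.seed(9)
  tr0 <- sim_truth(coupling = list(strength = 0, lag = 0, mode = "direct"))
  vals <- vapply(seq_len(60), function(s) {
    pp <- preprocess_pair(gen_bold_csf(tr0, seed = 300 + s))
    coupling_metrics(xcorr_profile(pp, "bold"),
                     xcorr_profile(pp, "negderiv"))$max_strength
  }, numeric(1))
  # max-|r| of independent band-limited series: mean magnitude well below
  # the strong-coupling regime, centred on zero
  expect_lt(mean(abs(vals)), 0.5)
  expect_lt(abs(mean(vals)), 0.15)
})
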