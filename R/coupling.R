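#' Construct a BOLD/CSF time-series pair
#'
#' @param bold,csf Numeric vectors of equal length (arbitrary units).
#' @param tr Repetition time in seconds (default 2).
#' @param discarded_volumes Number of initial volumes already removed.
#' @return A `timeseries_pair` object.
#' @export
timeseries_pair <- function(bold, csf, tr = 2, discarded_volumes = 0L) {
  if (length(bold) != length(csf)) stop("bold and csf must have equal length")
  if (tr <= 0) stop("tr must be positive")
  structure(list(bold = as.numeric(bold), csf = as.numeric(csf), tr = tr,
                 discarded_volumes = as.integer(discarded_volumes)),
            class = "timeseries_pair")
}

#' Preprocess a raw BOLD/CSF pair
#'
#' Discards the initial volumes, converts each series to percent change
#' about its temporal mean (`100 * (s - mean) / mean`), and applies a
#' zero-phase Butterworth band-pass (default 0.01-0.1 Hz, order 2 forward +
#' backward via [signal::filtfilt()]).
#'
#' @param pair A raw `timeseries_pair`.
#' @param discard Initial volumes to drop (default 10).
#' @param band Pass band in Hz (default `c(0.01, 0.1)`).
#' @param filter_order Butterworth order per pass direction.
#' @return A preprocessed `timeseries_pair`.
#' @export
preprocess_pair <- function(pair, discard = 10L, band = c(0.01, 0.1),
                            filter_order = 2L) {
  n <- length(pair$bold)
  # filtfilt needs a few filter lengths of support beyond the discard
  if (n - discard < 30) stop("series too short after discarding ", discard,
                             " volumes (need at least 30 for filtering)")
  fs <- 1 / pair$tr
  if (band[2] >= fs / 2) stop("upper band edge must be below Nyquist (",
                              fs / 2, " Hz)")
  pct <- function(s) {
    s <- s[-seq_len(discard)]
    m <- mean(s)
    if (abs(m) < 1e-12 * max(1, stats::sd(s))) {
      stop("temporal mean is ~0; percent change undefined")
    }
    100 * (s - m) / m
  }
  bw <- signal::butter(filter_order, band / (fs / 2), type = "pass")
  bp <- function(s) as.numeric(signal::filtfilt(bw, s))
  timeseries_pair(bp(pct(pair$bold)), bp(pct(pair$csf)), tr = pair$tr,
                  discarded_volumes = discard)
}

#' Lagged cross-correlation profile between BOLD (or its negative
#' derivative) and CSF
#'
#' For each lag `l` (a multiple of TR in `[-lag_window, +lag_window]`),
#' computes the Pearson correlation between `csf(t)` and `reference(t - l)`
#' over the overlapping support, with no padding. A positive lag therefore
#' means the reference (BOLD) leads CSF. In `"negderiv"` mode the reference
#' is the negative first-order temporal derivative of BOLD (central
#' differences; one-sided at the ends).
#'
#' @param pair A preprocessed `timeseries_pair`.
#' @param mode `"bold"` or `"negderiv"`.
#' @param lag_window Half-width of the lag window in seconds (default 20).
#' @return A `coupling_profile`: data frame with `lag` (s) and `r`, plus a
#'   `mode` attribute.
#' @export
xcorr_profile <- function(pair, mode = c("bold", "negderiv"), lag_window = 20) {
  mode <- match.arg(mode)
  n <- length(pair$bold)
  tr <- pair$tr
  max_k <- floor(lag_window / tr)
  if (max_k * tr >= (n - 3) * tr) stop("lag window must be well below the series span")
  ref <- if (mode == "bold") pair$bold else -central_diff(pair$bold, tr)
  ks <- seq.int(-max_k, max_k)
  r <- vapply(ks, function(k) {
    if (k >= 0) {
      a <- pair$csf[(1 + k):n]; b <- ref[1:(n - k)]
    } else {
      a <- pair$csf[1:(n + k)]; b <- ref[(1 - k):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("zero-variance segment in cross-correlation window")
    }
    stats::cor(a, b)
  }, numeric(1))
  out <- data.frame(lag = ks * tr, r = r)
  attr(out, "mode") <- mode
  class(out) <- c("coupling_profile", "data.frame")
  out
}

central_diff <- function(s, dt) {
  n <- length(s)
  d <- numeric(n)
  d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  d[1] <- (s[2] - s[1]) / dt
  d[n] <- (s[n] - s[n - 1]) / dt
  d
}

#' Summarise coupling profiles into the reported metrics
#'
#' From the direct BOLD-vs-CSF profile: the signed correlation of largest
#' magnitude (`max_strength`; ties broken toward the lag nearest 0) and the
#' correlations read directly at lags +2 s and -6 s. From the
#' negative-derivative profile: the correlation at lag 0.
#'
#' @param profile_bold A `"bold"`-mode [xcorr_profile()] covering -6 s and
#'   +2 s.
#' @param profile_deriv A `"negderiv"`-mode profile covering lag 0.
#' @return Named list: `max_strength`, `max_lag`, `r_at_plus2s`,
#'   `r_at_minus6s`, `deriv_coupling_at_0`.
#' @export
coupling_metrics <- function(profile_bold, profile_deriv) {
  read_at <- function(prof, lag) {
    i <- which(abs(prof$lag - lag) < 1e-9)
    if (!length(i)) {
      stop("lag ", lag, " s is not on the profile grid; TR must divide it")
    }
    prof$r[i]
  }
  ord <- order(-abs(profile_bold$r), abs(profile_bold$lag))
  best <- ord[1]
  list(max_strength = profile_bold$r[best],
       max_lag = profile_bold$lag[best],
       r_at_plus2s = read_at(profile_bold, 2),
       r_at_minus6s = read_at(profile_bold, -6),
       deriv_coupling_at_0 = read_at(profile_deriv, 0))
}
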