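# Shared fixtures, all built in code at test time.

# z-scored-looking signal with Gaussian bumps of given heights at given times
bump_signal <- function(peak_times, heights, fs = 100, duration = NULL,
                        width = 0.05) {
  if (is.null(duration)) duration <- max(peak_times) + 1
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  for (i in seq_along(peak_times)) {
    x <- x + heights[i] * exp(-(t - peak_times[i])^2 / (2 * width^2))
  }
  list(values = x, fs = fs)
}

# pulse train object straight from peak times (bypasses detection)
train_from_times <- function(times, fs = 100, channel = "test") {
  structure(list(peak_times = times,
                 peak_indices = round(times * fs) + 1L,
                 ibis = diff(times) * 1000, fs = fs, channel = channel),
            class = "pulse_train")
}

# tachogram with sinusoidally modulated inter-beat intervals, long enough
# for stable spectra
modulated_prv <- function(f_mod, amp_ms, mean_ibi = 800, duration = 300,
                          f2 = NULL, amp2 = 0) {
  t <- 0; ts <- numeric(0)
  while (t < duration) {
    ts <- c(ts, t)
    ibi <- mean_ibi + amp_ms * sin(2 * pi * f_mod * t)
    if (!is.null(f2)) ibi <- ibi + amp2 * sin(2 * pi * f2 * t)
    t <- t + ibi / 1000
  }
  structure(list(ibis = diff(ts) * 1000, times = ts[-1]), class = "prv_series")
}

# measured gain of the default band-pass for a sinusoid at f Hz, estimated by
# projecting the mid-record output onto the quadrature pair (immune to edge
# transients and sample-phase effects)
bp_gain <- function(f, fs = 100, duration = 60) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  y <- bandpass_zero_lag(sin(2 * pi * f * t), fs = fs)
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  s <- sin(2 * pi * f * t[mid]); c_ <- cos(2 * pi * f * t[mid])
  co <- stats::lm.fit(cbind(s, c_), y[mid])$coefficients
  sqrt(sum(co^2))
}

expect_all_matched <- function(truth_times, detected_times, tol_s = 0.011) {
  worst <- max(vapply(truth_times,
                      function(t) min(abs(detected_times - t)), numeric(1)))
  expect_lte(worst, tol_s)
}
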