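#' Convert raw PPG intensity to optical density
#'
#' Absorption changes are linearized by taking `OD = -ln(I / I_ref)` with the
#' channel's temporal mean as the reference intensity. The logarithm base and
#' reference choice only rescale/shift the OD and are removed by the later
#' z-scoring, so they are inconsequential for the downstream features; the
#' natural log + mean-reference convention is fixed here and pinned by tests.
#'
#' @param raw numeric vector of strictly positive intensities.
#' @return numeric OD vector (mean approximately 0 by construction).
#' @export
to_optical_density <- function(raw) {
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)) || any(raw <= 0)) stop("invalid intensity")
  -log(raw / mean(raw))
}

#' Decimate a signal with an anti-alias filter
#'
#' Low-pass filters with a linear-phase windowed-sinc FIR (zero-phase via
#' centered convolution, edges reflection-padded) before keeping every
#' `factor`-th sample. Plain subsampling would alias any content above the new
#' Nyquist rate into the pulse band, so decimation is always filtered.
#'
#' @param x numeric signal.
#' @param factor integer decimation factor (>= 1); 10 maps 1 kHz to 100 Hz.
#' @param fs input sampling rate in Hz (used only to size the kernel).
#' @return list with `values` (length `floor(n / factor)`) and `fs` (`fs / factor`).
#' @export
decimate <- function(x, factor = 10L, fs = 1000) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("invalid factor")
  x <- as.numeric(x)
  n <- length(x)
  n_out <- n %/% factor
  if (factor == 1L) return(list(values = x, fs = fs))
  numtaps <- 20L * factor + 1L
  h <- fir_lowpass(cutoff_hz = fs / (2 * factor), fs = fs, numtaps = numtaps)
  m <- (length(h) - 1L) / 2L
  # reflect-pad so the centered convolution is defined at the edges
  xe <- c(x[(m + 1):2], x, x[(n - 1):(n - m)])
  xf <- stats::filter(xe, h, method = "convolution", sides = 2)
  xf <- as.numeric(xf)[(m + 1):(m + n)]
  list(values = xf[seq(1L, by = factor, length.out = n_out)], fs = fs / factor)
}

#' Zero-lag Butterworth band-pass filter
#'
#' Designs a 4th-order (by default) Butterworth band-pass and applies it
#' forward and backward, so the phase response is identically zero and peak
#' positions are preserved. Note the effective magnitude response is the
#' square of the single-pass design (half-power, not -3 dB, at the edges).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz; must exceed `2 * high`.
#' @param low,high cut-off frequencies in Hz.
#' @param order prototype filter order.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_zero_lag <- function(x, fs, low = 0.2, high = 10, order = 4L) {
  if (fs <= 2 * high) stop("cutoff above Nyquist")
  sos <- butter_bandpass_sos(low, high, fs, order)
  sosfiltfilt(sos, as.numeric(x))
}

#' z-score a signal (population-sd convention)
#'
#' Signals are standardized with the population standard deviation (divide by
#' n); cohort feature tables use the sample convention (n - 1) instead — see
#' [fit_glm()]. The two conventions are deliberate and pinned by tests.
#'
#' @param x numeric vector with positive variance.
#' @return numeric vector with mean 0 and population sd 1.
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) stop("zero variance")
  (x - mean(x)) / s
}

#' Run the full PPG pre-processing chain on one channel
#'
#' Raw intensity -> optical density -> anti-aliased x10 decimation -> zero-lag
#' 4th-order Butterworth band-pass (0.2--10 Hz) -> z-score. Filtering precedes
#' normalization; the provenance of applied steps travels with the result.
#'
#' @param raw numeric vector of strictly positive intensities.
#' @param fs raw sampling rate in Hz (nominally 1000).
#' @param decimation_factor integer decimation factor.
#' @param bp_low_hz,bp_high_hz band-pass cut-offs in Hz.
#' @param filter_order Butterworth prototype order.
#' @return object of class `processed_signal`: list with `values`, `fs`,
#'   `provenance`.
#' @export
preprocess_ppg <- function(raw, fs = 1000, decimation_factor = 10L,
                           bp_low_hz = 0.2, bp_high_hz = 10, filter_order = 4L) {
  od <- to_optical_density(raw)
  dec <- decimate(od, factor = decimation_factor, fs = fs)
  filt <- bandpass_zero_lag(dec$values, fs = dec$fs, low = bp_low_hz,
                            high = bp_high_hz, order = filter_order)
  z <- zscore(filt)
  structure(
    list(values = z, fs = dec$fs,
         provenance = c("optical_density",
                        sprintf("decimate_x%d", decimation_factor),
                        sprintf("butterworth_bandpass_%g_%g_order%d_zerolag",
                                bp_low_hz, bp_high_hz, filter_order),
                        "zscore_population")),
    class = "processed_signal")
}

#' @export
print.processed_signal <- function(x, ...) {
  cat(sprintf("<processed_signal> %d samples @ %g Hz\n  steps: %s\n",
              length(x$values), x$fs, paste(x$provenance, collapse = " -> ")))
  invisible(x)
}
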