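#' Welch power spectral density
#'
#' Hann-windowed, mean-removed, overlapping-segment averaged periodogram with
#' density scaling (units x^2/Hz). For a 30 s tachogram the default is a
#' single full-length segment (the periodogram limit of Welch): shorter
#' segments could not resolve the 0.03 Hz lower edge of the LF band at all.
#'
#' @param x numeric signal, evenly sampled.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length; defaults to the full record.
#' @param overlap fractional overlap between segments (ignored for one segment).
#' @return list with `freq` (Hz) and `psd` (x^2/Hz), one-sided.
#' @export
welch_psd <- function(x, fs, nperseg = length(x), overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8) stop("record too short for spectral estimation")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  u <- sum(w^2)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nf])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nperseg is even)
  scale <- rep(2, nf); scale[1] <- 1
  if (nperseg %% 2 == 0) scale[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / nperseg, psd = psd * scale)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Trapezoidal integral of the PSD over [f1, f2]; the band edges are included
# exactly by linear interpolation of the PSD at f1 and f2.
band_power <- function(freq, psd, f1, f2) {
  if (f2 <= freq[1] || f1 >= freq[length(freq)]) return(0)
  f1 <- max(f1, freq[1]); f2 <- min(f2, freq[length(freq)])
  inner <- freq > f1 & freq < f2
  fg <- c(f1, freq[inner], f2)
  pg <- c(stats::approx(freq, psd, xout = f1)$y,
          psd[inner],
          stats::approx(freq, psd, xout = f2)$y)
  sum(diff(fg) * (utils::head(pg, -1) + utils::tail(pg, -1)) / 2)
}

#' LF/HF ratio of a pulse-rate-variability series
#'
#' The irregularly sampled tachogram is cubic-spline interpolated to an even
#' `fs_interp` grid (standard HRV practice), mean-removed, and its PSD is
#' estimated by Welch's method (one Hann segment by default). LF power is the
#' trapezoidal integral over 0.03--0.15 Hz, HF over 0.15--0.35 Hz.
#'
#' Records much shorter than ~60 s carry about one cycle at the 0.03 Hz LF
#' edge, so the LF estimate is fragile there; a warning is emitted below
#' `min_record_s` (the computation still runs for records down to 20 s).
#'
#' @param prv a `prv_series` from [compute_prv()].
#' @param fs_interp even-grid resampling rate in Hz.
#' @param lf_band,hf_band frequency bands in Hz.
#' @param min_record_s record length below which a reliability warning fires.
#' @return LF/HF power ratio (unitless).
#' @export
lf_hf_ratio <- function(prv, fs_interp = 4,
                        lf_band = c(0.03, 0.15), hf_band = c(0.15, 0.35),
                        min_record_s = 60) {
  span <- prv$times[length(prv$times)] - prv$times[1]
  if (length(prv$ibis) < 10 || span < 20) stop("insufficient beats")
  if (span < min_record_s) {
    warning(sprintf("PRV record spans %.1f s (< %g s); LF estimate near 0.03 Hz is fragile",
                    span, min_record_s))
  }
  grid <- seq(prv$times[1], prv$times[length(prv$times)], by = 1 / fs_interp)
  tach <- stats::spline(prv$times, prv$ibis, xout = grid, method = "fmm")$y
  ps <- welch_psd(tach, fs = fs_interp)
  lf <- band_power(ps$freq, ps$psd, lf_band[1], lf_band[2])
  hf <- band_power(ps$freq, ps$psd, hf_band[1], hf_band[2])
  if (hf <= .Machine$double.eps * max(ps$psd) * length(ps$psd)) {
    stop("degenerate spectrum")
  }
  lf / hf
}
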