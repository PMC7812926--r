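#' Design a Butterworth band-pass filter as second-order sections
#'
#' Designs an order-`order` analog Butterworth low-pass prototype, applies the
#' low-pass-to-band-pass transform and the bilinear transform (with frequency
#' pre-warping), and returns the digital filter as a cascade of biquads.
#' Second-order sections are used instead of a single transfer function because
#' the pass band (0.2--10 Hz at a 100 Hz rate) is narrow relative to Nyquist
#' and an order-8 polynomial form is numerically fragile there.
#'
#' @param low,high band edges in Hz (`0 < low < high < fs/2`).
#' @param fs sampling rate in Hz.
#' @param order order of the low-pass prototype; the band-pass filter has
#'   `2 * order` poles.
#' @return numeric matrix with one row per section and columns
#'   `b0, b1, b2, a0, a1, a2` (`a0` is always 1).
#' @seealso [sosfiltfilt()] for zero-phase application.
#' @export
butter_bandpass_sos <- function(low, high, fs, order = 4L) {
  stopifnot(is.numeric(low), is.numeric(high), is.numeric(fs), order >= 1)
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) stop("cutoff above Nyquist")
  n <- as.integer(order)

  # analog low-pass prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  # pre-warp band edges for the bilinear transform
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # low-pass -> band-pass in pole/zero form: n zeros at s = 0, 2n poles
  p_sc <- p_lp * bw / 2
  p_bp <- c(p_sc + sqrt(p_sc^2 - w0^2), p_sc - sqrt(p_sc^2 - w0^2))
  k_bp <- bw^n

  # bilinear transform; analog zeros at s = 0 map to z = 1, the n-fold degree
  # deficit contributes n zeros at z = -1
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  k_z <- k_bp * Re(prod(fs2 - rep(0i, n)) / prod(fs2 - p_bp))

  # pair conjugate poles into biquads; each section gets one zero at +1 and
  # one at -1, so b = g * (1, 0, -1); sections ordered with poles farthest
  # from the unit circle first
  p_up <- p_z[Im(p_z) > 0]
  p_up <- p_up[order(Mod(p_up))]
  if (length(p_up) != n) stop("internal error: expected ", n, " conjugate pole pairs")
  g <- abs(k_z)^(1 / n)
  sos <- t(vapply(p_up, function(p) {
    c(g, 0, -g, 1, -2 * Re(p), Mod(p)^2)
  }, numeric(6)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# Single-pass cascade filter (direct form II transposed) with optional
# per-section initial conditions `zi` (n_sections x 2 matrix).
sosfilt <- function(sos, x, zi = NULL) {
  nsec <- nrow(sos)
  if (is.null(zi)) zi <- matrix(0, nsec, 2)
  y <- as.numeric(x)
  for (s in seq_len(nsec)) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    a1 <- sos[s, 5]; a2 <- sos[s, 6]
    z1 <- zi[s, 1]; z2 <- zi[s, 2]
    out <- numeric(length(y))
    for (i in seq_along(y)) {
      xi <- y[i]
      yi <- b0 * xi + z1
      z1 <- b1 * xi - a1 * yi + z2
      z2 <- b2 * xi - a2 * yi
      out[i] <- yi
    }
    y <- out
  }
  y
}

# Steady-state DF2T state of each section for a unit-step input; used to
# suppress start-up transients in sosfiltfilt (same idea as scipy's
# sosfilt_zi: scale by the first sample of the padded signal).
sosfilt_zi <- function(sos) {
  nsec <- nrow(sos)
  zi <- matrix(0, nsec, 2)
  scale <- 1
  for (s in seq_len(nsec)) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    a1 <- sos[s, 5]; a2 <- sos[s, 6]
    yss <- (b0 + b1 + b2) / (1 + a1 + a2)
    z2 <- (b2 - a2 * yss) * scale
    z1 <- z2 + (b1 - a1 * yss) * scale
    zi[s, ] <- c(z1, z2)
    scale <- scale * yss
  }
  zi
}

#' Zero-phase (forward-backward) filtering with second-order sections
#'
#' Applies the cascade forward and then backward so the net phase response is
#' zero and the magnitude response is squared. Edges are handled by odd
#' (anti-symmetric) extension plus steady-state initial conditions, which keeps
#' transients out of the retained samples even for low cut-off frequencies.
#'
#' @param sos section matrix from [butter_bandpass_sos()].
#' @param x numeric signal.
#' @param padlen extension length in samples at each end; default
#'   `min(n - 1, max(150, 9 * nrow(sos)))`.
#' @param pad `"even"` (mirror, default) or `"odd"` (anti-symmetric)
#'   extension. The even extension preserves the local mean of pulsatile
#'   signals at the record boundary — an odd extension flips the pulses
#'   upside down, and the resulting low-frequency step is smeared over
#'   several seconds by a 0.2 Hz high-pass.
#' @return filtered signal, same length as `x`.
#' @export
sosfiltfilt <- function(sos, x, padlen = NULL, pad = c("even", "odd")) {
  pad <- match.arg(pad)
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, max(150L, 9L * nrow(sos)))
  if (n <= padlen) stop("signal too short for the requested pad length")
  if (padlen > 0) {
    head_ext <- x[(padlen + 1):2]
    tail_ext <- x[(n - 1):(n - padlen)]
    if (pad == "odd") {
      head_ext <- 2 * x[1] - head_ext
      tail_ext <- 2 * x[n] - tail_ext
    }
    xe <- c(head_ext, x, tail_ext)
  } else {
    xe <- x
  }
  zi <- sosfilt_zi(sos)
  y <- sosfilt(sos, xe, zi * xe[1])
  y <- rev(sosfilt(sos, rev(y), zi * y[length(y)]))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

# Windowed-sinc low-pass FIR kernel (Hamming window), unit DC gain, odd length.
fir_lowpass <- function(cutoff_hz, fs, numtaps) {
  if (numtaps %% 2 == 0) numtaps <- numtaps + 1L
  m <- (numtaps - 1) / 2
  t <- seq(-m, m)
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc_(2 * fc * t)
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h / sum(h)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
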