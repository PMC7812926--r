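#' Detect systolic peaks on a z-scored PPG signal
#'
#' Local maxima are accepted if they reach `min_height` on the normalized
#' scale; among candidates closer together than `min_distance_ms` the taller
#' one wins (earlier on ties), applied greedily from the tallest candidate
#' down. The 600 ms floor corresponds to a 100 bpm ceiling, compatible with
#' resting heart rate.
#'
#' @param signal a `processed_signal` (or list with `values`, `fs`).
#' @param min_height minimum peak value on the z-scored signal.
#' @param min_distance_ms minimum inter-peak distance in ms.
#' @param channel site label carried on the returned train.
#' @return object of class `pulse_train`: `peak_times` (s), `peak_indices`,
#'   `ibis` (ms), `fs`, `channel`.
#' @export
detect_peaks <- function(signal, min_height = 2, min_distance_ms = 600,
                         channel = "ppg") {
  x <- signal$values
  fs <- signal$fs
  n <- length(x)
  if (n < 3) stop("insufficient beats")
  # strict rise into the sample, non-strict fall out, so plateaus keep their
  # first sample (ties -> earlier)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  min_dist <- min_distance_ms / 1000 * fs
  if (length(cand) > 1) {
    ord <- order(-x[cand], cand)     # tallest first, earlier breaks ties
    keep <- logical(length(cand))
    taken <- integer(0)
    for (j in ord) {
      if (!any(abs(cand[j] - taken) < min_dist)) {
        keep[j] <- TRUE
        taken <- c(taken, cand[j])
      }
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 2) stop("insufficient beats")
  times <- (cand - 1) / fs
  structure(
    list(peak_times = times, peak_indices = cand,
         ibis = diff(times) * 1000, fs = fs, channel = channel),
    class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %s: %d peaks, mean IBI %.1f ms\n",
              x$channel, length(x$peak_times), mean(x$ibis)))
  invisible(x)
}

#' Trimmed single-pulse average
#'
#' Extracts a window around every systolic peak that fits inside the record,
#' builds a per-sample 25th--75th percentile envelope over the aligned pulses,
#' and averages only the pulses that stay entirely inside the envelope ("all
#' the values" between the quartiles). If no pulse survives, the plain mean is
#' used and a warning is issued.
#'
#' @param signal a `processed_signal`.
#' @param train a `pulse_train` detected on the same signal.
#' @param window two-element window in s relative to the peak, default
#'   `c(-0.6, 1.2)`.
#' @param trim lower/upper envelope percentiles, default `c(25, 75)`.
#' @return object of class `pulse_average`: `waveform`, `t` (window time
#'   axis, s), `stderr`, `n_used`, `n_total`.
#' @export
pulse_average <- function(signal, train, window = c(-0.6, 1.2), trim = c(25, 75)) {
  x <- signal$values
  fs <- signal$fs
  pre <- round(-window[1] * fs)
  post <- round(window[2] * fs)
  idx <- train$peak_indices
  idx <- idx[idx - pre >= 1 & idx + post <= length(x)]
  if (length(idx) < 3) stop("insufficient beats")
  mat <- vapply(idx, function(i) x[(i - pre):(i + post)], numeric(pre + post + 1))
  lo <- apply(mat, 1, stats::quantile, probs = trim[1] / 100, names = FALSE)
  hi <- apply(mat, 1, stats::quantile, probs = trim[2] / 100, names = FALSE)
  # numeric head-room so floating-point-level differences between otherwise
  # identical pulses cannot disqualify them from the envelope
  tol <- 1e-8 * diff(range(mat))
  inside <- apply(mat >= lo - tol & mat <= hi + tol, 2, all)
  if (!any(inside)) {
    warning("no pulse inside the trim envelope; falling back to plain mean")
    inside <- rep(TRUE, ncol(mat))
  }
  kept <- mat[, inside, drop = FALSE]
  n_used <- ncol(kept)
  wav <- rowMeans(kept)
  se <- if (n_used > 1) apply(kept, 1, stats::sd) / sqrt(n_used) else rep(0, nrow(kept))
  structure(
    list(waveform = wav, t = seq(-pre, post) / fs, stderr = se,
         n_used = n_used, n_total = length(idx)),
    class = "pulse_average")
}

#' Inter-site transit delay between two pulse trains
#'
#' Each distal (ulnar) peak is matched to the nearest preceding proximal
#' (brachial) peak no more than `pairing_window_ms` earlier — a bound chosen
#' to cover physiologic arm transit times. The delay is the 25--75 percentile
#' trimmed mean of the paired differences, positive when the distal site lags.
#'
#' @param brachial,ulnar `pulse_train` objects for the proximal and distal site.
#' @param pairing_window_ms maximum allowed proximal-to-distal lag in ms.
#' @return delay in ms.
#' @export
estimate_td <- function(brachial, ulnar, pairing_window_ms = 300) {
  tb <- brachial$peak_times
  tu <- ulnar$peak_times
  if (!length(tb) || !length(tu)) stop("unpairable channels")
  diffs <- vapply(tu, function(t) {
    prev <- tb[tb <= t]
    if (!length(prev)) return(NA_real_)
    d <- (t - max(prev)) * 1000
    if (d <= pairing_window_ms) d else NA_real_
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  if (!length(diffs)) stop("unpairable channels")
  trimmed_mean_2575(diffs)
}

# mean of the values lying inside the closed [25th, 75th] percentile band
trimmed_mean_2575 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  mean(x[x >= q[1] & x <= q[2]])
}

#' Pulse-rate-variability series from a pulse train
#'
#' Successive peak-to-peak intervals (the tachogram), time-stamped at the
#' later peak of each pair. The PRV series is deliberately not filtered.
#'
#' @param train a `pulse_train` with at least 2 peaks (a 2-peak train yields a
#'   single interval — valid here, but rejected by the spectral stage).
#' @return object of class `prv_series`: `ibis` (ms), `times` (s).
#' @export
compute_prv <- function(train) {
  if (length(train$peak_times) < 2) stop("insufficient beats")
  structure(
    list(ibis = diff(train$peak_times) * 1000,
         times = train$peak_times[-1]),
    class = "prv_series")
}

# internal: build a prv_series straight from beat times (ground truth path)
prv_from_times <- function(times) {
  structure(list(ibis = diff(times) * 1000, times = times[-1]),
            class = "prv_series")
}
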