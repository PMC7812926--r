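#' Waveform parameters for the synthetic two-site PPG generator
#'
#' The beat-to-beat interval is modulated deterministically by one
#' low-frequency and one high-frequency sinusoid,
#' `IBI(t_k) = mean_ibi + lf_amp * sin(2 pi f_lf t_k) + hf_amp * sin(2 pi f_hf t_k)`,
#' so the tachogram band powers have closed forms and the LF/HF ratio is
#' analytically testable. The pulse template is the sum of two Gaussian lobes
#' (systolic + dicrotic); any template with a single dominant systolic maximum
#' works, and the shape is configurable.
#'
#' @param duration record length in s; `duration * fs` must be an integer.
#' @param fs sampling rate in Hz (nominally 1000).
#' @param mean_ibi mean inter-beat interval in ms.
#' @param lf_mod,hf_mod `c(freq_hz, amplitude_ms)` modulation terms; LF
#'   frequency must lie in (0.03, 0.15) Hz, HF in (0.15, 0.35) Hz (unless the
#'   amplitude is zero).
#' @param td ulnar lag behind brachial, ms (>= 0).
#' @param pulse_template list: `systolic_width_s`, `dicrotic_frac`,
#'   `dicrotic_delay_s`, `dicrotic_width_s`, `ulnar_amp` (relative amplitude
#'   of the distal channel).
#' @param noise_sd additive white intensity noise, as a fraction of the pulse
#'   amplitude.
#' @param drift_amp slow multiplicative baseline drift amplitude (fraction of
#'   baseline intensity, at `drift_freq` Hz < 0.1) to exercise the band-pass.
#' @param drift_freq drift frequency in Hz.
#' @param seed RNG seed.
#' @return validated list of class `waveform_params`.
#' @export
waveform_params <- function(duration = 30, fs = 1000, mean_ibi = 800,
                            lf_mod = c(0.1, 0), hf_mod = c(0.25, 0),
                            td = 80,
                            pulse_template = list(),
                            noise_sd = 0, drift_amp = 0, drift_freq = 0.05,
                            seed = 1L) {
  tpl <- utils::modifyList(list(systolic_width_s = 0.05, dicrotic_frac = 0.30,
                                dicrotic_delay_s = 0.35, dicrotic_width_s = 0.08,
                                ulnar_amp = 0.9), pulse_template)
  stopifnot(fs > 0, mean_ibi > 0, td >= 0, noise_sd >= 0, duration > 0)
  if (abs(duration * fs - round(duration * fs)) > 1e-9) {
    stop("duration * fs must yield an integer sample count")
  }
  if (lf_mod[2] != 0 && (lf_mod[1] <= 0.03 || lf_mod[1] >= 0.15)) {
    stop("LF modulation frequency must lie in (0.03, 0.15) Hz")
  }
  if (hf_mod[2] != 0 && (hf_mod[1] <= 0.15 || hf_mod[1] >= 0.35)) {
    stop("HF modulation frequency must lie in (0.15, 0.35) Hz")
  }
  structure(list(duration = duration, fs = fs, mean_ibi = mean_ibi,
                 lf_mod = lf_mod, hf_mod = hf_mod, td = td,
                 pulse_template = tpl, noise_sd = noise_sd,
                 drift_amp = drift_amp, drift_freq = drift_freq,
                 seed = as.integer(seed)),
            class = "waveform_params")
}

# usable-record guard in s (start, end): peaks closer to the record boundary
# than this are excluded from the ground truth (see generate_ppg_pair)
EDGE_GUARD_S <- c(0.05, 0.15)

# two-lobe Gaussian pulse template evaluated at times u (s, relative to peak)
pulse_template_eval <- function(u, tpl) {
  exp(-u^2 / (2 * tpl$systolic_width_s^2)) +
    tpl$dicrotic_frac *
      exp(-(u - tpl$dicrotic_delay_s)^2 / (2 * tpl$dicrotic_width_s^2))
}

# superpose one template per beat onto the sampling grid (vectorized per beat)
render_pulses <- function(beat_times, n, fs, tpl, amp = 1) {
  x <- numeric(n)
  half <- 0.6  # template support: +-0.6 s covers > 8 systolic sigmas
  for (tk in beat_times) {
    i0 <- max(1L, floor((tk - half) * fs) + 1L)
    i1 <- min(n, ceiling((tk + half + tpl$dicrotic_delay_s) * fs) + 1L)
    if (i0 > i1) next
    u <- (seq(i0, i1) - 1) / fs - tk
    x[i0:i1] <- x[i0:i1] + amp * pulse_template_eval(u, tpl)
  }
  x
}

#' Generate a synthetic two-site PPG recording with ground truth
#'
#' Beat times follow the two-sinusoid IBI model of [waveform_params()]; the
#' distal (ulnar) channel is the same pulse train delayed by `td` with its own
#' template amplitude. Pulses are rendered at their exact (off-grid) beat
#' times, converted to intensity through Beer-Lambert attenuation
#' (`I = I0 * exp(-OD)`), and optionally corrupted with white noise and a slow
#' baseline drift. The ground truth (RMSSD, LF/HF, heart rate) is computed
#' from the true beat times with the same feature functions the analysis
#' chain uses, so generator and features are oracle-consistent by
#' construction.
#'
#' @param params a `waveform_params` object.
#' @return list of class `ppg_pair`: `recording` (a `ppg_recording`: `time`,
#'   `brachial`, `ulnar` intensity vectors, `fs`, `sites`) and `truth`
#'   (`beat_times` s, `ibis` ms, `td` ms, `heart_rate` bpm, `rmssd` ms,
#'   `lf_hf`, NA when the record is too short for a spectrum).
#' @export
generate_ppg_pair <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  p <- params
  n <- as.integer(round(p$duration * p$fs))
  tgrid <- (seq_len(n) - 1) / p$fs

  # beat times from the deterministic IBI recursion; the train starts well
  # before t = 0 and runs past the end so the record is stationary (the heart
  # was beating before the recording started) — without the warm-up the
  # 0.2 Hz high-pass turns the onset into a slow baseline swell that
  # depresses early peaks
  all_beats <- numeric(0)
  t <- 0.4 - 4 * p$mean_ibi / 1000
  while (t < p$duration + 1.0) {
    all_beats <- c(all_beats, t)
    ibi_ms <- p$mean_ibi +
      p$lf_mod[2] * sin(2 * pi * p$lf_mod[1] * t) +
      p$hf_mod[2] * sin(2 * pi * p$hf_mod[1] * t)
    if (ibi_ms <= 0) stop("IBI modulation drives the interval nonpositive")
    t <- t + ibi_ms / 1000
  }
  # ground truth = beats whose systolic peak falls inside the record, with a
  # small edge guard (zero-phase filtering reflects the signal at the record
  # boundaries, so peaks in the last ~0.15 s are not reliably representable)
  beats <- all_beats[all_beats >= EDGE_GUARD_S[1] &
                       all_beats <= p$duration - EDGE_GUARD_S[2]]
  if (length(beats) < 2) stop("degenerate recording")

  tpl <- p$pulse_template
  od_scale <- 0.1     # peak optical-density excursion of one pulse
  i0 <- 10000         # baseline detector counts (arbitrary units)
  od_b <- od_scale * render_pulses(all_beats, n, p$fs, tpl, amp = 1)
  od_u <- od_scale * render_pulses(all_beats + p$td / 1000, n, p$fs, tpl,
                                   amp = tpl$ulnar_amp)
  drift <- 1 + p$drift_amp * sin(2 * pi * p$drift_freq * tgrid)
  set.seed(p$seed)
  noise_abs <- p$noise_sd * i0 * (1 - exp(-od_scale))
  brachial <- i0 * drift * exp(-od_b) + stats::rnorm(n, 0, noise_abs)
  ulnar <- i0 * drift * exp(-od_u) + stats::rnorm(n, 0, noise_abs)
  if (any(brachial <= 0) || any(ulnar <= 0)) {
    stop("noise level drove intensity nonpositive; lower noise_sd")
  }

  ulnar_all <- all_beats + p$td / 1000
  truth_prv <- prv_from_times(beats)
  truth <- list(
    beat_times = beats,
    ulnar_beat_times = ulnar_all[ulnar_all >= EDGE_GUARD_S[1] &
                                   ulnar_all <= p$duration - EDGE_GUARD_S[2]],
    ibis = truth_prv$ibis,
    td = p$td,
    heart_rate = heart_rate(truth_prv),
    rmssd = rmssd(truth_prv$ibis),
    lf_hf = tryCatch(
      suppressWarnings(lf_hf_ratio(truth_prv)),
      error = function(e) NA_real_))
  structure(
    list(recording = structure(list(time = tgrid, brachial = brachial,
                                    ulnar = ulnar, fs = p$fs,
                                    sites = c("brachial", "ulnar")),
                               class = "ppg_recording"),
         truth = truth, params = p),
    class = "ppg_pair")
}

#' Configuration for a synthetic cohort with a known linear anxiety model
#'
#' The anxiety score is `sa = sa_offset + sa_scale * (Xz %*% beta_true +
#' noise_z)`, where `Xz` holds the sample-z-scored features (gender coded
#' 1 = female / 2 = male, z-scored like the rest) and `noise_z` is Gaussian on
#' the standardized scale.
#'
#' For the fitted standardized coefficients to equal `beta_true` in
#' expectation, the standardized outcome must have unit variance:
#' `beta' R beta + noise_z^2 = 1`, where `R` is the correlation matrix of the
#' regressors. With the default coefficients, independent features would give
#' `beta' beta = 0.40` — less than the target `R^2 = 0.66` — so the three
#' pulse-derived features are generated *equicorrelated* with the pairwise
#' correlation that makes `beta' R beta = target_r2` exactly (plausible
#' physiologically: LF/HF and RMSSD derive from the same tachogram). The
#' residual sd on the standardized scale is then `sqrt(1 - target_r2)`.
#' Supplying `feature_rho` and/or `noise_sd` overrides this calibration.
#'
#' @param n_subjects cohort size (>= 8).
#' @param beta_true named coefficients over `abp`, `lf_hf`, `rmssd`, `gender`
#'   on the standardized scale; defaults are the stated-world values of the
#'   fitted anxiety model.
#' @param noise_sd residual sd on the standardized outcome scale, or `NULL`
#'   to use `sqrt(sum(beta^2 cross terms) * (1 - r2) / r2)` via
#'   [noise_sd_for_r2()] with the calibrated signal variance.
#' @param target_r2 population R^2 of the linear model (default 0.66).
#' @param feature_rho pairwise correlation among the three pulse features, or
#'   `NULL` to solve `beta' R beta = target_r2` for it.
#' @param feature_means,feature_sds location/scale of the raw feature draws
#'   (`abp` mmHg, `lf_hf` ratio, `rmssd` ms).
#' @param gender_fraction fraction of the cohort labeled 1 (female).
#' @param sa_offset,sa_scale affine map from the standardized outcome to the
#'   20--80 score range.
#' @param seed RNG seed.
#' @return validated list of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_subjects = 102L,
                                beta_true = c(abp = 0.2358, lf_hf = 0.3176,
                                              rmssd = 0.3042, gender = -0.3947),
                                noise_sd = NULL, target_r2 = 0.66,
                                feature_rho = NULL,
                                feature_means = c(abp = 120, lf_hf = 2.0, rmssd = 45),
                                feature_sds = c(abp = 15, lf_hf = 0.7, rmssd = 18),
                                gender_fraction = 48 / 102,
                                sa_offset = 38.5, sa_scale = 9,
                                seed = 1L) {
  stopifnot(n_subjects >= 8, gender_fraction >= 0, gender_fraction <= 1,
            sa_scale > 0, target_r2 > 0, target_r2 <= 1)
  if (n_subjects < length(beta_true) + 2) stop("underdetermined cohort")
  ppg <- c("abp", "lf_hf", "rmssd")
  if (!all(ppg %in% names(beta_true))) {
    stop("beta_true must be named over abp, lf_hf, rmssd, gender")
  }
  b3 <- beta_true[ppg]
  cross <- sum(b3["abp"] * b3["lf_hf"], b3["abp"] * b3["rmssd"],
               b3["lf_hf"] * b3["rmssd"])
  if (is.null(feature_rho)) {
    feature_rho <- (target_r2 - sum(beta_true^2)) / (2 * cross)
  }
  if (feature_rho <= -0.5 || feature_rho >= 1) {
    stop("feature_rho outside (-0.5, 1); equicorrelation matrix not positive definite")
  }
  signal_var <- sum(beta_true^2) + 2 * feature_rho * cross
  if (is.null(noise_sd)) noise_sd <- noise_sd_for_r2(beta_true, target_r2,
                                                     signal_var = signal_var)
  stopifnot(noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects), beta_true = beta_true,
                 noise_sd = noise_sd, feature_rho = feature_rho,
                 signal_var = signal_var,
                 feature_means = feature_means, feature_sds = feature_sds,
                 gender_fraction = gender_fraction,
                 sa_offset = sa_offset, sa_scale = sa_scale,
                 seed = as.integer(seed)),
            class = "synth_cohort_config")
}

#' Residual sd giving a target population R^2
#'
#' `R2 = S / (S + noise_sd^2)` where `S = beta' R beta` is the variance of the
#' linear predictor over z-scored regressors; inverting gives
#' `noise_sd = sqrt(S * (1 - R2) / R2)` on the standardized outcome scale.
#' For independent regressors `S = sum(beta^2)` (the default).
#'
#' @param beta_true standardized coefficient vector.
#' @param r2 target population R^2 in (0, 1].
#' @param signal_var variance of the linear predictor (`beta' R beta`).
#' @return noise sd on the standardized outcome scale.
#' @export
noise_sd_for_r2 <- function(beta_true, r2, signal_var = sum(beta_true^2)) {
  stopifnot(r2 > 0, r2 <= 1)
  sqrt(signal_var * (1 - r2) / r2)
}

#' Generate a synthetic cohort table with known coefficients
#'
#' @param config a `synth_cohort_config`.
#' @return list: `table` (a `cohort_table` data.frame with columns
#'   `subject_id`, `gender`, `abp`, `lf_hf`, `rmssd`, `sa`, `valid`, `reason`),
#'   `beta_true`, `beta_realized` (the exact standardized coefficients of this
#'   finite sample after outcome z-scoring: `beta_true / sd(lin + noise)` —
#'   for `noise_sd = 0` a fit must recover these to numerical tolerance),
#'   `noise_sd`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_cohort_config"))
  cfg <- config
  n <- cfg$n_subjects
  set.seed(cfg$seed)
  # equicorrelated Gaussian draws for the three pulse features
  r3 <- matrix(cfg$feature_rho, 3, 3); diag(r3) <- 1
  z <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(r3)
  feats <- sweep(sweep(z, 2, cfg$feature_sds[c("abp", "lf_hf", "rmssd")], "*"),
                 2, cfg$feature_means[c("abp", "lf_hf", "rmssd")], "+")
  colnames(feats) <- c("abp", "lf_hf", "rmssd")
  # positivity floors for the ratio/interval features (draws are far from 0,
  # so the truncation is negligible but keeps the invariants honest)
  feats[, "lf_hf"] <- pmax(feats[, "lf_hf"], 0.05)
  feats[, "rmssd"] <- pmax(feats[, "rmssd"], 0.5)
  n_female <- round(cfg$gender_fraction * n)
  n_female <- min(max(n_female, 1L), n - 1L)  # both genders must occur
  gender <- rep(2, n)
  gender[sample.int(n, n_female)] <- 1
  x <- cbind(feats, gender = gender)
  xz <- apply_scaler(x, fit_scaler(x))
  lin <- drop(xz[, names(cfg$beta_true)] %*% cfg$beta_true) +
    stats::rnorm(n, 0, cfg$noise_sd)
  sa <- cfg$sa_offset + cfg$sa_scale * lin
  clamped <- sa < 20 | sa > 80
  sa <- pmin(pmax(sa, 20), 80)
  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    gender = gender, abp = x[, "abp"], lf_hf = x[, "lf_hf"],
                    rmssd = x[, "rmssd"], sa = sa,
                    valid = TRUE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", class(tab))
  list(table = tab, beta_true = cfg$beta_true,
       beta_realized = if (any(clamped)) NULL else cfg$beta_true / stats::sd(lin),
       noise_sd = cfg$noise_sd, n_clamped = sum(clamped), config = cfg)
}

#' Generate a full synthetic cohort of two-site recordings
#'
#' End-to-end stand-in for a study: per-subject waveform parameters (mean
#' interval, LF/HF modulation amplitudes, transit delay) are drawn from
#' physiologic ranges, recordings are synthesized, and the anxiety score is a
#' linear function of the sample-z-scored *true* features (ABP from true heart
#' rate and delay, true LF/HF, true RMSSD, gender) plus Gaussian noise.
#' Running the analysis chain on the recordings should recover the features
#' and hence the linear structure.
#'
#' @param n_subjects cohort size.
#' @param duration,fs per-recording length (s) and rate (Hz).
#' @param intensity_noise_sd white intensity noise (fraction of pulse amplitude).
#' @param sa_noise_sd residual anxiety noise in score units.
#' @param beta_true,sa_offset,sa_scale linear anxiety model (see
#'   [synth_cohort_config()]).
#' @param gender_fraction fraction labeled 1 (female).
#' @param seed RNG seed.
#' @return list: `recordings` (named list of `brachial`/`ulnar`/`fs`),
#'   `metadata` (subject_id, gender, sa), `truth` (per-subject true features).
#' @export
generate_ppg_cohort <- function(n_subjects = 12L, duration = 30, fs = 1000,
                                intensity_noise_sd = 0, sa_noise_sd = 0,
                                beta_true = c(abp = 0.2358, lf_hf = 0.3176,
                                              rmssd = 0.3042, gender = -0.3947),
                                gender_fraction = 48 / 102,
                                sa_offset = 45, sa_scale = 12,
                                seed = 1L) {
  set.seed(as.integer(seed))
  ids <- sprintf("S%03d", seq_len(n_subjects))
  mean_ibi <- stats::runif(n_subjects, 650, 1100)
  lf_amp <- stats::runif(n_subjects, 10, 40)
  hf_amp <- stats::runif(n_subjects, 10, 40)
  f_lf <- stats::runif(n_subjects, 0.08, 0.12)
  f_hf <- stats::runif(n_subjects, 0.20, 0.30)
  td <- stats::runif(n_subjects, 40, 120)
  n_female <- min(max(round(gender_fraction * n_subjects), 1L), n_subjects - 1L)
  gender <- rep(2, n_subjects)
  gender[sample.int(n_subjects, n_female)] <- 1
  sub_seeds <- sample.int(2^30, n_subjects)

  recordings <- vector("list", n_subjects)
  names(recordings) <- ids
  truth <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    pair <- generate_ppg_pair(waveform_params(
      duration = duration, fs = fs, mean_ibi = mean_ibi[i],
      lf_mod = c(f_lf[i], lf_amp[i]), hf_mod = c(f_hf[i], hf_amp[i]),
      td = td[i], noise_sd = intensity_noise_sd, seed = sub_seeds[i]))
    recordings[[i]] <- list(brachial = pair$recording$brachial,
                            ulnar = pair$recording$ulnar, fs = fs)
    tr <- pair$truth
    truth[[i]] <- data.frame(
      subject_id = ids[i], gender = gender[i],
      abp = estimate_abp(tr$heart_rate, tr$td), lf_hf = tr$lf_hf,
      rmssd = tr$rmssd, heart_rate = tr$heart_rate, td = tr$td,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  x <- as.matrix(truth[, c("abp", "lf_hf", "rmssd")])
  x <- cbind(x, gender = gender)
  xz <- apply_scaler(x, fit_scaler(x))
  lin <- drop(xz[, names(beta_true)] %*% beta_true)
  sa <- sa_offset + sa_scale * lin + stats::rnorm(n_subjects, 0, sa_noise_sd)
  sa <- pmin(pmax(sa, 20), 80)
  truth$sa <- sa
  list(recordings = recordings,
       metadata = data.frame(subject_id = ids, gender = gender, sa = sa,
                             stringsAsFactors = FALSE),
       truth = truth)
}
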