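#' Mean heart rate from a PRV series
#'
#' @param prv a `prv_series` (or anything with an `ibis` field in ms).
#' @return heart rate in bpm: `60000 / mean(ibis)`.
#' @export
heart_rate <- function(prv) {
  ibis <- prv$ibis
  if (!length(ibis)) stop("insufficient beats")
  60000 / mean(ibis)
}

#' Blood-pressure surrogate from heart rate and transit delay
#'
#' Affine pulse-wave model relating systolic arterial blood pressure to heart
#' rate and the brachial-to-ulnar transit delay:
#' `ABP = 184.3 - 1.329 * HR + 0.0848 * TD` with HR in bpm and TD in ms.
#' Pressure falls with heart rate and rises with transit delay.
#'
#' @param heart_rate heart rate in bpm (> 0).
#' @param td transit delay in ms (>= 0).
#' @return estimated pressure in mmHg.
#' @export
estimate_abp <- function(heart_rate, td) {
  if (any(!is.finite(heart_rate)) || any(heart_rate <= 0) ||
      any(!is.finite(td)) || any(td < 0)) {
    stop("invalid input")
  }
  184.3 - 1.329 * heart_rate + 0.0848 * td
}

#' Root mean square of successive inter-beat-interval differences
#'
#' `RMSSD = sqrt( (1 / (N - 1)) * sum_{i=1}^{N-1} (dSP[i+1] - dSP[i])^2 )`
#' where `dSP` are the N successive systolic peak-to-peak intervals in ms.
#' Note the normalizer is `N - 1`, the number of intervals minus one, i.e. the
#' count of successive differences.
#'
#' @param ibis numeric vector of inter-beat intervals in ms (N >= 2).
#' @return RMSSD in ms.
#' @export
rmssd <- function(ibis) {
  ibis <- as.numeric(ibis)
  n <- length(ibis)
  if (n < 2) stop("insufficient intervals")
  sqrt(sum(diff(ibis)^2) / (n - 1))
}

#' Build the cohort feature table from paired recordings
#'
#' Runs each subject's two raw channels through the pre-processing chain,
#' detects peaks on both, and computes the four regressors: ABP (from heart
#' rate and the inter-site transit delay), LF/HF and RMSSD (both from the
#' proximal/brachial PRV), and gender (1 = female, 2 = male). A failing stage
#' marks the row invalid with the reason attached — rows are never silently
#' dropped.
#'
#' @param recordings named list: one element per subject, each a list with
#'   `brachial` and `ulnar` raw intensity vectors and `fs`.
#' @param metadata data.frame with columns `subject_id`, `gender`, and
#'   (optionally, for training) `sa`.
#' @param config optional list of overrides: `peak_min_height`,
#'   `peak_min_distance_ms`, `td_pairing_window_ms`, `decimation_factor`,
#'   `bp_low_hz`, `bp_high_hz`, `filter_order`, `min_record_s`.
#' @return data.frame of class `cohort_table` with columns `subject_id`,
#'   `gender`, `abp`, `lf_hf`, `rmssd`, `sa`, `heart_rate`, `td`, `valid`,
#'   `reason`.
#' @export
build_feature_table <- function(recordings, metadata, config = list()) {
  cfg <- utils::modifyList(list(
    peak_min_height = 2, peak_min_distance_ms = 600,
    td_pairing_window_ms = 300, decimation_factor = 10L,
    bp_low_hz = 0.2, bp_high_hz = 10, filter_order = 4L,
    min_record_s = 60), config)
  rows <- lapply(names(recordings), function(id) {
    meta <- metadata[metadata$subject_id == id, , drop = FALSE]
    if (nrow(meta) != 1) {
      return(feature_row(id, NA, reason = "missing metadata"))
    }
    sa <- if ("sa" %in% names(meta)) meta$sa else NA_real_
    rec <- recordings[[id]]
    out <- tryCatch({
      fv <- extract_features(rec, cfg)
      feature_row(id, meta$gender, sa = sa, fv = fv)
    }, error = function(e) {
      feature_row(id, meta$gender, sa = sa, reason = conditionMessage(e))
    })
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("cohort_table", class(tab))
  tab
}

# features for one subject's pair of raw channels
extract_features <- function(rec, cfg) {
  proc <- lapply(rec[c("brachial", "ulnar")], function(raw) {
    preprocess_ppg(raw, fs = rec$fs,
                   decimation_factor = cfg$decimation_factor,
                   bp_low_hz = cfg$bp_low_hz, bp_high_hz = cfg$bp_high_hz,
                   filter_order = cfg$filter_order)
  })
  trains <- Map(function(p, ch) {
    detect_peaks(p, min_height = cfg$peak_min_height,
                 min_distance_ms = cfg$peak_min_distance_ms, channel = ch)
  }, proc, names(proc))
  prv <- compute_prv(trains$brachial)
  hr <- heart_rate(prv)
  td <- estimate_td(trains$brachial, trains$ulnar,
                    pairing_window_ms = cfg$td_pairing_window_ms)
  lfhf <- withCallingHandlers(
    lf_hf_ratio(prv, min_record_s = cfg$min_record_s),
    warning = function(w) invokeRestart("muffleWarning"))
  list(abp = estimate_abp(hr, td), lf_hf = lfhf, rmssd = rmssd(prv$ibis),
       heart_rate = hr, td = td)
}

feature_row <- function(id, gender, sa = NA_real_, fv = NULL, reason = NA_character_) {
  if (is.null(fv)) {
    fv <- list(abp = NA_real_, lf_hf = NA_real_, rmssd = NA_real_,
               heart_rate = NA_real_, td = NA_real_)
  }
  data.frame(subject_id = id, gender = as.numeric(gender),
             abp = fv$abp, lf_hf = fv$lf_hf, rmssd = fv$rmssd,
             sa = as.numeric(sa), heart_rate = fv$heart_rate, td = fv$td,
             valid = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}
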