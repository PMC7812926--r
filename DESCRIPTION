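Package: anxppg
Title: State-Anxiety Prediction from Two-Site Photoplethysmography
Version: 0.1.0
Authors@R:
    person("anxppg", "maintainers", email = "anxppg@example.org", role = c("aut", "cre"))
Description: Tools to estimate state anxiety (STAI-Y state scale) from dual-site
    photoplethysmography (PPG). Implements the full chain: optical-density
    conversion, anti-aliased decimation, zero-phase Butterworth band-pass
    filtering, constrained systolic-peak detection, trimmed single-pulse
    averaging, inter-site transit-delay estimation, pulse-rate-variability
    features (RMSSD, Welch LF/HF), a blood-pressure surrogate from heart rate
    and transit delay, a cross-validated standardized general linear model with
    agreement statistics (Pearson, paired t, Bland-Altman, incremental R2,
    Steiger dependent-correlation test), and ROC analysis with class-balanced
    bootstrap AUC and correlated-AUC comparisons. A synthetic-data module
    generates two-site pulse waveforms and cohorts with known ground truth so
    every stage is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
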