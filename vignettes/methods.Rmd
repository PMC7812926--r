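---
title: "Estimating state anxiety from two-site PPG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating state anxiety from two-site PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxppg)
```

## The problem

State anxiety — the transient "anxiety right now" component of the
State-Trait Anxiety Inventory (STAI-Y state scale, scores 20–80) — modulates
autonomic outflow, and autonomic outflow shapes the arterial pulse. A
photoplethysmogram (PPG) recorded at two sites along the arm therefore
carries information about a person's anxiety level: the pulse rate and its
variability reflect sympathovagal balance, and the transit delay between a
proximal (brachial) and distal (ulnar/radial) site reflects vascular tone and
pressure. `anxppg` implements the full chain from raw two-channel PPG
intensity to a cross-validated linear prediction of the state-anxiety score,
plus a classifier analysis of "high" anxiety (score > 40), for researchers in
affective computing and psychophysiology who want a transparent, fully
testable reference implementation.

## The signal model and pre-processing chain

Raw intensity is converted to optical density, `OD = -ln(I / mean(I))`,
which linearizes absorption changes. The log base and reference intensity
only rescale and shift the OD; both are removed by the final z-scoring, so
these conventions are provably inconsequential (the tests pin them anyway).

The OD trace (nominally 1 kHz) is decimated by 10 with a windowed-sinc FIR
anti-alias filter — naive subsampling would fold >50 Hz instrument noise
into the pulse band — then band-pass filtered with a 4th-order Butterworth
(0.2–10 Hz) applied forward and backward. "Zero-lag" is read as
forward–backward application of the 4th-order design: phase is identically
zero, peak positions are preserved, and the effective magnitude response is
the square of the single-pass design (the band edges sit at half power). No
filter-design library ships with the supported toolchain, so the design
(bilinear transform of the analog prototype, factored into second-order
sections for numerical stability at a 0.2 Hz edge on a 100 Hz rate) lives in
`R/filters.R`; its response was validated against an independent reference
implementation during development, agreeing to 1e-11, and is pinned by
magnitude-response tests.

Two boundary conventions matter and are deliberate:

* **Padding.** Forward–backward filtering needs the record extended at both
  ends. The common anti-symmetric ("odd") extension flips the pulse train
  upside down at the boundary; the resulting low-frequency step is smeared
  across several seconds by the 0.2 Hz high-pass and visibly depresses the
  first and last beats. `sosfiltfilt()` therefore defaults to the mirror
  ("even") extension, which preserves the local mean of pulsatile signals.
* **z-scoring.** Signals use the population-sd convention (divide by n);
  cohort feature columns use the sample convention (n − 1). Both are pinned
  by tests. Filtering precedes normalization.

## Beat detection, averaging, and features

Systolic peaks are local maxima of the normalized signal with height ≥ 2
(in sd units) and inter-peak spacing ≥ 600 ms (a 100 bpm resting ceiling).
When two candidates are closer than the spacing floor the taller wins,
earlier on ties — the paper-style constraints leave the conflict rule open,
so it is fixed here and tested by enumeration.

The single-pulse average takes a window from 0.6 s before to 1.2 s after
each peak and keeps only pulses whose *every* sample lies inside the
per-sample 25th–75th percentile envelope of the aligned pulses — the only
reading consistent with "all the values" — with a small numeric tolerance so
floating-point-level differences cannot disqualify otherwise identical
pulses. If nothing survives, the plain mean is used and a warning logged.

The inter-site transit delay (TD) pairs each distal peak with the nearest
preceding proximal peak within 300 ms (a bound covering physiologic arm
transit times; configurable) and reports the 25–75 % trimmed mean of the
paired differences in ms.

Four regressors feed the model:

* **ABP** (mmHg): `184.3 − 1.329·HR + 0.0848·TD`, an affine pulse-wave
  surrogate for systolic pressure, HR in bpm and TD in ms.
* **RMSSD** (ms): `sqrt( sum((ΔSP[i+1] − ΔSP[i])^2) / (N − 1) )` over the N
  successive peak-to-peak intervals. Note the normalizer counts the
  successive differences, matching the defining formula, not the more common
  HRV convention of N − 2 for N intervals.
* **LF/HF**: the tachogram is cubic-spline interpolated to an even 4 Hz
  grid, mean-removed, and its PSD estimated by Welch's method with a single
  Hann-windowed segment — the periodogram limit of Welch, because shorter
  segments of a 30 s record cannot resolve the 0.03 Hz LF edge at all. LF
  power integrates 0.03–0.15 Hz and HF 0.15–0.35 Hz by the trapezoid rule,
  with PSD values linearly interpolated at the exact band edges. A 30 s
  record holds roughly one cycle at the LF edge, so the estimate is fragile
  there; `min_record_s` (default 60) controls a reliability warning without
  blocking records down to 20 s.
* **Gender**: coded 1 = female, 2 = male, and z-scored like every other
  regressor.

## The model and its evaluation

The model is `Y = Xβ + ε` fit by ordinary least squares on z-scored
variables with no intercept; on that scale βs are comparable association
strengths and the model R² equals the squared in-sample correlation between
fitted and observed outcome (an identity the tests verify). Generalization
is assessed by 1,000 random 75/27 train–test splits: scalers are fit on the
training rows only and applied to the test rows (standard leakage hygiene —
the source procedure is silent on this), one seed governs all splits, and a
subject's predicted score `SAp` is the mean of their test-set predictions
across splits, which is the only aggregation that yields one prediction per
subject for the agreement analyses. Both the mean per-split test correlation
and the pooled `cor(SAp, SA)` are reported, since either framing is
defensible for a headline correlation.

Agreement between observed and predicted scores uses Pearson correlation,
the paired t-test, and Bland–Altman bias with ±1.96 sd limits. Nested models
are compared by incremental R² (`R²(without k) − R²(full)`, computed by QR
projection so exactly collinear columns degrade gracefully), dependent
correlations sharing the anxiety variable by Steiger's (1980) z, and
correlated ROC areas by the Hanley–McNeil (1983) paired z — with the
original's printed lookup table replaced by using the average within-class
correlation of the two score vectors directly, and DeLong's covariance-based
test available as `method = "delong"`.

High anxiety is a score strictly above 40. Because the classes are
unbalanced, the AUC is also reported as the mean of a class-balanced
bootstrap (default 10,000 iterations): each iteration resamples, with
replacement, m subjects from each class, m being the smaller class size —
the minimal intervention that balances the classes.

## The synthetic world

`generate_ppg_pair()` renders beats whose intervals follow a deterministic
two-sinusoid modulation (one LF, one HF component), so tachogram band powers
have closed forms and LF/HF is analytically testable. The pulse template is
two Gaussian lobes (systolic + dicrotic); any single-dominant-maximum shape
is acceptable and the shape is configurable. Defaults (systolic sd 50 ms,
dicrotic fraction 0.30 at 350 ms) give z-scored peak heights ≈ 2.3–2.9
across resting heart rates, comfortably above the detection floor of 2. The
beat train starts well before t = 0 so the record is stationary — without
the warm-up, the 0.2 Hz high-pass turns the onset into a slow swell that
depresses early peaks. Ground-truth RMSSD, LF/HF and heart rate are computed
from the true beat times *with the same feature functions the analysis chain
uses*, making generator and features oracle-consistent by construction.
White intensity noise (a fraction of pulse amplitude) and a slow
(< 0.1 Hz) baseline drift exercise the band-pass. Peaks within 0.05 s of
the record start or 0.15 s of its end are excluded from the ground truth:
zero-phase filtering reflects the signal at the boundaries, and peaks inside
that margin are not reliably representable by any method.

`generate_cohort()` draws a feature table with a known linear anxiety
structure. One calibration is worth spelling out: with *independent*
regressors, the default coefficient vector (sum of squares 0.40) cannot
coexist with a population R² of 0.66 under a z-scored outcome — the
variances do not add up. The resolution is that the three pulse features are
drawn equicorrelated, with the pairwise correlation (≈ 0.52) solving
`β'Rβ = R²` exactly; this is also what one expects physiologically, since
LF/HF and RMSSD derive from the same tachogram and all three features share
autonomic drive. The residual sd is then `sqrt(1 − R²)` on the standardized
scale. Scores are mapped affinely to the 20–80 range (offset 38.5, scale 9,
chosen so that roughly 44 % of subjects exceed the high-anxiety threshold,
matching the reference class balance, and clipped at the instrument floor of
20 — a floor the real inventory also has). Feature locations (ABP
120 ± 15 mmHg, LF/HF 2.0 ± 0.7, RMSSD 45 ± 18 ms, 47 % female) are
realistic resting values chosen once; no distributional description of the
original cohort exists to copy.

What the generator does *not* emulate: motion artifacts, ectopic beats,
respiratory sinus arrhythmia beyond a single HF line, probe-contact
variation, wave-reflection morphology changes, or any nonlinear
anxiety–physiology coupling. A green test therefore establishes that the
pipeline recovers a known linear world through its own signal chain — not
that the linear model is the right physiology.

Two quantization facts propagate into test tolerances. At a 100 Hz working
rate, peak times carry ±5 ms jitter, which inflates RMSSD by roughly
`sqrt(50)` ms² in quadrature (1–3 ms for typical values) and perturbs the
30 s LF/HF estimate by up to tens of percent relative — so "noise-free"
end-to-end recovery is excellent but not exact, and the end-to-end
correlation on a noiseless cohort lands near 0.9 rather than literally 1.0.

## Numerical choices and degenerate inputs

* Nonpositive intensities, constant signals, < 2 detected beats, tachograms
  shorter than 20 s or with < 10 beats, zero HF power, rank-deficient
  designs, and single-class label vectors all raise typed errors rather
  than propagating NaNs.
* Failing subjects in `build_feature_table()` are flagged invalid with the
  reason attached, never silently dropped.
* Reports embed the configuration, seed, and input checksum, and contain no
  timestamps, so reruns are byte-identical.

## Known limitations

* The 0.03 Hz LF edge is statistically fragile on 30 s records; treat
  single-subject LF/HF values with caution (the package warns).
* The ABP surrogate is an affine population model, not a calibrated pressure
  measurement.
* The balanced-bootstrap AUC and the correlated-AUC tests assume exchangeable
  subjects; no clustering or repeated measures are handled.
* The reproduction of the original study's headline statistics requires its
  deposited per-subject tables, which are not redistributable here; the
  corresponding acceptance test documents this and fails until a local copy
  (`inst/extdata/study_cohort.csv`) is supplied.
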