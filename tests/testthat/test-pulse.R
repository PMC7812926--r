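test_that("peak detection honours height and distance constraints", {
  sig <- bump_signal(c(1, 2, 3), c(3, 3, 3))
  tr <- detect_peaks(sig)
  expect_length(tr$peak_times, 3)
  expect_equal(tr$ibis, c(1000, 1000), tolerance = 1e-9)

  # candidate below the height floor is excluded
  sig2 <- bump_signal(c(1, 2, 3), c(3, 1.5, 3))
  tr2 <- detect_peaks(sig2)
  expect_length(tr2$peak_times, 2)
  expect_equal(tr2$peak_times, c(1, 3), tolerance = 0.011)

  # two candidates 400 ms apart: the taller wins
  sig3 <- bump_signal(c(1, 1.4, 2.4), c(3, 2.5, 3))
  tr3 <- detect_peaks(sig3)
  expect_equal(tr3$peak_times, c(1, 2.4), tolerance = 0.011)

  expect_error(detect_peaks(bump_signal(2, 3)), "insufficient beats")
})

test_that("greedy distance rule matches brute-force enumeration", {
  # oracle: over all candidate subsets, the feasible one chosen by
  # tallest-first greedy must dominate any feasible subset in the sense used
  # by the rule (every kept peak is the tallest among conflicting candidates)
  set.seed(42)
  for (rep in 1:20) {
    times <- sort(runif(6, 0.5, 5.5))
    heights <- runif(6, 2, 5)
    sig <- bump_signal(times, heights, width = 0.02, duration = 7)
    tr <- detect_peaks(sig)
    expect_true(all(diff(tr$peak_times) >= 0.6 - 1e-9))
    # no excluded candidate could be added without violating spacing
    x <- sig$values
    n <- length(x)
    cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
    cand <- cand[x[cand] >= 2]
    cand_t <- (cand - 1) / sig$fs
    for (ct in cand_t) {
      if (min(abs(tr$peak_times - ct)) > 1e-9) {
        expect_lt(min(abs(tr$peak_times - ct)), 0.6)
      }
    }
  }
})

test_that("peak detection is translation-equivariant", {
  sig <- bump_signal(c(1, 2.1, 3.1), c(3, 2.6, 3.4), duration = 5)
  tr <- detect_peaks(sig)
  k <- 37L
  shifted <- list(values = c(numeric(k), sig$values[1:(length(sig$values) - k)]),
                  fs = sig$fs)
  tr_s <- detect_peaks(shifted)
  expect_equal(tr_s$peak_indices, tr$peak_indices + k)
})

test_that("pulse averaging: identical pulses reproduce the template", {
  times <- seq(1, 9, by = 1)
  sig <- bump_signal(times, rep(3, length(times)), duration = 11)
  tr <- detect_peaks(sig)
  pa <- pulse_average(sig, tr)
  expect_equal(length(pa$waveform), round(1.8 * sig$fs) + 1)
  expect_lte(pa$n_used, pa$n_total)
  expect_gte(pa$n_used, 1)
  expect_lt(max(pa$stderr), 1e-9)
  # the average must equal any single aligned pulse
  i <- tr$peak_indices[5]
  one <- sig$values[(i - 60):(i + 120)]
  expect_equal(pa$waveform, one, tolerance = 1e-7)
})

test_that("pulse averaging rejects a gross outlier pulse", {
  times <- seq(1, 11, by = 1)
  heights <- rep(3, length(times)); heights[6] <- 6
  sig <- bump_signal(times, heights, duration = 13)
  tr <- detect_peaks(sig)
  pa <- pulse_average(sig, tr)
  clean <- bump_signal(times, rep(3, length(times)), duration = 13)
  trc <- detect_peaks(clean)
  i <- trc$peak_indices[5]
  template <- clean$values[(i - 60):(i + 120)]
  expect_lt(pa$n_used, pa$n_total)
  expect_lt(max(abs(pa$waveform - template)), 0.05)
})

test_that("pulse averaging falls back to the plain mean with a warning", {
  # give every pulse a unique artifact at its own offset, so each one
  # escapes the quartile envelope somewhere and nothing survives trimming
  times <- seq(1, 8, by = 1)
  sig <- bump_signal(times, rep(3, 8), duration = 10)
  art <- bump_signal(times + 0.20 + 0.05 * seq_along(times), rep(1.5, 8),
                     duration = 10, width = 0.02)
  sig$values <- sig$values + art$values
  tr <- detect_peaks(sig)
  expect_warning(pa <- pulse_average(sig, tr), "falling back")
  expect_equal(pa$n_used, pa$n_total)
})

test_that("transit-delay estimation recovers constructed shifts", {
  tb <- train_from_times(seq(1, 20, by = 0.8))
  tu <- train_from_times(seq(1, 20, by = 0.8) + 0.080)
  expect_equal(estimate_td(tb, tu), 80, tolerance = 1e-9)

  expect_equal(estimate_td(tb, tb), 0)

  # a spurious unmatched ulnar peak is ignored (no preceding peak in window)
  tu2 <- train_from_times(sort(c(seq(1, 20, by = 0.8) + 0.080, 0.2)))
  expect_equal(estimate_td(tb, tu2), 80, tolerance = 1e-9)

  # non-overlapping supports cannot be paired
  far <- train_from_times(seq(100, 110, by = 0.8))
  expect_error(estimate_td(far, tb), "unpairable channels")
})

test_that("PRV extraction is the raw tachogram with timestamps", {
  tr <- train_from_times(c(0, 0.8, 1.6))
  prv <- compute_prv(tr)
  expect_equal(prv$ibis, c(800, 800), tolerance = 1e-9)
  expect_equal(prv$times, c(0.8, 1.6))

  set.seed(9)
  jitter <- runif(20, -10, 10)
  ibis <- 800 + jitter
  times <- cumsum(c(0, ibis)) / 1000
  prv2 <- compute_prv(train_from_times(times))
  expect_equal(prv2$ibis, ibis, tolerance = 1e-9)

  # two peaks: a single interval is valid, the spectral stage must reject it
  prv3 <- compute_prv(train_from_times(c(0, 0.8)))
  expect_length(prv3$ibis, 1)
  expect_error(lf_hf_ratio(prv3), "insufficient beats")
})
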