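test_that("band-pass preserves in-band tones and rejects drift", {
  fs <- 100
  t <- (0:(fs * 60 - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  tone2 <- sin(2 * pi * 2 * t)
  drift <- sin(2 * pi * 0.05 * t)
  expect_gt(20 * log10(rms(bandpass_filter(tone2, fs)) / rms(tone2)), -1)
  expect_lt(20 * log10(rms(bandpass_filter(drift, fs)) / rms(drift)), -20)
  expect_equal(bandpass_filter(rep(0, 500), fs), rep(0, 500))
  expect_error(bandpass_filter(tone2, 15), "20 Hz")
  expect_error(bandpass_filter(c(1, NA, 2), fs), "non-finite")
  # idempotence in the passband: second pass changes RMS by < 1 dB
  once <- bandpass_filter(tone2, fs)
  twice <- bandpass_filter(once, fs)
  expect_lt(abs(20 * log10(rms(twice) / rms(once))), 1)
})

test_that("segmentation recovers the fencepost beat count and onset timing", {
  r <- make_clean_record(duration = 10)
  segs <- segment_waveforms(r$clean, r$fs)
  expect_length(segs, 9L)
  starts <- vapply(segs, function(w) w$start_time, numeric(1))
  expect_lte(stats::median(abs(starts - r$beat_onsets[seq_along(starts)])) * r$fs, 2)
  expect_warning(out <- segment_waveforms(rep(1, 100), 50), "onsets")
  expect_length(out, 0L)
})

test_that("fiducial detection hits analytic truth on noiseless beats", {
  r <- make_clean_record(duration = 10)
  res <- fiducial_errors(r, r$clean, r$fs)
  expect_equal(res$n_compliant, 9L)
  expect_lte(max(res$errors), 1)
})

test_that("non-physiological beats are flagged non-compliant", {
  ramp <- ppg_waveform(seq(0, 1, length.out = 40), 50)
  expect_false(detect_extrema(ramp)$compliant)
  expect_null(detect_extrema(ramp)$extrema)
  # a time-reversed valid beat puts the dominant peak after the small one
  r <- make_clean_record(duration = 10)
  seg <- segment_waveforms(r$clean, r$fs)[[3]]
  rev_beat <- ppg_waveform(rev(seg$samples), seg$fs, seg$start_time)
  expect_false(detect_extrema(rev_beat)$compliant)
  expect_error(detect_extrema(ppg_waveform(1:5, 50)), "8 samples")
})

test_that("fiducial detection commutes with amplitude scaling", {
  r <- make_clean_record(duration = 10)
  seg <- segment_waveforms(r$clean, r$fs)[[2]]
  a <- detect_extrema(seg)
  seg_scaled <- seg
  seg_scaled$samples <- 3.5 * seg$samples
  b <- detect_extrema(seg_scaled)
  expect_equal(b$extrema$t, a$extrema$t)
  expect_equal(b$extrema$y, 3.5 * a$extrema$y, tolerance = 1e-9)
})

test_that("compliance score behaves as a normalized correlation", {
  tpl <- compliance_template()
  self <- ppg_waveform(tpl$samples, 50)
  expect_equal(as.numeric(compliance_score(self, tpl)), 1, tolerance = 1e-9)
  neg <- ppg_waveform(-tpl$samples, 50)
  expect_equal(as.numeric(compliance_score(neg, tpl)), -1, tolerance = 1e-9)
  zero <- ppg_waveform(rep(0.3, 80), 50)
  sc <- compliance_score(zero, tpl)
  expect_equal(as.numeric(sc), 0)
  expect_false(attr(sc, "compliant"))
  # pure-noise beats are uncorrelated on average
  scores <- with_seed(42, vapply(seq_len(1000), function(i)
    as.numeric(compliance_score(ppg_waveform(stats::rnorm(100), 50), tpl)),
    numeric(1)))
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("IBI extraction reproduces beat spacing", {
  beats <- lapply(c(0, 1, 2), function(t0)
    hand_beat(t0, ys = c(0, 1, 0.3, 0.4)))
  ibi <- extract_ibi(beats)
  expect_equal(ibi$intervals, c(1000, 1000))
  expect_error(extract_ibi(beats[1]), "at least 2")
  # recovered IBIs on a modulated noiseless record match generator truth
  cfg <- sim_config(duration = 60, fs = 50, mean_ibi = 0.9, seed = 3,
                    lf_mod = c(0.1, 0.06), hf_mod = c(0.25, 0.04))
  r <- simulate_ppg(cfg)
  segs <- Filter(function(w) isTRUE(w$compliant),
                 lapply(segment_waveforms(r$clean, r$fs), detect_extrema))
  got <- extract_ibi(segs)
  truth <- diff(r$beat_onsets) * 1000
  m <- min(length(got$intervals), length(truth))
  expect_lt(sqrt(mean((got$intervals[seq_len(m)] - truth[seq_len(m)])^2)), 20)
})

test_that("noisy fiducial recovery stays within two samples median error", {
  r <- make_clean_record(duration = 10, noise_sd = 0.05, seed = 3)
  res <- fiducial_errors(r, bandpass_filter(r$samples, r$fs), r$fs)
  expect_gte(res$n_compliant, 4L)
  expect_lte(stats::median(res$errors), 2)
})
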