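test_that("tachogram interpolation honours its contracts", {
  ibi <- ibi_series(seq(0, 10, by = 1))  # constant 1000 ms
  tg <- tachogram(ibi)
  expect_true(all(abs(tg$values) < 1e-9))
  expect_equal(tg$mean_ibi, 1000)
  expect_error(tachogram(ibi_series(seq(0, 7, by = 1))), "at least 8")
  # a sinusoidally modulated IBI series peaks at the modulation frequency
  t <- seq(0, 120, by = 0.9)
  beat_times <- t + cumsum(rep(0, length(t)))
  ibis <- 900 + 50 * sin(2 * pi * 0.1 * t)
  bt <- cumsum(c(0, ibis[-length(ibis)] / 1000))
  tg2 <- tachogram(ibi_series(bt))
  w <- drivermon:::welch_psd(tg2$values, tg2$fs, seg_len = length(tg2$values))
  in_band <- w$freq > 0.02
  expect_lt(abs(w$freq[in_band][which.max(w$psd[in_band])] - 0.1), 0.02)
})

test_that("single-band modulation drives the LF/HF ratio to its extreme", {
  expect_gte(true_lfhf(300, 0.08, 0, seed = 3), 5)
  expect_lte(true_lfhf(300, 0, 0.08, seed = 3), 0.2)
  mixed <- true_lfhf(300, 0.08, 0.08, seed = 3)
  expect_gte(mixed, 0.5); expect_lte(mixed, 2)
})

test_that("band power never exceeds the series variance (Parseval sanity)", {
  cfg <- sim_config(duration = 180, fs = 100, mean_ibi = 0.85, seed = 5,
                    lf_mod = c(0.1, 0.05), hf_mod = c(0.25, 0.05))
  r <- simulate_ppg(cfg)
  tg <- tachogram(ibi_series(r$beat_onsets))
  bp <- band_powers(tg)
  expect_lte(bp$lf_power + bp$hf_power, stats::var(tg$values) * 1.1)
})

test_that("the LF/HF ratio is invariant to uniform tachogram scaling", {
  cfg <- sim_config(duration = 180, fs = 100, mean_ibi = 0.85, seed = 6,
                    lf_mod = c(0.1, 0.05), hf_mod = c(0.25, 0.03))
  r <- simulate_ppg(cfg)
  tg <- tachogram(ibi_series(r$beat_onsets))
  tg2 <- tg; tg2$values <- 7 * tg$values
  expect_equal(band_powers(tg2)$ratio, band_powers(tg)$ratio, tolerance = 1e-9)
})

test_that("attention classification applies an inclusive wakeful boundary", {
  spec <- structure(list(lf_power = 2, hf_power = 2, ratio = 1,
                         ratio_defined = TRUE), class = "hrv_spectrum")
  expect_equal(classify_attention(spec, threshold = 1)$state, "wakeful")
  spec$ratio <- 0.99
  expect_equal(classify_attention(spec, threshold = 1)$state, "drowsy")
  spec$ratio_defined <- FALSE
  expect_error(classify_attention(spec, 1), "undefined")
})

test_that("drowsy and wakeful cohorts are classified at >= 90% accuracy", {
  sim_ratio <- function(kind, seed) {
    cfg <- sim_config(duration = 120, fs = 100,
                      mean_ibi = stats::runif(1, 0.75, 0.95), seed = seed,
                      noise_sd = 0.03,
                      lf_mod = c(0.1, if (kind == "wakeful") 0.08 else 0.02),
                      hf_mod = c(0.25, if (kind == "wakeful") 0.02 else 0.08))
    r <- simulate_ppg(cfg)
    segs <- Filter(function(w) isTRUE(w$compliant),
                   lapply(segment_waveforms(bandpass_filter(r$samples, r$fs), r$fs),
                          detect_extrema))
    band_powers(tachogram(extract_ibi(segs)))$ratio
  }
  ratios <- with_seed(10, {
    data.frame(
      ratio = c(vapply(1:20, function(s) sim_ratio("wakeful", 100 + s), numeric(1)),
                vapply(1:20, function(s) sim_ratio("drowsy", 200 + s), numeric(1))),
      label = rep(c("wakeful", "drowsy"), each = 20))
  })
  thr <- calibrate_attention_threshold(ratios$ratio, ratios$label)
  pred <- ifelse(ratios$ratio >= thr, "wakeful", "drowsy")
  acc_w <- mean(pred[ratios$label == "wakeful"] == "wakeful")
  acc_d <- mean(pred[ratios$label == "drowsy"] == "drowsy")
  expect_gte(acc_w, 0.9)
  expect_gte(acc_d, 0.9)
})

test_that("the Welch estimator agrees with an independent periodogram", {
  set.seed(12)
  fs <- 4
  t <- (0:1023) / fs
  x <- sin(2 * pi * 0.3 * t) + 0.2 * rnorm(length(t))
  w <- drivermon:::welch_psd(x, fs, seg_len = length(x))
  ref <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                           detrend = TRUE, plot = FALSE)
  expect_lt(abs(w$freq[which.max(w$psd)] - ref$freq[which.max(ref$spec)]),
            0.02)
  # Parseval: integrated one-sided density recovers the series variance
  white <- rnorm(2048)
  ww <- drivermon:::welch_psd(white, fs, seg_len = 512)
  tot <- drivermon:::band_integral(ww$freq, ww$psd, 0, fs / 2)
  expect_lt(abs(tot - stats::var(white)) / stats::var(white), 0.1)
})
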