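test_that("unmodulated simulation produces exact beat count and constant IBIs", {
  r <- make_clean_record(duration = 10)
  expect_length(r$beat_onsets, 10L)
  expect_equal(r$ibis, rep(1, 10), tolerance = 1e-12)
  expect_equal(diff(r$beat_onsets), rep(1, 9), tolerance = 1e-12)
})

test_that("every generator is bit-identical under a fixed seed", {
  cfg <- sim_config(duration = 15, fs = 100, noise_sd = 0.05, drift_amp = 0.1,
                    lf_mod = c(0.1, 0.05), hf_mod = c(0.25, 0.05), seed = 7)
  expect_identical(simulate_ppg(cfg), simulate_ppg(cfg))
  r <- simulate_ppg(cfg)
  expect_identical(
    simulate_landmark_series(r, 12, 6, gains = rep(1, 6), noise_sd = 0.1, seed = 3),
    simulate_landmark_series(r, 12, 6, gains = rep(1, 6), noise_sd = 0.1, seed = 3))
  expect_identical(simulate_eye_patches(5, "open", seed = 11),
                   simulate_eye_patches(5, "open", seed = 11))
  expect_identical(simulate_bp_cohort(10, seed = 5), simulate_bp_cohort(10, seed = 5))
})

test_that("too-short simulations are rejected", {
  expect_error(simulate_ppg(sim_config(duration = 1.5, mean_ibi = 1)), "2 beats")
  expect_error(sim_config(lf_mod = c(0.1, 0.6)), "depths")
  expect_error(sim_config(lf_mod = c(0.3, 0.1), hf_mod = c(0.25, 0.1)), "below")
})

test_that("ground-truth extrema match the rendered noiseless signal", {
  r <- make_clean_record(duration = 10, fs = 200)
  for (b in seq_along(r$beat_onsets)) {
    lo <- r$beat_onsets[b]
    hi <- if (b < length(r$beat_onsets)) r$beat_onsets[b + 1L] else length(r$clean) / r$fs
    idx <- which(r$t >= lo & r$t < hi)
    tb <- r$true_extrema[r$true_extrema$beat == b, ]
    seg <- r$clean[idx]
    # m1 is the argmin, m2 the argmax of the rendered beat, within one sample
    expect_lte(abs(r$t[idx[which.min(seg)]] - tb$t[1]) * r$fs, 1)
    expect_lte(abs(r$t[idx[which.max(seg)]] - tb$t[2]) * r$fs, 1)
    # m3/m4: local comparison on the rendered samples around the true time
    for (k in 3:4) {
      i0 <- which.min(abs(r$t - tb$t[k]))
      expect_lte(abs(r$clean[i0] - tb$y[k]), 2e-4)
    }
  }
})

test_that("IBI modulation concentrates tachogram power in the active band", {
  for (mode in c("lf", "hf")) {
    cfg <- sim_config(duration = 120, fs = 100, mean_ibi = 1, seed = 1,
                      lf_mod = c(0.1, if (mode == "lf") 0.1 else 0),
                      hf_mod = c(0.25, if (mode == "hf") 0.1 else 0))
    r <- simulate_ppg(cfg)
    tg <- tachogram(ibi_series(r$beat_onsets))
    bp <- band_powers(tg)
    frac <- if (mode == "lf") bp$lf_power else bp$hf_power
    expect_gte(frac / (bp$lf_power + bp$hf_power), 0.9)
    # periodogram peak sits at the modulation frequency
    w <- drivermon:::welch_psd(tg$values, tg$fs, seg_len = length(tg$values))
    in_band <- w$freq > 0.02
    peak <- w$freq[in_band][which.max(w$psd[in_band])]
    expect_lt(abs(peak - if (mode == "lf") 0.1 else 0.25), 0.02)
  }
})

test_that("landmark series has the contracted geometry and coupling", {
  r <- make_clean_record(duration = 20, fs = 1000)
  ls <- simulate_landmark_series(r, 68, 68, gains = rep(2, 68), noise_sd = 0, fps = 50)
  expect_equal(dim(ls$intensities), c(1000L, 68L))
  # equal-gain noiseless coupling: composite equals gain * resampled PPG
  mu <- composite_signal(ls)
  base <- drivermon:::resample_linear(r$samples, r$fs, 50)
  expect_equal(mu$raw, 2 * base, tolerance = 1e-10)

  # uncoupled channels carry no cardiac signal
  ls0 <- simulate_landmark_series(r, 68, 0, gains = numeric(0), fps = 50, seed = 4)
  mu0 <- composite_signal(ls0)
  expect_lt(abs(stats::cor(mu0$raw, base)), 0.1)

  expect_error(simulate_landmark_series(r, 68, 68, fps = 2000), "upsample")
  expect_error(simulate_landmark_series(r, 4, 8), "n_coupled")
})

test_that("eye patches have the contracted shape, labels and class contrast", {
  open <- simulate_eye_patches(10, "open", seed = 1)
  closed <- simulate_eye_patches(10, "closed", seed = 1)
  expect_length(open$images, 10L)
  expect_true(all(vapply(open$images, function(im) all(dim(im) == c(77L, 77L)), logical(1))))
  expect_true(all(open$labels == "wakeful"))
  expect_true(all(closed$labels == "drowsy"))
  expect_true(all(vapply(c(open$images, closed$images),
                         function(im) all(im >= 0 & im <= 1), logical(1))))
  # central 20x20 window separates the classes (open: iris+sclera, closed: skin+lid)
  centre <- function(im) mean(im[29:48, 29:48])
  m_open <- vapply(open$images, centre, numeric(1))
  m_closed <- vapply(closed$images, centre, numeric(1))
  expect_gt(abs(mean(m_open) - mean(m_closed)), 0.05)
})

test_that("bp cohort separates mAI by class and rejects degenerate settings", {
  coh <- simulate_bp_cohort(200, seed = 9)
  mai <- vapply(coh$waveforms, compute_mai, numeric(1))
  mn <- mai[coh$labels == "normal"]; mab <- mai[coh$labels == "abnormal"]
  pooled_sd <- sqrt((stats::var(mn) + stats::var(mab)) / 2)
  expect_gt(abs(mean(mn) - mean(mab)), 2 * pooled_sd)
  # degenerate morphology (merged lobes) is rejected
  expect_error(
    simulate_bp_cohort(3, class_params = list(
      normal = list(dia_amp = 5, dia_amp_sd = 0),
      abnormal = list(dia_amp = 5.1, dia_amp_sd = 0)), seed = 1))
})

test_that("toy feature maps and boxes obey their shape contracts", {
  fm <- make_toy_feature_map(3, 4, 5, seed = 1)
  expect_equal(dim(fm), c(3L, 4L, 5L))
  expect_length(as.vector(fm), 60L)
  const <- make_toy_feature_map(2, 3, 3, fill = 1.5)
  expect_true(all(const == 1.5))
  boxes <- make_toy_boxes(data.frame(x = 0, y = 0, w = c(10, 20, 30, 40), h = 5))
  expect_length(boxes, 4L)
  expect_equal(vapply(boxes, function(b) b$w, numeric(1)), c(10, 20, 30, 40))
})
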