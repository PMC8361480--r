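small_lstm_cfg <- function(max_epochs = 25L, seed = 1L) {
  seq_model_config("lstm", input_units = 16L, hidden = c(8L, 8L),
                   lr = 5e-3, batch = 64L, max_epochs = max_epochs, seed = seed)
}

test_that("the composite signal is the landmark mean and is permutation-invariant", {
  r <- make_clean_record(duration = 20, fs = 200)
  ls <- simulate_landmark_series(r, 8, 8, gains = rep(1, 8), noise_sd = 0.1,
                                 fps = 20, seed = 2)
  mu <- composite_signal(ls)
  ls_perm <- ls
  ls_perm$intensities <- ls$intensities[, sample(8)]
  expect_equal(composite_signal(ls_perm)$values, mu$values, tolerance = 1e-12)
  # constant landmarks give a constant raw composite
  ls_const <- ls
  ls_const$intensities[] <- 3.2
  expect_true(all(abs(composite_signal(ls_const)$raw - 3.2) < 1e-12))
  # a single landmark passes through unchanged
  ls1 <- simulate_landmark_series(r, 1, 1, gains = 1, noise_sd = 0, fps = 20)
  expect_equal(composite_signal(ls1)$raw, ls1$intensities[, 1L])
  # non-finite intensities are rejected
  ls_bad <- ls
  ls_bad$intensities[3, 3] <- NA
  expect_error(composite_signal(ls_bad), "non-finite")
  # fully coupled noiseless: composite correlates perfectly with the PPG
  ls_full <- simulate_landmark_series(r, 68, 68, gains = rep(0.7, 68),
                                      noise_sd = 0, fps = 20)
  base <- drivermon:::resample_linear(r$samples, r$fs, 20)
  expect_equal(abs(stats::cor(composite_signal(ls_full)$raw, base)), 1,
               tolerance = 1e-10)
})

test_that("lstm cell matches closed forms and hand arithmetic", {
  # zero weights: C_t = 0.5 C_prev, h_t = 0.5 tanh(0.5 C_prev)
  p <- lstm_cell_params(1, 1)
  for (nm in c("W_f", "W_i", "W_C", "W_o")) p[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_C", "b_o")) p[[nm]][] <- 0
  out <- lstm_cell_step(p, x_t = 0.3, h_prev = 0.2, C_prev = 2)
  expect_equal(out$C, 1, tolerance = 1e-12)
  expect_equal(out$h, 0.5 * tanh(1), tolerance = 1e-12)
  # all-zero state and input stays at zero
  out0 <- lstm_cell_step(p, 0, 0, 0)
  expect_equal(out0$h, 0)
  # hand-computed scalar gates to 1e-10
  p$W_f[] <- 0.5; p$W_i[] <- -0.3; p$W_C[] <- 0.7; p$W_o[] <- 0.2
  p$b_f <- 0.1; p$b_i <- -0.2; p$b_C <- 0.3; p$b_o <- 0.05
  h_prev <- 0.4; x_t <- -0.6; C_prev <- 0.8
  sig <- function(a) 1 / (1 + exp(-a))
  z <- c(h_prev, x_t)
  f <- sig(sum(0.5 * z) + 0.1)
  i <- sig(sum(-0.3 * z) - 0.2)
  g <- tanh(sum(0.7 * z) + 0.3)
  o <- sig(sum(0.2 * z) + 0.05)
  C_exp <- f * C_prev + i * g
  h_exp <- o * tanh(C_exp)
  out2 <- lstm_cell_step(p, x_t, h_prev, C_prev)
  expect_lt(abs(out2$C - C_exp), 1e-10)
  expect_lt(abs(out2$h - h_exp), 1e-10)
  expect_error(lstm_cell_step(p, c(1, 2), 0.1, 0.1), "mismatch")
})

test_that("lstm output is bounded by the gate nonlinearities", {
  set.seed(5)
  for (trial in 1:20) {
    p <- lstm_cell_params(3, 4, init_scale = 2)
    out <- lstm_cell_step(p, stats::rnorm(3, sd = 5), stats::rnorm(4),
                          stats::rnorm(4, sd = 5))
    expect_true(all(abs(out$h) < 1))
  }
})

test_that("the dilation schedule caps at 16 and covers a calibration window", {
  cfg <- seq_model_config("tdcnn")
  rf <- tdcnn_receptive_field(cfg)
  expect_equal(rf$dilations[1:5], c(2, 4, 8, 16, 16))
  expect_true(all(rf$dilations <= 16))
  expect_gte(rf$receptive_field, 1000)
})

test_that("calibration learns an identity mapping and is seed-deterministic", {
  r <- make_clean_record(duration = 20, fs = 200, seed = 4)
  ls <- simulate_landmark_series(r, 4, 4, gains = rep(1, 4), noise_sd = 0,
                                 fps = 25, seed = 5)
  mu <- composite_signal(ls)
  cfg <- small_lstm_cfg()
  fit1 <- v2p_calibrate(cfg, mu, r)
  expect_lt(min(fit1$history$val), 0.05)
  fit2 <- v2p_calibrate(cfg, mu, r)
  expect_identical(fit1$history, fit2$history)
  # reconstruction on the calibration window beats held-out loss by design
  rec <- v2p_reconstruct(fit1, mu)
  base <- drivermon:::resample_linear(r$clean, r$fs, 25)
  expect_gt(stats::cor(rec$values, base[seq_along(rec$values)]), 0.8)
})

test_that("degenerate or short inputs are rejected at reconstruction", {
  r <- make_clean_record(duration = 20, fs = 200, seed = 4)
  ls <- simulate_landmark_series(r, 4, 4, gains = rep(1, 4), noise_sd = 0,
                                 fps = 25, seed = 5)
  mu <- composite_signal(ls)
  fit <- v2p_calibrate(small_lstm_cfg(), mu, r)
  mu_const <- mu
  mu_const$values <- rep(0, 300)
  expect_true(v2p_reconstruct(fit, mu_const)$degenerate)
  mu_short <- mu
  mu_short$values <- mu$values[1:5]
  expect_error(v2p_reconstruct(fit, mu_short), "shorter")
  # unpaired lengths are rejected at calibration
  r_half <- r
  r_half$samples <- r$samples[1:2000]
  expect_error(v2p_calibrate(small_lstm_cfg(), mu, r_half), "same window")
})

test_that("the dilated temporal CNN trains toward the fiducial labeling", {
  r <- make_clean_record(duration = 16, fs = 100, seed = 6)
  ls <- simulate_landmark_series(r, 4, 4, gains = rep(1, 4), noise_sd = 0,
                                 fps = 25, seed = 7)
  mu <- composite_signal(ls)
  cfg <- seq_model_config("tdcnn", blocks = 6L, channels = 4L, lr = 5e-3,
                          max_epochs = 30L, dropout = 0, seed = 2)
  fit <- v2p_calibrate(cfg, mu, r)
  h <- fit$history$train
  expect_lt(h[length(h)], h[1L])
  rec <- v2p_reconstruct(fit, mu)
  expect_true(all(rec$classes %in% 0:4))
  expect_length(rec$classes, length(mu$values))
})

test_that("reconstructed and native HRV agree across simulated sessions", {
  # one calibration, several sessions with varying autonomic balance
  r_cal <- simulate_ppg(sim_config(duration = 25, fs = 200, mean_ibi = 0.85,
                                   seed = 30, noise_sd = 0.02))
  ls_cal <- simulate_landmark_series(r_cal, 12, 8, gains = rep(1, 8),
                                     noise_sd = 0.15, fps = 25, seed = 31)
  cfg <- seq_model_config("lstm", input_units = 32L, hidden = c(16L, 16L),
                          lr = 5e-3, batch = 64L, max_epochs = 40L, seed = 1)
  fit <- v2p_calibrate(cfg, composite_signal(ls_cal), r_cal)
  ratios <- with_seed(99, t(vapply(1:8, function(s) {
    lf <- stats::runif(1, 0.01, 0.08)
    hf <- 0.09 - lf
    r <- simulate_ppg(sim_config(duration = 75, fs = 200, mean_ibi = 0.85,
                                 seed = 300 + s, noise_sd = 0.02,
                                 lf_mod = c(0.1, lf), hf_mod = c(0.25, hf)))
    ls <- simulate_landmark_series(r, 12, 8, gains = rep(1, 8),
                                   noise_sd = 0.15, fps = 25, seed = 400 + s)
    rec <- v2p_reconstruct(fit, composite_signal(ls))
    c(rec = band_powers(tachogram(ibi_series(rec$m1_times)))$ratio,
      true = band_powers(tachogram(ibi_series(r$beat_onsets)))$ratio)
  }, numeric(2))))
  expect_gt(stats::cor(log(ratios[, "rec"]), log(ratios[, "true"])), 0.9)
})
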