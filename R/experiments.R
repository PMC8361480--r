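# Self-contained evaluation experiments. Each runs the full pipeline on
# synthetic data at desk scale and returns the headline quantities that the
# test suite asserts and scripts/acceptance.R reports. Sub-seeds are derived
# from the single `seed` argument.

#' Fiducial-recovery experiment
#'
#' Noiseless arm: 10-beat record at 50 Hz, segmentation + extrema detection
#' against generator truth. Noisy arm: the same conditions with additive
#' noise at 5% of the pulse amplitude, after band-pass filtering.
#'
#' @param seed integer seed.
#' @return list with `max_error_clean` and `median_error_noisy` (samples),
#'   and the beat counts used.
#' @export
exp_fiducial_recovery <- function(seed = 1L) {
  score <- function(record, signal) {
    segs <- Filter(function(w) isTRUE(w$compliant),
                   lapply(segment_waveforms(signal, record$fs), detect_extrema))
    errs <- numeric(0)
    for (w in segs) {
      b <- which.min(abs(record$beat_onsets - w$start_time))
      if (abs(record$beat_onsets[b] - w$start_time) * record$fs > 3) next
      tb <- record$true_extrema[record$true_extrema$beat == b, ]
      errs <- c(errs, abs(w$extrema$t - tb$t) * record$fs)
    }
    list(errs = errs, n = length(segs))
  }
  r0 <- simulate_ppg(sim_config(duration = 10, fs = 50, mean_ibi = 1, seed = seed))
  clean <- score(r0, r0$clean)
  rn <- simulate_ppg(sim_config(duration = 10, fs = 50, mean_ibi = 1,
                                seed = seed + 1L, noise_sd = 0.05))
  noisy <- score(rn, bandpass_filter(rn$samples, rn$fs))
  list(max_error_clean = max(clean$errs),
       median_error_noisy = stats::median(noisy$errs),
       n_beats_clean = clean$n, n_beats_noisy = noisy$n)
}

#' LSTM-cell oracle experiment
#'
#' Compares one forward step against scalar hand arithmetic of the gate
#' recurrences and the zero-weight closed form `C_t = 0.5 C_prev`.
#'
#' @return list with `max_abs_error` (hand arithmetic) and
#'   `zero_weight_error` (closed form).
#' @export
exp_lstm_cell_oracle <- function() {
  p <- lstm_cell_params(1, 1)
  for (nm in c("W_f", "W_i", "W_C", "W_o")) p[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_C", "b_o")) p[[nm]][] <- 0
  z0 <- lstm_cell_step(p, 0.3, 0.2, 2)
  zw_err <- max(abs(z0$C - 1), abs(z0$h - 0.5 * tanh(1)))
  p$W_f[] <- 0.5; p$W_i[] <- -0.3; p$W_C[] <- 0.7; p$W_o[] <- 0.2
  p$b_f <- 0.1; p$b_i <- -0.2; p$b_C <- 0.3; p$b_o <- 0.05
  h_prev <- 0.4; x_t <- -0.6; C_prev <- 0.8
  sg <- function(a) 1 / (1 + exp(-a))
  z <- c(h_prev, x_t)
  f <- sg(sum(0.5 * z) + 0.1); i <- sg(sum(-0.3 * z) - 0.2)
  g <- tanh(sum(0.7 * z) + 0.3); o <- sg(sum(0.2 * z) + 0.05)
  C_exp <- f * C_prev + i * g
  out <- lstm_cell_step(p, x_t, h_prev, C_prev)
  list(max_abs_error = max(abs(out$C - C_exp), abs(out$h - o * tanh(C_exp))),
       zero_weight_error = zw_err)
}

#' Vision2PPG parameter-recovery experiment
#'
#' One 80 s coupled recording: the first 20 s calibrate the LSTM (paper
#' topology, reduced epochs), the following 60 s are held out. Then the
#' calibrated model is applied to `n_sessions` fresh recordings with varying
#' LF/HF balance and the LF/HF ratio from reconstructed beat onsets is
#' correlated with the ratio from generator-truth onsets.
#'
#' @param seed integer seed.
#' @param epochs training epoch cap (desk-scale default 25).
#' @param n_sessions number of fresh recordings for the HRV comparison.
#' @return list with `heldout_correlation`, `m1_median_error_ms`,
#'   `hrv_ratio_correlation` and sizes.
#' @export
exp_v2p_recovery <- function(seed = 1L, epochs = 25L, n_sessions = 20L) {
  base <- as.integer(seed) * 1000L
  r <- simulate_ppg(sim_config(duration = 80, fs = 1000, mean_ibi = 0.9,
                               seed = base + 11L, lf_mod = c(0.1, 0.05),
                               hf_mod = c(0.25, 0.04), noise_sd = 0.02))
  gains <- with_seed(base + 12L, stats::runif(40, 0.5, 1.5))
  ls <- simulate_landmark_series(r, 68, 40, gains = gains, noise_sd = 0.3,
                                 fps = 50, seed = base + 12L)
  mu_all <- composite_signal(ls, calib_window = 1:1000)
  mu_cal <- mu_all; mu_cal$values <- mu_all$values[1:1000]
  ppg_cal <- r; ppg_cal$samples <- r$samples[1:20000]
  cfg <- seq_model_config("lstm", max_epochs = epochs, batch = 64L,
                          lr = 1e-3, seed = base + 5L)
  fit <- v2p_calibrate(cfg, mu_cal, ppg_cal)
  mu_test <- mu_all; mu_test$values <- mu_all$values[1001:4000]
  rec <- v2p_reconstruct(fit, mu_test)
  truth <- resample_linear(r$clean, r$fs, 50)[1001:4000]
  held_r <- stats::cor(rec$values, truth)
  tru_m1 <- r$beat_onsets[r$beat_onsets >= 20]
  m1_err <- vapply(rec$m1_times + 20, function(t) min(abs(tru_m1 - t)), numeric(1))
  ratios <- with_seed(base + 99L, t(vapply(seq_len(n_sessions), function(s) {
    lf <- stats::runif(1, 0.01, 0.08); hf <- 0.09 - lf
    rs <- simulate_ppg(sim_config(duration = 75, fs = 1000, mean_ibi = 0.9,
                                  seed = base + 300L + s, noise_sd = 0.02,
                                  lf_mod = c(0.1, lf), hf_mod = c(0.25, hf)))
    lss <- simulate_landmark_series(rs, 68, 40, gains = gains, noise_sd = 0.3,
                                    fps = 50, seed = base + 400L + s)
    recs <- v2p_reconstruct(fit, composite_signal(lss))
    c(rec = band_powers(tachogram(ibi_series(recs$m1_times)))$ratio,
      true = band_powers(tachogram(ibi_series(rs$beat_onsets)))$ratio)
  }, numeric(2))))
  list(heldout_correlation = held_r,
       m1_median_error_ms = stats::median(m1_err) * 1000,
       hrv_ratio_correlation = stats::cor(log(ratios[, "rec"]),
                                          log(ratios[, "true"])),
       n_sessions = n_sessions, n_beats = length(rec$m1_times))
}

#' HRV discrimination experiment
#'
#' Single-band tachograms from generator-truth onsets (LF-only and HF-only),
#' plus a 20+20 cohort of noisy recordings pushed through the full detection
#' pipeline and classified at the calibrated LF/HF threshold.
#'
#' @param seed integer seed.
#' @param n_per_class recordings per class.
#' @return list with `lfhf_lf_only`, `lfhf_hf_only`, `accuracy` and sizes.
#' @export
exp_hrv_discrimination <- function(seed = 1L, n_per_class = 20L) {
  base <- as.integer(seed) * 1000L
  lf_only <- band_powers(tachogram(ibi_series(
    simulate_ppg(sim_config(duration = 300, fs = 100, mean_ibi = 0.8,
                            seed = base + 1L, lf_mod = c(0.1, 0.08),
                            hf_mod = c(0.25, 0)))$beat_onsets)))$ratio
  hf_only <- band_powers(tachogram(ibi_series(
    simulate_ppg(sim_config(duration = 300, fs = 100, mean_ibi = 0.8,
                            seed = base + 2L, lf_mod = c(0.1, 0),
                            hf_mod = c(0.25, 0.08)))$beat_onsets)))$ratio
  sim_ratio <- function(kind, s) {
    r <- simulate_ppg(sim_config(
      duration = 120, fs = 100, mean_ibi = stats::runif(1, 0.75, 0.95),
      seed = s, noise_sd = 0.03,
      lf_mod = c(0.1, if (kind == "wakeful") 0.08 else 0.02),
      hf_mod = c(0.25, if (kind == "wakeful") 0.02 else 0.08)))
    segs <- Filter(function(w) isTRUE(w$compliant),
                   lapply(segment_waveforms(bandpass_filter(r$samples, r$fs),
                                            r$fs), detect_extrema))
    band_powers(tachogram(extract_ibi(segs)))$ratio
  }
  ratios <- with_seed(base + 10L, data.frame(
    ratio = c(vapply(seq_len(n_per_class),
                     function(s) sim_ratio("wakeful", base + 100L + s), numeric(1)),
              vapply(seq_len(n_per_class),
                     function(s) sim_ratio("drowsy", base + 200L + s), numeric(1))),
    label = rep(c("wakeful", "drowsy"), each = n_per_class)))
  thr <- calibrate_attention_threshold(ratios$ratio, ratios$label)
  pred <- ifelse(ratios$ratio >= thr, "wakeful", "drowsy")
  list(lfhf_lf_only = lf_only, lfhf_hf_only = hf_only,
       accuracy = mean(pred == ratios$label), threshold = thr,
       n = 2L * n_per_class)
}

#' Blood-pressure classifier experiment
#'
#' A beat cohort with the stated mAI class separation; phi vectors from
#' consecutive beat pairs, a 70/30 split, the 64-500-300-1 network trained
#' with scaled conjugate gradient, plus a label-shuffled control. The
#' default cohort (400 beats per class) gives the shuffled control enough
#' held-out vectors that its binomial noise stays well inside the
#' chance band.
#'
#' @param seed integer seed.
#' @param n_beats_per_class cohort size per class.
#' @return list with `mai_separation_sd`, `heldout_accuracy`,
#'   `shuffled_accuracy` and sizes.
#' @export
exp_bp_classifier <- function(seed = 1L, n_beats_per_class = 400L) {
  base <- as.integer(seed) * 1000L
  coh <- simulate_bp_cohort(n_beats_per_class, seed = base + 9L)
  mai <- vapply(coh$waveforms, compute_mai, numeric(1))
  mn <- mai[coh$labels == "normal"]; ab <- mai[coh$labels == "abnormal"]
  sep <- abs(mean(mn) - mean(ab)) / sqrt((stats::var(mn) + stats::var(ab)) / 2)
  pm <- phi_matrix(coh$waveforms, coh$labels)
  n <- nrow(pm$X)
  tr <- with_seed(base + 1L, sample(n, round(0.7 * n)))
  m <- train_snn(pm$X[tr, ], pm$y[tr], max_iter = 120L, seed = base + 2L)
  acc <- mean(classify_bp(m, pm$X[-tr, ])$label == as.character(pm$y[-tr]))
  y_sh <- with_seed(base + 3L, sample(pm$y[tr]))
  m_sh <- train_snn(pm$X[tr, ], y_sh, max_iter = 120L, seed = base + 2L)
  acc_sh <- mean(classify_bp(m_sh, pm$X[-tr, ])$label == as.character(pm$y[-tr]))
  list(mai_separation_sd = sep, heldout_accuracy = acc,
       shuffled_accuracy = acc_sh, n_vectors = n)
}

#' Eye-state classifier experiment
#'
#' 200 synthetic patches per class, 70/30 split, the 32/64/128 CNN trained at
#' the deployed learning rate for a reduced number of epochs, plus a
#' label-shuffled control.
#'
#' @param seed integer seed.
#' @param n_per_class patches per class.
#' @param epochs reduced training epochs.
#' @return list with `heldout_accuracy`, `shuffled_accuracy` and sizes.
#' @export
exp_eye_classifier <- function(seed = 1L, n_per_class = 200L, epochs = 2L) {
  base <- as.integer(seed) * 1000L
  open <- simulate_eye_patches(n_per_class, "open", seed = base + 21L)
  closed <- simulate_eye_patches(n_per_class, "closed", seed = base + 22L)
  imgs <- c(open$images, closed$images)
  labs <- c(as.character(open$labels), as.character(closed$labels))
  idx <- with_seed(base + 3L, sample(length(imgs)))
  n_tr <- round(0.7 * length(imgs))
  tr <- idx[seq_len(n_tr)]; te <- idx[(n_tr + 1L):length(imgs)]
  mod <- train_eye_cnn(imgs[tr], labs[tr],
                       eye_cnn_config(epochs = epochs, seed = base + 5L))
  acc <- mean(classify_eye(mod, imgs[te])$state == labs[te])
  labs_sh <- labs
  labs_sh[tr] <- with_seed(base + 7L, sample(labs[tr]))
  mod_sh <- train_eye_cnn(imgs[tr], labs_sh[tr],
                          eye_cnn_config(epochs = 1L, seed = base + 5L))
  acc_sh <- mean(classify_eye(mod_sh, imgs[te])$state == labs[te])
  list(heldout_accuracy = acc, shuffled_accuracy = acc_sh,
       n_train = length(tr), n_test = length(te))
}

#' Criss-cross attention oracle experiment
#'
#' Exhaustive triple-loop recomputation of affinity and aggregation over all
#' instances with `C' <= 4` and `H, W <= 6`, the per-position weight
#' normalization, and the R = 1 vs R = 2 receptive-field perturbation count
#' on a 6x6 grid.
#'
#' @param seed integer seed.
#' @return list with `oracle_max_abs_diff`, `max_weight_sum_error`,
#'   `r1_changed`, `r2_changed` and the instance count.
#' @export
exp_crisscross_oracle <- function(seed = 1L) {
  worst <- 0; worst_w <- 0; n_inst <- 0L
  with_seed(seed, {
    for (Cp in 1:4) for (H in 1:6) for (W in 1:6) {
      n_inst <- n_inst + 1L
      F1 <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
      F2 <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
      D <- cc_affinity(F1, F2)
      # brute force: loops over positions, path entries and channels
      for (r in seq_len(H)) for (cc in seq_len(W)) {
        u <- (cc - 1L) * H + r
        path <- criss_cross_path(c(r, cc), H, W)
        for (i in seq_len(nrow(path))) {
          ref <- sum(F1[, r, cc] * F2[, path[i, 1L], path[i, 2L]])
          worst <- max(worst, abs(D[i, u] - ref))
        }
      }
      A <- cc_attention_map(D)
      worst_w <- max(worst_w, max(abs(colSums(A) - 1)))
      theta <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
      H_in <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
      out <- cc_aggregate(A, theta, H_in)
      for (r in seq_len(H)) for (cc in seq_len(W)) {
        u <- (cc - 1L) * H + r
        path <- criss_cross_path(c(r, cc), H, W)
        ref <- H_in[, r, cc]
        for (i in seq_len(nrow(path)))
          ref <- ref + A[i, u] * theta[, path[i, 1L], path[i, 2L]]
        worst <- max(worst, max(abs(out[, r, cc] - ref)))
      }
    }
  })
  pars <- cc_params(4L, seed = seed)
  X <- unclass(make_toy_feature_map(4, 6, 6, seed = seed + 1L))
  X2 <- X; X2[, 2, 3] <- X2[, 2, 3] + 1
  d1 <- apply(abs(recurrent_cc(X2, pars, 1L) - recurrent_cc(X, pars, 1L)),
              c(2, 3), max)
  d2 <- apply(abs(recurrent_cc(X2, pars, 2L) - recurrent_cc(X, pars, 2L)),
              c(2, 3), max)
  list(oracle_max_abs_diff = worst, max_weight_sum_error = worst_w,
       r1_changed = sum(d1 > 1e-12), r2_changed = sum(d2 > 1e-12),
       n_instances = n_inst)
}

#' Salience-filter experiment
#'
#' Toy box sets including the exact-threshold boundary case.
#'
#' @return list with `survivors` and `boundary_survivors`.
#' @export
exp_salience_filter <- function() {
  cfg <- salience_config(40, 40)
  boxes <- make_toy_boxes(data.frame(x = 0, y = 0,
                                     h = c(50, 10, 10, 41, 40),
                                     w = c(10, 10, 50, 10, 40)))
  boundary <- make_toy_boxes(data.frame(x = 0, y = 0, h = 40, w = 40))
  list(survivors = length(filter_salient_boxes(boxes, cfg)),
       boundary_survivors = length(filter_salient_boxes(boundary, cfg)))
}

#' DSDS truth-table experiment
#'
#' Exhaustive enumeration of the 16 input combinations against the
#' independently coded rule table, plus the monotonicity and alert-implies-
#' salient properties.
#'
#' @return list with `agreement` (fraction), `monotone`, `alert_implies_salient`.
#' @export
exp_dsds_truth_table <- function() {
  grid <- expand.grid(h = c(FALSE, TRUE), b = c(FALSE, TRUE),
                      e = c(FALSE, TRUE), s = c(FALSE, TRUE))
  lv <- function(h, b, e, s) assess_risk(risk_inputs(h, b, e, s))$level
  got <- mapply(lv, grid$h, grid$b, grid$e, grid$s)
  oracle <- mapply(function(h, b, e, s) {
    if (h && (b || e) && s) "high" else if ((h || e) && s) "medium_low" else "none"
  }, grid$h, grid$b, grid$e, grid$s)
  rank <- c(none = 0L, medium_low = 1L, high = 2L)
  mono <- TRUE
  for (k in seq_len(nrow(grid))) {
    g <- as.logical(grid[k, ])
    for (j in which(!g)) {
      g2 <- g; g2[j] <- TRUE
      if (rank[[lv(g2[1], g2[2], g2[3], g2[4])]] <
          rank[[lv(g[1], g[2], g[3], g[4])]]) mono <- FALSE
    }
  }
  list(agreement = mean(got == oracle), monotone = mono,
       alert_implies_salient = all(got == "none" | grid$s))
}
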