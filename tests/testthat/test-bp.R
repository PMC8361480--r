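test_that("the modified augmentation index reproduces direct substitutions", {
  expect_equal(compute_mai(hand_beat(0, c(0, 2, 1, 0.5))), 0.5)
  expect_equal(compute_mai(hand_beat(0, c(0, 2, 1, 0))), 1)
  expect_equal(compute_mai(hand_beat(0, c(0.2, 2, 1.2, 1.0))), 0)
  expect_error(compute_mai(hand_beat(0, c(0.7, 2, 0.7, 0.5))), "undefined")
  # invariant to uniform amplitude scaling (the literal formula is a ratio
  # of amplitude differences over an amplitude difference)
  base <- compute_mai(hand_beat(0, c(0.1, 2, 1.1, 0.6)))
  expect_equal(compute_mai(hand_beat(0, 5 * c(0.1, 2, 1.1, 0.6))), base)
})

test_that("beat-pair features satisfy the translation and scaling identities", {
  ys <- c(0, 1, 0.3, 0.45)
  b1 <- hand_beat(0, ys)
  b2 <- hand_beat(1.0, ys)  # identical beat one period later
  pf <- beat_pair_features(b1, b2)
  expect_equal(pf$dx, rep(1.0, 4))
  expect_equal(pf$dy, rep(0, 4))
  # amplitude-scaled successor: dy = y of beat j, dx unchanged
  b3 <- hand_beat(1.0, 2 * ys)
  pf2 <- beat_pair_features(b1, b3)
  expect_equal(pf2$dy, ys)
  expect_equal(pf2$dx, pf$dx)
  # direct-substitution check on hand-placed extrema
  bh <- hand_beat(0, c(0, 1.5, 0.4, 0.6), ts_rel = c(0, 0.3, 0.5, 0.7))
  bh2 <- hand_beat(0.9, c(0.05, 1.4, 0.35, 0.62), ts_rel = c(0, 0.31, 0.52, 0.68))
  pf3 <- beat_pair_features(bh, bh2)
  expect_equal(pf3$coords[, "x"], c(0, 0.3, 0.5, 0.7))
  expect_equal(pf3$dx, c(0.9, 0.91, 0.92, 0.88), tolerance = 1e-12)
  expect_equal(pf3$dy, c(0.05, -0.1, -0.05, 0.02), tolerance = 1e-12)
  expect_equal(pf3$mai, ((0.4 - 0) - 0.6) / (0.4 - 0))
  # missing extrema are rejected
  expect_error(beat_pair_features(ppg_waveform(1:50, 50), b2), "extrema")
})

test_that("phi assembly packs, pads and stays order-sensitive", {
  ys <- c(0, 1, 0.3, 0.45)
  p1 <- beat_pair_features(hand_beat(0, ys), hand_beat(1, ys))
  p2 <- beat_pair_features(hand_beat(1, 2 * ys), hand_beat(2, ys))
  phi3 <- assemble_phi(list(p1, p2, p1))
  expect_length(phi3, 64L)
  expect_true(all(phi3[52:64] == 0))
  phi1 <- assemble_phi(list(p1))
  expect_true(all(phi1[18:64] == 0))
  expect_false(isTRUE(all.equal(assemble_phi(list(p1, p2, p1)),
                                assemble_phi(list(p2, p1, p1)))))
  expect_error(assemble_phi(list()), "at least one")
})

test_that("reference labeling applies the 15% band with inclusive boundaries", {
  expect_equal(label_from_reference(120, 80), "normal")
  expect_equal(label_from_reference(139, 80), "abnormal")  # 139 > 1.15 * 120
  expect_equal(label_from_reference(102, 68), "normal")    # exactly at 0.85
  expect_equal(label_from_reference(138, 92), "normal")    # both at +15%
  expect_equal(label_from_reference(120, 95), "abnormal")
  expect_equal(label_from_reference(101.9, 80), "abnormal")
})

test_that("the shallow network separates linearly separable phi classes", {
  set.seed(2)
  X <- rbind(matrix(stats::rnorm(50 * 64), 50),
             matrix(stats::rnorm(50 * 64, mean = 1.5), 50))
  y <- rep(c("normal", "abnormal"), each = 50)
  m <- train_snn(X, y, hidden = c(20L, 10L), max_iter = 80, seed = 3)
  expect_equal(mean(classify_bp(m, X)$label == y), 1)
  expect_error(train_snn(X, rep("normal", 100)), "both classes")
})

test_that("the 0.5 output boundary maps to normal", {
  # zero weights give a logistic output of exactly 0.5
  m <- structure(list(par = rep(0, 64 * 2 + 2 + 2 * 1 + 1),
                      sizes = c(64L, 2L, 1L),
                      center = rep(0, 64), scale = rep(1, 64)),
                 class = "snn_model")
  out <- classify_bp(m, rep(1, 64))
  expect_equal(out$output, 0.5)
  expect_equal(out$flag, 0L)
  expect_equal(out$label, "normal")
})

test_that("label swapping mirrors classifier accuracy", {
  coh <- simulate_bp_cohort(60, seed = 4)
  pm <- phi_matrix(coh$waveforms, coh$labels)
  n <- nrow(pm$X)
  tr <- with_seed(7, sample(n, round(0.7 * n)))
  m1 <- train_snn(pm$X[tr, ], pm$y[tr], hidden = c(50L, 20L), max_iter = 80, seed = 5)
  acc <- mean(classify_bp(m1, pm$X[-tr, ])$label == as.character(pm$y[-tr]))
  y_sw <- factor(ifelse(pm$y == "normal", "abnormal", "normal"),
                 levels = levels(pm$y))
  m2 <- train_snn(pm$X[tr, ], y_sw[tr], hidden = c(50L, 20L), max_iter = 80, seed = 5)
  acc_sw <- mean(classify_bp(m2, pm$X[-tr, ])$label == as.character(pm$y[-tr]))
  expect_lt(abs(acc_sw - (1 - acc)), 0.15)
})
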