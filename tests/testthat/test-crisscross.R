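# Exhaustive triple-loop oracles used to verify the vectorized operations.
oracle_affinity <- function(F1, F2) {
  d <- dim(F1); H <- d[2L]; W <- d[3L]
  D <- matrix(NA_real_, H + W - 1L, H * W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    u <- (cc - 1L) * H + r
    path <- criss_cross_path(c(r, cc), H, W)
    for (i in seq_len(nrow(path)))
      D[i, u] <- sum(F1[, r, cc] * F2[, path[i, 1L], path[i, 2L]])
  }
  D
}

oracle_aggregate <- function(A, theta, H_in) {
  d <- dim(theta); H <- d[2L]; W <- d[3L]
  out <- H_in
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    u <- (cc - 1L) * H + r
    path <- criss_cross_path(c(r, cc), H, W)
    for (i in seq_len(nrow(path)))
      out[, r, cc] <- out[, r, cc] + A[i, u] * theta[, path[i, 1L], path[i, 2L]]
  }
  out
}

test_that("criss-cross paths have the contracted geometry", {
  expect_equal(criss_cross_path(c(1, 1), 1, 1), cbind(1L, 1L))
  for (u in list(c(1, 1), c(2, 3), c(3, 4))) {
    path <- criss_cross_path(u, 3, 4)
    expect_equal(nrow(path), 6L)  # H + W - 1
    expect_equal(sum(path[, 1L] == u[1L] & path[, 2L] == u[2L]), 1L)
  }
  # union over all u covers the grid
  covered <- matrix(FALSE, 3, 4)
  for (r in 1:3) for (cc in 1:4) {
    path <- criss_cross_path(c(r, cc), 3, 4)
    covered[path] <- TRUE
  }
  expect_true(all(covered))
  expect_error(criss_cross_path(c(4, 1), 3, 4), "outside")
})

test_that("affinity, softmax and aggregation match the exhaustive oracle", {
  set.seed(8)
  for (Cp in c(1L, 2L, 4L)) for (H in c(1L, 3L, 6L)) for (W in c(1L, 4L, 6L)) {
    F1 <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
    F2 <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
    D <- cc_affinity(F1, F2)
    expect_lt(max(abs(D - oracle_affinity(F1, F2))), 1e-6)
    A <- cc_attention_map(D)
    expect_true(all(abs(colSums(A) - 1) < 1e-6))
    theta <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
    H_in <- array(stats::rnorm(Cp * H * W), c(Cp, H, W))
    expect_lt(max(abs(cc_aggregate(A, theta, H_in) -
                        oracle_aggregate(A, theta, H_in))), 1e-6)
  }
})

test_that("degenerate affinity inputs behave symmetrically", {
  Fc <- array(2, c(1, 3, 4))
  D <- cc_affinity(Fc, Fc)
  expect_true(all(D == 4))  # c^2 everywhere in each search row
  F0 <- array(0, c(2, 3, 3))
  expect_true(all(cc_affinity(F0, F0) == 0))
  expect_error(cc_affinity(array(0, c(1, 2, 2)), array(0, c(2, 2, 2))), "share")
})

test_that("attention weights respond to logits as a softmax should", {
  D <- matrix(0, 6, 12)
  attr(D, "H") <- 3L; attr(D, "W") <- 4L
  A <- cc_attention_map(D)
  expect_true(all(abs(A - 1 / 6) < 1e-12))
  D2 <- D; D2[4, 7] <- 50
  A2 <- cc_attention_map(D2)
  expect_gt(A2[4, 7], 1 - 1e-6)
})

test_that("aggregation reduces to known closed forms", {
  H <- 3L; W <- 4L; C <- 2L
  A <- matrix(1 / (H + W - 1), H + W - 1, H * W)
  theta <- array(2.5, c(C, H, W))
  zero_in <- array(0, c(C, H, W))
  out <- cc_aggregate(A, theta, zero_in)
  expect_true(all(abs(out - 2.5) < 1e-9))
  # one-hot attention on u's own path slot plus the residual doubles the input
  H_in <- array(stats::rnorm(C * H * W), c(C, H, W))
  A_self <- matrix(0, H + W - 1, H * W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    u <- (cc - 1L) * H + r
    A_self[cc, u] <- 1  # the row part places u at path index = its column
  }
  out2 <- cc_aggregate(A_self, H_in, H_in)
  expect_equal(out2, 2 * H_in, tolerance = 1e-9)
  # zero logits: path mean of the value map plus the input
  D0 <- matrix(0, H + W - 1, H * W)
  attr(D0, "H") <- H; attr(D0, "W") <- W
  A0 <- cc_attention_map(D0)
  theta2 <- array(stats::rnorm(C * H * W), c(C, H, W))
  out3 <- cc_aggregate(A0, theta2, H_in)
  r <- 2L; cc <- 3L
  idx <- criss_cross_path(c(r, cc), H, W)
  pm <- rowMeans(vapply(seq_len(nrow(idx)),
                        function(i) theta2[, idx[i, 1L], idx[i, 2L]],
                        numeric(C)))
  expect_equal(out3[, r, cc], H_in[, r, cc] + pm, tolerance = 1e-9)
})

test_that("recurrence widens the receptive field to the full image", {
  C <- 4L
  pars <- cc_params(C, seed = 2)
  X <- unclass(make_toy_feature_map(C, 6, 6, seed = 3))
  X2 <- X; X2[, 2, 3] <- X2[, 2, 3] + 1
  expect_equal(recurrent_cc(X, pars, 1L), criss_cross_layer(X, pars))
  d1 <- apply(abs(recurrent_cc(X2, pars, 1L) - recurrent_cc(X, pars, 1L)),
              c(2, 3), max)
  d2 <- apply(abs(recurrent_cc(X2, pars, 2L) - recurrent_cc(X, pars, 2L)),
              c(2, 3), max)
  expect_equal(sum(d1 > 1e-12), 11L)   # row + column of the perturbed pixel
  expect_equal(sum(d2 > 1e-12), 36L)   # full-image dependency at R = 2
  expect_equal(dim(recurrent_cc(X, pars, 3L)), dim(X))
})

test_that("the salience filter applies strict thresholds", {
  cfg <- salience_config(40, 40)
  boxes <- make_toy_boxes(data.frame(x = 0, y = 0,
                                     h = c(50, 10, 10), w = c(10, 10, 50)))
  expect_length(filter_salient_boxes(boxes, cfg), 2L)
  boundary <- make_toy_boxes(data.frame(x = 0, y = 0, h = 40, w = 10))
  expect_length(filter_salient_boxes(boundary, cfg), 0L)
  expect_length(filter_salient_boxes(list(), cfg), 0L)
})
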