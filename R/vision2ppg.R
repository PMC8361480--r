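#' Composite landmark signal
#'
#' Collapses the per-landmark intensity matrix to its frame-wise mean
#' `mu(t_k) = (1/N_L) sum_j l_j(t_k)` and z-normalizes it with mean/s.d.
#' estimated on a calibration window (default: the full series). The
#' normalization constants are stored so a calibrated model can be applied to
#' later segments on the same scale.
#'
#' @param ls a `landmark_series`.
#' @param calib_window optional integer index range used for the
#'   normalization constants.
#' @return object of class `composite_signal`: `values` (normalized), `raw`,
#'   `fps`, `norm_mean`, `norm_sd`.
#' @export
composite_signal <- function(ls, calib_window = NULL) {
  stopifnot(inherits(ls, "landmark_series"))
  if (!all(is.finite(ls$intensities)))
    stop("landmark intensities contain non-finite values", call. = FALSE)
  mu <- rowMeans(ls$intensities)
  win <- if (is.null(calib_window)) seq_along(mu) else calib_window
  m <- mean(mu[win]); s <- stats::sd(mu[win])
  if (!is.finite(s) || s == 0) s <- 1
  structure(list(values = (mu - m) / s, raw = mu, fps = ls$fps,
                 norm_mean = m, norm_sd = s),
            class = "composite_signal")
}

#' LSTM cell parameters
#'
#' The four gate weight matrices share the shape `hidden x (hidden + input)`
#' (they act on the concatenation `[h_prev, x_t]`), with one bias vector per
#' gate. Initialization is small uniform with a +1 forget-gate bias.
#'
#' @param input input dimension.
#' @param hidden hidden state dimension.
#' @param init_scale half-width of the uniform initial weights.
#' @return list of class `lstm_cell_params` with `W_f`, `W_i`, `W_C`, `W_o`,
#'   `b_f`, `b_i`, `b_C`, `b_o`.
#' @export
lstm_cell_params <- function(input, hidden, init_scale = 0.08) {
  mk <- function() matrix(stats::runif(hidden * (hidden + input),
                                       -init_scale, init_scale),
                          nrow = hidden)
  structure(list(W_f = mk(), W_i = mk(), W_C = mk(), W_o = mk(),
                 b_f = rep(1, hidden), b_i = rep(0, hidden),
                 b_C = rep(0, hidden), b_o = rep(0, hidden),
                 input = input, hidden = hidden),
            class = "lstm_cell_params")
}

#' One forward step of the LSTM cell
#'
#' Implements the standard gated recurrence: forget gate
#' `f_t = sigma(W_f [h_prev, x_t] + b_f)`, input gate
#' `i_t = sigma(W_i [h_prev, x_t] + b_i)`, candidate state
#' `Ct_t = tanh(W_C [h_prev, x_t] + b_C)`, cell state
#' `C_t = f_t * C_prev + i_t * Ct_t`, output gate
#' `o_t = sigma(W_o [h_prev, x_t] + b_o)` and output
#' `h_t = o_t * tanh(C_t)`.
#'
#' Accepts vectors (a single example) or matrices with one example per row.
#'
#' @param p an [lstm_cell_params()].
#' @param x_t input vector (length `input`) or `B x input` matrix.
#' @param h_prev,C_prev previous output and cell state (length `hidden` or
#'   `B x hidden`).
#' @return list with `h` and `C` (and, invisibly, the gate activations used
#'   by backpropagation as attribute `cache`).
#' @export
lstm_cell_step <- function(p, x_t, h_prev, C_prev) {
  stopifnot(inherits(p, "lstm_cell_params"))
  vec <- !is.matrix(x_t)
  if (vec) {
    x_t <- matrix(x_t, nrow = 1L)
    h_prev <- matrix(h_prev, nrow = 1L)
    C_prev <- matrix(C_prev, nrow = 1L)
  }
  if (ncol(x_t) != p$input || ncol(h_prev) != p$hidden || ncol(C_prev) != p$hidden)
    stop("dimension mismatch between parameters and state", call. = FALSE)
  z <- cbind(h_prev, x_t)
  f <- sigmoid(sweep(z %*% t(p$W_f), 2L, p$b_f, `+`))
  i <- sigmoid(sweep(z %*% t(p$W_i), 2L, p$b_i, `+`))
  g <- tanh(sweep(z %*% t(p$W_C), 2L, p$b_C, `+`))
  o <- sigmoid(sweep(z %*% t(p$W_o), 2L, p$b_o, `+`))
  C <- f * C_prev + i * g
  h <- o * tanh(C)
  out <- if (vec) list(h = as.numeric(h), C = as.numeric(C)) else list(h = h, C = C)
  attr(out, "cache") <- list(z = z, f = f, i = i, g = g, o = o, C = C,
                             C_prev = C_prev)
  out
}

#' Sequence model configuration
#'
#' Architecture and training settings for the two PPG-reconstruction models.
#' The LSTM reads the composite landmark signal framed as sliding windows of
#' `input_units` consecutive samples (stride 1, one target sample per window)
#' through two hidden layers of 64 and 128 cells and a scalar regression
#' head. The dilated temporal CNN stacks `blocks` residual blocks of two
#' causal dilated convolutions (kernel 3), dilation doubling from 2 and
#' capped at 16, with a per-time-step 5-class softmax head over
#' `{none, m1, m2, m3, m4}`.
#'
#' @param kind `"lstm"` or `"tdcnn"`.
#' @param input_units LSTM window length (= input layer width).
#' @param hidden LSTM hidden layer sizes.
#' @param lr initial learning rate (Adam).
#' @param batch minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on the held-out tail.
#' @param blocks,kernel,channels,dropout dilated-CNN block count, kernel
#'   width, channel width and spatial dropout rate.
#' @param seed integer seed for initialization and shuffling.
#' @return list of class `seq_model_config`.
#' @export
seq_model_config <- function(kind = c("lstm", "tdcnn"),
                             input_units = 64L, hidden = c(64L, 128L),
                             lr = 1e-3, batch = if (kind[1] == "lstm") 512L else 1L,
                             max_epochs = if (kind[1] == "lstm") 200L else 60L,
                             patience = 6L,
                             blocks = 25L, kernel = 3L, channels = 8L,
                             dropout = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(input_units >= 1L, all(hidden >= 1L), lr > 0, batch >= 1L,
            blocks >= 1L, kernel >= 2L, channels >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(kind = kind, input_units = as.integer(input_units),
                 hidden = as.integer(hidden), lr = lr,
                 batch = as.integer(batch), max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), blocks = as.integer(blocks),
                 kernel = as.integer(kernel), channels = as.integer(channels),
                 dropout = dropout, seed = as.integer(seed)),
            class = "seq_model_config")
}

#' Dilation schedule and receptive field of the dilated temporal CNN
#'
#' The per-block dilation doubles from 2 and is capped at 16; each block
#' applies two causal convolutions, so the receptive field is
#' `1 + sum_b 2 (kernel - 1) d_b`.
#'
#' @param cfg a `seq_model_config` of kind `"tdcnn"`.
#' @return list with `dilations` and `receptive_field` (samples).
#' @export
tdcnn_receptive_field <- function(cfg) {
  d <- pmin(2^(seq_len(cfg$blocks)), 16L)
  list(dilations = d,
       receptive_field = 1L + sum(2L * (cfg$kernel - 1L) * d))
}

# ---- internal: stacked-LSTM forward/backward over a window batch ----------

lstm_stack_init <- function(cfg) {
  sizes <- c(1L, cfg$hidden)
  layers <- lapply(seq_along(cfg$hidden), function(l)
    lstm_cell_params(sizes[l], sizes[l + 1L]))
  H_top <- cfg$hidden[length(cfg$hidden)]
  list(layers = layers,
       W_out = matrix(stats::runif(H_top, -0.08, 0.08), nrow = 1L),
       b_out = 0)
}

# X: B x T window batch; returns predictions and (optionally) the BPTT cache.
lstm_stack_forward <- function(params, X, keep_cache = FALSE) {
  B <- nrow(X); Tn <- ncol(X)
  L <- length(params$layers)
  h <- lapply(params$layers, function(p) matrix(0, B, p$hidden))
  C <- h
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    x <- matrix(X[, t], ncol = 1L)
    step_caches <- if (keep_cache) vector("list", L) else NULL
    for (l in seq_len(L)) {
      out <- lstm_cell_step(params$layers[[l]], x, h[[l]], C[[l]])
      if (keep_cache) step_caches[[l]] <- attr(out, "cache")
      h[[l]] <- out$h; C[[l]] <- out$C
      x <- out$h
    }
    if (keep_cache) cache[[t]] <- step_caches
  }
  top <- h[[L]]
  pred <- as.numeric(top %*% t(params$W_out)) + params$b_out
  list(pred = pred, top = top, cache = cache)
}

lstm_zero_grads <- function(params) {
  gl <- lapply(params$layers, function(p)
    list(W_f = 0 * p$W_f, W_i = 0 * p$W_i, W_C = 0 * p$W_C, W_o = 0 * p$W_o,
         b_f = 0 * p$b_f, b_i = 0 * p$b_i, b_C = 0 * p$b_C, b_o = 0 * p$b_o))
  list(layers = gl, W_out = 0 * params$W_out, b_out = 0)
}

# Backward pass for MSE loss on the final-step scalar prediction.
lstm_stack_backward <- function(params, X, y, fw) {
  B <- nrow(X); Tn <- ncol(X); L <- length(params$layers)
  grads <- lstm_zero_grads(params)
  dpred <- 2 * (fw$pred - y) / B
  grads$W_out <- matrix(dpred, nrow = 1L) %*% fw$top
  grads$b_out <- sum(dpred)
  dh_next <- lapply(params$layers, function(p) matrix(0, B, p$hidden))
  dC_next <- dh_next
  dh_next[[L]] <- outer(dpred, as.numeric(params$W_out))
  for (t in seq.int(Tn, 1L)) {
    dx_upper <- NULL
    for (l in seq.int(L, 1L)) {
      p <- params$layers[[l]]
      cc <- fw$cache[[t]][[l]]
      dh <- dh_next[[l]]
      if (!is.null(dx_upper)) dh <- dh + dx_upper
      tC <- tanh(cc$C)
      do <- dh * tC
      dC <- dC_next[[l]] + dh * cc$o * (1 - tC^2)
      df <- dC * cc$C_prev
      di <- dC * cc$g
      dg <- dC * cc$i
      dC_prev <- dC * cc$f
      da_f <- df * cc$f * (1 - cc$f)
      da_i <- di * cc$i * (1 - cc$i)
      da_g <- dg * (1 - cc$g^2)
      da_o <- do * cc$o * (1 - cc$o)
      g <- grads$layers[[l]]
      g$W_f <- g$W_f + t(da_f) %*% cc$z
      g$W_i <- g$W_i + t(da_i) %*% cc$z
      g$W_C <- g$W_C + t(da_g) %*% cc$z
      g$W_o <- g$W_o + t(da_o) %*% cc$z
      g$b_f <- g$b_f + colSums(da_f)
      g$b_i <- g$b_i + colSums(da_i)
      g$b_C <- g$b_C + colSums(da_g)
      g$b_o <- g$b_o + colSums(da_o)
      grads$layers[[l]] <- g
      dz <- da_f %*% p$W_f + da_i %*% p$W_i + da_g %*% p$W_C + da_o %*% p$W_o
      H <- p$hidden
      dh_next[[l]] <- dz[, seq_len(H), drop = FALSE]
      dC_next[[l]] <- dC_prev
      dx_upper <- if (p$input > 1L || l > 1L)
        dz[, H + seq_len(p$input), drop = FALSE] else NULL
      if (l == 1L) dx_upper <- NULL
    }
  }
  grads
}

# ---- internal: Adam optimizer -------------------------------------------
# The gradient structure mirrors only the trainable leaves of the parameter
# list (structural fields like layer sizes and dilations are absent from it);
# the walk follows the gradients, so those fields are left untouched.

adam_state <- function(grad_template) {
  walk <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) lapply(x, walk) else 0 * x
  }
  list(m = walk(grad_template), v = walk(grad_template), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  walk <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(g)) {
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = tt))
}

#' Calibrate a Vision2PPG sequence model
#'
#' Trains the configured model to map the composite landmark signal onto the
#' concurrently sampled PPG. The PPG is linearly downsampled to the landmark
#' frame rate and z-scored; for the LSTM the task is next-sample regression
#' from 64-sample windows (MSE loss), for the dilated CNN it is per-sample
#' 5-class fiducial labeling (cross-entropy against labels derived from the
#' record's ground-truth extrema or from derivative analysis). The last 20%
#' of the calibration window is held out for early stopping.
#'
#' @param cfg a [seq_model_config()].
#' @param mu a [composite_signal()] covering the calibration window (>= 15 s).
#' @param ppg the paired `ppg_record`.
#' @return object of class `v2p_model` with the trained weights, the
#'   normalization constants and the training history.
#' @export
v2p_calibrate <- function(cfg, mu, ppg) {
  stopifnot(inherits(cfg, "seq_model_config"), inherits(mu, "composite_signal"),
            inherits(ppg, "ppg_record"))
  if (length(mu$values) / mu$fps < 15)
    stop("calibration window must cover at least 15 s", call. = FALSE)
  target_raw <- resample_linear(ppg$samples, ppg$fs, mu$fps)
  n <- min(length(target_raw), length(mu$values))
  if (abs(length(target_raw) - length(mu$values)) > 2L)
    stop("landmark and PPG series do not cover the same window", call. = FALSE)
  x <- mu$values[seq_len(n)]
  t_mean <- mean(target_raw[seq_len(n)]); t_sd <- stats::sd(target_raw[seq_len(n)])
  if (t_sd == 0) stop("degenerate (constant) PPG target", call. = FALSE)
  y <- (target_raw[seq_len(n)] - t_mean) / t_sd
  if (cfg$kind == "lstm") {
    fit <- with_seed(cfg$seed, train_lstm(cfg, x, y))
  } else {
    labels <- fiducial_class_labels(ppg, mu$fps, n)
    fit <- with_seed(cfg$seed, train_tdcnn(cfg, x, labels))
  }
  structure(list(kind = cfg$kind, cfg = cfg, params = fit$params,
                 history = fit$history, fps = mu$fps,
                 mu_norm = c(mean = mu$norm_mean, sd = mu$norm_sd),
                 target_norm = c(mean = t_mean, sd = t_sd)),
            class = "v2p_model")
}

#' @export
print.v2p_model <- function(x, ...) {
  cat(sprintf("<v2p_model> %s; %d epochs trained, final val loss %.4g\n",
              x$kind, length(x$history$val), min(x$history$val)))
  invisible(x)
}

train_lstm <- function(cfg, x, y) {
  W <- cfg$input_units
  n_win <- length(x) - W
  if (n_win < 10L) stop("calibration series too short for the window length",
                        call. = FALSE)
  X <- matrix(0, n_win, W)
  for (t in seq_len(n_win)) X[t, ] <- x[t:(t + W - 1L)]
  yy <- y[W + seq_len(n_win)]
  n_val <- max(1L, floor(0.2 * n_win))
  idx_val <- seq.int(n_win - n_val + 1L, n_win)
  idx_tr <- seq_len(n_win - n_val)
  params <- lstm_stack_init(cfg)
  opt <- adam_state(lstm_zero_grads(params))
  best <- list(val = Inf, params = params)
  hist_tr <- numeric(0); hist_val <- numeric(0)
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(idx_tr)
    bsz <- min(cfg$batch, length(ord))
    losses <- numeric(0)
    for (s in seq.int(1L, length(ord), by = bsz)) {
      take <- ord[s:min(s + bsz - 1L, length(ord))]
      fw <- lstm_stack_forward(params, X[take, , drop = FALSE], keep_cache = TRUE)
      losses <- c(losses, mean((fw$pred - yy[take])^2))
      gr <- lstm_stack_backward(params, X[take, , drop = FALSE], yy[take], fw)
      up <- adam_update(params, gr, opt, cfg$lr)
      params <- up$params; opt <- up$state
    }
    val <- mean((lstm_stack_forward(params, X[idx_val, , drop = FALSE])$pred -
                   yy[idx_val])^2)
    hist_tr <- c(hist_tr, mean(losses)); hist_val <- c(hist_val, val)
    if (val < best$val - 1e-6) {
      best <- list(val = val, params = params); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  list(params = best$params, history = list(train = hist_tr, val = hist_val))
}

#' Reconstruct PPG (or fiducial classes) from a composite landmark signal
#'
#' Applies a calibrated model feed-forward. For the LSTM, the composite
#' signal is edge-padded by one window so the output covers every frame, and
#' the prediction is returned on the calibration PPG scale; fiducials are
#' then located with the same derivative analysis used on native PPG. For
#' the dilated CNN the per-sample argmax over `{none, m1..m4}` is returned,
#' and m1 times are read off the class sequence directly.
#'
#' @param model a `v2p_model`.
#' @param mu a `composite_signal` at the model's frame rate.
#' @return object of class `v2p_reconstruction`: `values` (predicted PPG,
#'   a.u.), `fps`, `waveforms` (compliant beats with extrema), `m1_times`,
#'   `degenerate` flag, and for the CNN head `classes`.
#' @export
v2p_reconstruct <- function(model, mu) {
  stopifnot(inherits(model, "v2p_model"), inherits(mu, "composite_signal"))
  x <- mu$values
  if (model$kind == "lstm") {
    W <- model$cfg$input_units
    if (length(x) < W) stop("series shorter than the model window", call. = FALSE)
    xp <- c(rep(x[1], W - 1L), x)
    n_out <- length(x)
    X <- matrix(0, n_out, W)
    for (t in seq_len(n_out)) X[t, ] <- xp[t:(t + W - 1L)]
    pred_z <- lstm_stack_forward(model$params, X)$pred
    values <- pred_z * model$target_norm["sd"] + model$target_norm["mean"]
    names(values) <- NULL
    if (stats::sd(pred_z) < 1e-6) {
      return(structure(list(values = values, fps = model$fps, waveforms = list(),
                            m1_times = numeric(0), degenerate = TRUE),
                       class = "v2p_reconstruction"))
    }
    # beat timing by template matched filtering: on a noisy reconstruction
    # the whole-beat correlation localizes onsets far better than the flat
    # onset valley; full fiducial sets still come from derivative analysis
    m1 <- beat_anchor_times(values, model$fps)
    segs <- segment_waveforms(values, model$fps)
    if (length(m1) < 2L) m1 <- vapply(segs, function(w) w$start_time, numeric(1))
    waves <- Filter(function(w) isTRUE(w$compliant), lapply(segs, detect_extrema))
    structure(list(values = values, fps = model$fps, waveforms = waves,
                   m1_times = m1, degenerate = FALSE),
              class = "v2p_reconstruction")
  } else {
    rf <- tdcnn_receptive_field(model$cfg)$receptive_field
    if (length(x) < model$cfg$kernel)
      stop("series shorter than the model receptive footprint", call. = FALSE)
    probs <- tdcnn_forward(model$params, matrix(x, ncol = 1L),
                           model$cfg, train = FALSE)$probs
    cls <- max.col(probs) - 1L  # 0 = none, 1..4 = m1..m4
    m1 <- (which(cls == 1L) - 1L) / model$fps
    structure(list(values = NULL, fps = model$fps, classes = cls,
                   waveforms = list(), m1_times = m1,
                   degenerate = length(unique(cls)) == 1L,
                   receptive_field = rf),
              class = "v2p_reconstruction")
  }
}

#' @export
print.v2p_reconstruction <- function(x, ...) {
  cat(sprintf("<v2p_reconstruction> %s; %d beats located%s\n",
              if (is.null(x$values)) "fiducial classes" else
                sprintf("%d predicted samples", length(x$values)),
              length(x$m1_times),
              if (isTRUE(x$degenerate)) " [degenerate input]" else ""))
  invisible(x)
}

# Per-sample 5-class labels {0 none, 1..4 m1..m4} from ground-truth extrema.
fiducial_class_labels <- function(ppg, fps, n) {
  lab <- integer(n)
  te <- ppg$true_extrema
  codes <- c(m1 = 1L, m2 = 2L, m3 = 3L, m4 = 4L)
  for (r in seq_len(nrow(te))) {
    i <- round(te$t[r] * fps) + 1L
    if (i >= 1L && i <= n) lab[i] <- codes[[te$name[r]]]
  }
  lab
}

# ---- internal: dilated causal temporal CNN --------------------------------

tdcnn_init <- function(cfg) {
  d <- tdcnn_receptive_field(cfg)$dilations
  sc <- function(fan_in) sqrt(1 / fan_in)
  blocks <- lapply(seq_len(cfg$blocks), function(b) {
    cin <- if (b == 1L) 1L else cfg$channels
    s1 <- sc(cin * cfg$kernel); s2 <- sc(cfg$channels * cfg$kernel)
    list(
      W1 = array(stats::runif(cfg$kernel * cin * cfg$channels, -s1, s1),
                 dim = c(cfg$kernel, cin, cfg$channels)),
      b1 = rep(0, cfg$channels),
      W2 = array(stats::runif(cfg$kernel * cfg$channels * cfg$channels, -s2, s2),
                 dim = c(cfg$kernel, cfg$channels, cfg$channels)),
      b2 = rep(0, cfg$channels),
      Wres = if (b == 1L)
        matrix(stats::runif(cfg$channels, -1, 1), nrow = 1L) else NULL,
      dilation = d[b])
  })
  list(blocks = blocks,
       W_head = matrix(stats::runif(cfg$channels * 5L, -sc(cfg$channels),
                                    sc(cfg$channels)), nrow = cfg$channels),
       b_head = rep(0, 5L))
}

# Causal dilated convolution: y[t, ] = sum_j x[t - j*d, ] %*% W[j+1, , ].
conv1d_causal <- function(x, W, b, d) {
  Tn <- nrow(x); k <- dim(W)[1L]
  y <- matrix(rep(b, each = Tn), nrow = Tn)
  for (j in seq_len(k)) {
    shift <- (j - 1L) * d
    if (shift >= Tn) next
    rows <- seq_len(Tn - shift)
    Wj <- matrix(W[j, , ], nrow = dim(W)[2L])
    y[rows + shift, ] <- y[rows + shift, ] +
      x[rows, , drop = FALSE] %*% Wj
  }
  y
}

conv1d_causal_backward <- function(x, W, d, dy) {
  Tn <- nrow(x); k <- dim(W)[1L]
  dW <- 0 * W
  dx <- matrix(0, nrow = Tn, ncol = dim(W)[2L])
  for (j in seq_len(k)) {
    shift <- (j - 1L) * d
    if (shift >= Tn) next
    rows <- seq_len(Tn - shift)
    Wj <- matrix(W[j, , ], nrow = dim(W)[2L])
    dW[j, , ] <- t(x[rows, , drop = FALSE]) %*% dy[rows + shift, , drop = FALSE]
    dx[rows, ] <- dx[rows, ] +
      dy[rows + shift, , drop = FALSE] %*% t(Wj)
  }
  list(dW = dW, db = colSums(dy), dx = dx)
}

tdcnn_forward <- function(params, x, cfg, train = FALSE) {
  h <- x
  caches <- vector("list", length(params$blocks))
  for (b in seq_along(params$blocks)) {
    blk <- params$blocks[[b]]
    a1 <- conv1d_causal(h, blk$W1, blk$b1, blk$dilation)
    m1 <- if (train && cfg$dropout > 0)
      (stats::runif(ncol(a1)) >= cfg$dropout) / (1 - cfg$dropout) else
        rep(1, ncol(a1))
    a1d <- sweep(a1, 2L, m1, `*`)
    a2 <- conv1d_causal(a1d, blk$W2, blk$b2, blk$dilation)
    r <- pmax(a2, 0)
    m2 <- if (train && cfg$dropout > 0)
      (stats::runif(ncol(r)) >= cfg$dropout) / (1 - cfg$dropout) else
        rep(1, ncol(r))
    rd <- sweep(r, 2L, m2, `*`)
    res <- if (is.null(blk$Wres)) h else h %*% blk$Wres
    out <- rd + res
    caches[[b]] <- list(h_in = h, a1d = a1d, a2 = a2, m1 = m1, m2 = m2)
    h <- out
  }
  logits <- sweep(h %*% params$W_head, 2L, params$b_head, `+`)
  probs <- softmax(logits)
  list(probs = probs, h = h, caches = caches)
}

tdcnn_backward <- function(params, x, lab, cfg, fw) {
  Tn <- nrow(fw$probs)
  onehot <- matrix(0, Tn, 5L)
  onehot[cbind(seq_len(Tn), lab + 1L)] <- 1
  # class-balanced weights: fiducial samples are rare
  wts <- ifelse(lab == 0L, 1, 8); wts <- wts / sum(wts)
  dlogits <- (fw$probs - onehot) * wts
  grads <- list(blocks = vector("list", length(params$blocks)),
                W_head = t(fw$h) %*% dlogits, b_head = colSums(dlogits))
  dh <- dlogits %*% t(params$W_head)
  for (b in seq.int(length(params$blocks), 1L)) {
    blk <- params$blocks[[b]]
    cc <- fw$caches[[b]]
    drd <- dh
    dr <- sweep(drd, 2L, cc$m2, `*`)
    da2 <- dr * (cc$a2 > 0)
    bk2 <- conv1d_causal_backward(cc$a1d, blk$W2, blk$dilation, da2)
    da1 <- sweep(bk2$dx, 2L, cc$m1, `*`)
    bk1 <- conv1d_causal_backward(cc$h_in, blk$W1, blk$dilation, da1)
    if (is.null(blk$Wres)) {
      dres_W <- NULL
      dh <- bk1$dx + dh
    } else {
      dres_W <- t(cc$h_in) %*% dh
      dh <- bk1$dx + dh %*% t(blk$Wres)
    }
    grads$blocks[[b]] <- list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW,
                              b2 = bk2$db, Wres = dres_W)
  }
  grads
}

tdcnn_zero_grads <- function(params) {
  list(blocks = lapply(params$blocks, function(blk)
    list(W1 = 0 * blk$W1, b1 = 0 * blk$b1, W2 = 0 * blk$W2, b2 = 0 * blk$b2,
         Wres = if (is.null(blk$Wres)) NULL else 0 * blk$Wres)),
    W_head = 0 * params$W_head, b_head = 0 * params$b_head)
}

train_tdcnn <- function(cfg, x, labels) {
  params <- tdcnn_init(cfg)
  opt <- adam_state(tdcnn_zero_grads(params))
  X <- matrix(x, ncol = 1L)
  hist <- numeric(0)
  n_val <- max(1L, floor(0.2 * length(x)))
  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- tdcnn_forward(params, X, cfg, train = TRUE)
    Tn <- nrow(fw$probs)
    wts <- ifelse(labels == 0L, 1, 8); wts <- wts / sum(wts)
    loss <- -sum(wts * log(pmax(fw$probs[cbind(seq_len(Tn), labels + 1L)], 1e-12)))
    gr <- tdcnn_backward(params, X, labels, cfg, fw)
    up <- adam_update(params, gr, opt, cfg$lr)
    params <- up$params; opt <- up$state
    hist <- c(hist, loss)
  }
  list(params = params, history = list(train = hist, val = hist))
}
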