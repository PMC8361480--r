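#' Eye-state CNN configuration
#'
#' The classifier consumes a single 77x77 grayscale eye patch. Three 3x3
#' convolution layers of 32, 64 and 128 filters, each followed by batch
#' normalization and ReLU, with 2x2 max pooling after the first two
#' convolutions only (77 -> 38 -> 19 spatially), then one dense layer and a
#' two-way softmax. Training uses Adam with cross-entropy loss.
#'
#' @param filters convolution filter counts.
#' @param dense width of the hidden dense layer.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @return list of class `eye_cnn_config`.
#' @export
eye_cnn_config <- function(filters = c(32L, 64L, 128L), dense = 128L,
                           lr = 0.001, batch = 32L, epochs = 100L, seed = 1L) {
  stopifnot(length(filters) == 3L, all(filters >= 1L), dense >= 1L,
            lr > 0, batch >= 1L, epochs >= 1L)
  structure(list(filters = as.integer(filters), dense = as.integer(dense),
                 lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 input = c(77L, 77L, 1L)),
            class = "eye_cnn_config")
}

# Spatial sizes through the stack: conv layers pad "same"; 2x2/2 pooling
# floors odd sizes (77 -> 38 -> 19).
eye_cnn_shapes <- function(cfg) {
  s1 <- 77L; p1 <- s1 %/% 2L  # 38
  p2 <- p1 %/% 2L             # 19
  list(conv = c(s1, p1, p2), flat = p2 * p2 * cfg$filters[3L])
}

#' Build an (untrained) eye-state CNN
#'
#' @param cfg an [eye_cnn_config()].
#' @param zero_init initialize all weights to zero (diagnostic use: the
#'   softmax then returns exactly (0.5, 0.5)).
#' @return object of class `eye_cnn`.
#' @export
build_eye_cnn <- function(cfg = eye_cnn_config(), zero_init = FALSE) {
  shapes <- eye_cnn_shapes(cfg)
  he <- function(k, cin, cout) {
    s <- sqrt(2 / (k * k * cin))
    v <- if (zero_init) rep(0, k * k * cin * cout) else
      stats::rnorm(k * k * cin * cout, 0, s)
    array(v, dim = c(k * k, cin, cout))
  }
  dmat <- function(nin, nout) {
    s <- sqrt(2 / nin)
    if (zero_init) matrix(0, nin, nout) else
      matrix(stats::rnorm(nin * nout, 0, s), nin, nout)
  }
  cin <- c(1L, cfg$filters[1:2])
  params <- with_seed(cfg$seed, list(
    conv = lapply(1:3, function(l) list(
      W = he(3L, cin[l], cfg$filters[l]),
      b = rep(0, cfg$filters[l]),
      gamma = rep(1, cfg$filters[l]),
      beta = rep(0, cfg$filters[l]))),
    W_d = dmat(shapes$flat, cfg$dense),
    b_d = rep(0, cfg$dense),
    W_o = dmat(cfg$dense, 2L),
    b_o = rep(0, 2L)))
  bn <- lapply(cfg$filters, function(f)
    list(mean = rep(0, f), var = rep(1, f)))
  structure(list(cfg = cfg, params = params, bn_running = bn,
                 trained = FALSE, classes = c("wakeful", "drowsy")),
            class = "eye_cnn")
}

#' @export
print.eye_cnn <- function(x, ...) {
  cat(sprintf("<eye_cnn> conv %s, dense %d, %strained\n",
              paste(x$cfg$filters, collapse = "/"), x$cfg$dense,
              if (x$trained) "" else "un"))
  invisible(x)
}

# ---- internal: conv/pool/BN machinery on (B, H, W, C) arrays --------------

# "same"-padded 3x3 convolution via 9 shifted slice products.
conv2d_same <- function(A, W, b) {
  dB <- dim(A); B <- dB[1L]; H <- dB[2L]; Wd <- dB[3L]; Cin <- dB[4L]
  Cout <- dim(W)[3L]
  Y <- array(rep(b, each = B * H * Wd), dim = c(B, H, Wd, Cout))
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    ri <- max(1L, 1L - dy):min(H, H - dy)
    ci <- max(1L, 1L - dx):min(Wd, Wd - dx)
    src <- A[, ri + dy, ci + dx, , drop = FALSE]
    m <- matrix(src, ncol = Cin)
    res <- m %*% matrix(W[k, , ], nrow = Cin)
    Y[, ri, ci, ] <- Y[, ri, ci, , drop = FALSE] +
      array(res, dim = c(B, length(ri), length(ci), Cout))
  }
  Y
}

conv2d_same_backward <- function(A, W, dY) {
  dB <- dim(A); B <- dB[1L]; H <- dB[2L]; Wd <- dB[3L]; Cin <- dB[4L]
  dW <- 0 * W
  dA <- array(0, dim = dB)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    ri <- max(1L, 1L - dy):min(H, H - dy)
    ci <- max(1L, 1L - dx):min(Wd, Wd - dx)
    src <- matrix(A[, ri + dy, ci + dx, , drop = FALSE], ncol = Cin)
    dYs <- matrix(dY[, ri, ci, , drop = FALSE], ncol = dim(W)[3L])
    dW[k, , ] <- t(src) %*% dYs
    dA[, ri + dy, ci + dx, ] <- dA[, ri + dy, ci + dx, , drop = FALSE] +
      array(dYs %*% t(matrix(W[k, , ], nrow = Cin)),
            dim = c(B, length(ri), length(ci), Cin))
  }
  list(dW = dW, db = colSums(matrix(dY, ncol = dim(W)[3L])), dA = dA)
}

# 2x2 max pool, stride 2, floor on odd sizes.
maxpool2 <- function(A) {
  dB <- dim(A); B <- dB[1L]; H <- dB[2L]; W <- dB[3L]; C <- dB[4L]
  Hp <- H %/% 2L; Wp <- W %/% 2L
  i1 <- seq.int(1L, 2L * Hp, by = 2L); j1 <- seq.int(1L, 2L * Wp, by = 2L)
  s <- list(A[, i1, j1, , drop = FALSE], A[, i1 + 1L, j1, , drop = FALSE],
            A[, i1, j1 + 1L, , drop = FALSE], A[, i1 + 1L, j1 + 1L, , drop = FALSE])
  Y <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  # first slot achieving the max wins (tie-break)
  which_max <- array(4L, dim = dim(Y))
  for (q in 3:1) which_max[s[[q]] == Y] <- q
  list(Y = Y, arg = which_max, in_dim = dB)
}

maxpool2_backward <- function(pool, dY) {
  dA <- array(0, dim = pool$in_dim)
  Hp <- dim(dY)[2L]; Wp <- dim(dY)[3L]
  i1 <- seq.int(1L, 2L * Hp, by = 2L); j1 <- seq.int(1L, 2L * Wp, by = 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (q in 1:4) {
    mask <- pool$arg == q
    tmp <- array(0, dim = dim(dY))
    tmp[mask] <- dY[mask]
    dA[, i1 + offs[[q]][1L], j1 + offs[[q]][2L], ] <-
      dA[, i1 + offs[[q]][1L], j1 + offs[[q]][2L], , drop = FALSE] + tmp
  }
  dA
}

bn_forward <- function(A, gamma, beta, running, train, momentum = 0.9,
                       eps = 1e-5) {
  C <- dim(A)[4L]
  m2 <- matrix(A, ncol = C)
  if (train) {
    mu <- colMeans(m2)
    va <- colMeans(sweep(m2, 2L, mu)^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * va
  } else {
    mu <- running$mean; va <- running$var
  }
  xhat <- sweep(sweep(m2, 2L, mu), 2L, sqrt(va + eps), `/`)
  out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(Y = array(out, dim = dim(A)), xhat = xhat, mu = mu, va = va,
       running = running, eps = eps)
}

bn_backward <- function(cache, gamma, dY) {
  C <- length(gamma)
  dy <- matrix(dY, ncol = C)
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  iv <- 1 / sqrt(cache$va + cache$eps)
  dx <- sweep(dxhat - rep(1 / n, n) %o% colSums(dxhat) -
                cache$xhat * (rep(1 / n, n) %o% colSums(dxhat * cache$xhat)),
              2L, iv, `*`)
  list(dA = array(dx, dim = dim(dY)), dgamma = dgamma, dbeta = dbeta)
}

eye_cnn_forward <- function(model, A, train = FALSE) {
  p <- model$params
  caches <- list()
  h <- A
  for (l in 1:3) {
    cv <- conv2d_same(h, p$conv[[l]]$W, p$conv[[l]]$b)
    bn <- bn_forward(cv, p$conv[[l]]$gamma, p$conv[[l]]$beta,
                     model$bn_running[[l]], train)
    if (train) model$bn_running[[l]] <- bn$running
    r <- pmax(bn$Y, 0)
    pool <- if (l < 3L) maxpool2(r) else NULL
    caches[[l]] <- list(h_in = h, bn = bn, relu_in = bn$Y, pool = pool)
    h <- if (l < 3L) pool$Y else r
  }
  flat <- matrix(h, nrow = dim(h)[1L])
  d1 <- sweep(flat %*% p$W_d, 2L, p$b_d, `+`)
  d1r <- pmax(d1, 0)
  logits <- sweep(d1r %*% p$W_o, 2L, p$b_o, `+`)
  probs <- softmax(logits)
  list(probs = probs, caches = caches, flat = flat, d1 = d1, d1r = d1r,
       h_dim = dim(h), model = model)
}

eye_cnn_backward <- function(model, fw, y_onehot) {
  p <- model$params
  B <- nrow(fw$probs)
  dlogits <- (fw$probs - y_onehot) / B
  g <- list(conv = vector("list", 3L))
  g$W_o <- t(fw$d1r) %*% dlogits
  g$b_o <- colSums(dlogits)
  dd1r <- dlogits %*% t(p$W_o)
  dd1 <- dd1r * (fw$d1 > 0)
  g$W_d <- t(fw$flat) %*% dd1
  g$b_d <- colSums(dd1)
  dh <- array(dd1 %*% t(p$W_d), dim = fw$h_dim)
  for (l in 3:1) {
    cc <- fw$caches[[l]]
    if (l < 3L) dh <- maxpool2_backward(cc$pool, dh)
    dr <- dh * (cc$relu_in > 0)
    bnb <- bn_backward(cc$bn, p$conv[[l]]$gamma, dr)
    cvb <- conv2d_same_backward(cc$h_in, p$conv[[l]]$W, bnb$dA)
    g$conv[[l]] <- list(W = cvb$dW, b = cvb$db,
                        gamma = bnb$dgamma, beta = bnb$dbeta)
    dh <- cvb$dA
  }
  g
}

#' Train the eye-state CNN
#'
#' Minibatch Adam on softmax cross-entropy. Patches are matrices in `[0, 1]`;
#' labels follow the `wakeful`/`drowsy` convention of
#' [simulate_eye_patches()].
#'
#' @param patches list of 77x77 matrices.
#' @param labels factor/character labels (both classes must be present).
#' @param cfg an [eye_cnn_config()].
#' @return a trained `eye_cnn`.
#' @export
train_eye_cnn <- function(patches, labels, cfg = eye_cnn_config()) {
  labels <- as.character(labels)
  stopifnot(length(patches) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  model <- build_eye_cnn(cfg)
  n <- length(patches)
  A_all <- array(0, dim = c(n, 77L, 77L, 1L))
  for (i in seq_len(n)) A_all[i, , , 1L] <- patches[[i]]
  y <- match(labels, model$classes) - 1L
  grads_template <- NULL
  opt <- NULL
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n)
      for (s in seq.int(1L, n, by = cfg$batch)) {
        take <- ord[s:min(s + cfg$batch - 1L, n)]
        A <- A_all[take, , , , drop = FALSE]
        oh <- matrix(0, length(take), 2L)
        oh[cbind(seq_along(take), y[take] + 1L)] <- 1
        fw <- eye_cnn_forward(model, A, train = TRUE)
        model$bn_running <- fw$model$bn_running
        g <- eye_cnn_backward(model, fw, oh)
        if (is.null(opt)) opt <- adam_state(g)
        up <- adam_update(model$params, g, opt, cfg$lr)
        model$params <- up$params; opt <- up$state
      }
    }
  })
  model$trained <- TRUE
  model
}

#' Classify eye patches
#'
#' @param model a trained `eye_cnn`.
#' @param patches a single 77x77 matrix or a list of them.
#' @return data frame with `state` and the two class probabilities.
#' @export
classify_eye <- function(model, patches) {
  stopifnot(inherits(model, "eye_cnn"))
  if (is.matrix(patches)) patches <- list(patches)
  for (im in patches)
    if (!all(dim(im) == c(77L, 77L)))
      stop("patches must be 77x77", call. = FALSE)
  n <- length(patches)
  A <- array(0, dim = c(n, 77L, 77L, 1L))
  for (i in seq_len(n)) A[i, , , 1L] <- patches[[i]]
  probs <- eye_cnn_forward(model, A, train = FALSE)$probs
  data.frame(state = model$classes[max.col(probs)],
             p_wakeful = probs[, 1L], p_drowsy = probs[, 2L])
}
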