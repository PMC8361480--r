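#' Modified augmentation index of a beat
#'
#' `mAI = ((y_m3 - y_m1) - y_m4) / (y_m3 - y_m1)`, computed literally on the
#' ordered fiducial amplitudes (onset minimum, systolic peak, dicrotic notch,
#' diastolic peak). The index is undefined when the notch amplitude equals
#' the onset amplitude.
#'
#' @param w a `ppg_waveform` with all four extrema set.
#' @return the index (dimensionless).
#' @export
compute_mai <- function(w) {
  stopifnot(inherits(w, "ppg_waveform"))
  if (is.null(w$extrema) || nrow(w$extrema) < 4L)
    stop("beat has no complete fiducial set", call. = FALSE)
  y <- stats::setNames(w$extrema$y, w$extrema$name)
  denom <- y[["m3"]] - y[["m1"]]
  if (abs(denom) < 1e-12)
    stop("mAI undefined: notch amplitude equals onset amplitude", call. = FALSE)
  ((y[["m3"]] - y[["m1"]]) - y[["m4"]]) / denom
}

#' Per-pair beat features for blood-pressure classification
#'
#' For a pair of consecutive beats j, j+1 the feature set packs the four
#' fiducial coordinates of beat j (times onset-relative, so features do not
#' depend on where the pair sits in the recording), the per-fiducial
#' displacements `dx_i = x_i^{j+1} - x_i^j` (absolute times, i.e. about one
#' beat period for identical beats) and `dy_i = y_i^{j+1} - y_i^j`, and the
#' modified augmentation index of beat j.
#'
#' @param w_j,w_j1 consecutive `ppg_waveform`s with all four extrema.
#' @return object of class `beat_pair_features`: `coords` (4 x 2 matrix of
#'   onset-relative time and amplitude), `dx`, `dy` (length 4, seconds and
#'   a.u.), `mai`.
#' @export
beat_pair_features <- function(w_j, w_j1) {
  for (w in list(w_j, w_j1))
    if (is.null(w$extrema) || nrow(w$extrema) < 4L)
      stop("both beats must carry all four extrema", call. = FALSE)
  e0 <- w_j$extrema; e1 <- w_j1$extrema
  structure(list(
    coords = cbind(x = e0$t - e0$t[1L], y = e0$y),
    dx = e1$t - e0$t,
    dy = e1$y - e0$y,
    mai = compute_mai(w_j)),
    class = "beat_pair_features")
}

#' Assemble the 64-element phi input vector
#'
#' Each beat pair contributes 17 values (8 onset-relative coordinates, 4 dx,
#' 4 dy, 1 mAI); up to three consecutive pairs are concatenated (51 values)
#' and the vector is zero-padded to the network's 64-unit input width. With
#' fewer pairs the remaining slots are zero.
#'
#' @param pairs list of [beat_pair_features()] (at least one).
#' @param center,scale optional length-64 standardization constants from a
#'   calibration cohort.
#' @return numeric vector of length 64.
#' @export
assemble_phi <- function(pairs, center = NULL, scale = NULL) {
  if (inherits(pairs, "beat_pair_features")) pairs <- list(pairs)
  if (length(pairs) < 1L) stop("need at least one beat pair", call. = FALSE)
  pairs <- pairs[seq_len(min(3L, length(pairs)))]
  v <- unlist(lapply(pairs, function(p)
    c(t(p$coords), p$dx, p$dy, p$mai)), use.names = FALSE)
  phi <- c(v, rep(0, 64L - length(v)))
  if (!is.null(center)) phi <- phi - center
  if (!is.null(scale)) phi <- phi / ifelse(scale == 0, 1, scale)
  phi
}

#' Blood-pressure reference calibration
#'
#' The normal band is the reference pressure plus/minus the fractional
#' tolerance; 120/80 mmHg with 15% is the default working point.
#'
#' @param ref_sbp,ref_dbp reference systolic/diastolic pressure (mmHg).
#' @param tolerance fractional band half-width in (0, 1).
#' @return object of class `bp_calibration`.
#' @export
bp_calibration <- function(ref_sbp = 120, ref_dbp = 80, tolerance = 0.15) {
  stopifnot(ref_sbp > 0, ref_dbp > 0, tolerance > 0, tolerance < 1)
  structure(list(ref_sbp = ref_sbp, ref_dbp = ref_dbp, tolerance = tolerance),
            class = "bp_calibration")
}

#' Label a pressure reading against the calibrated reference
#'
#' Abnormal iff the systolic value falls outside `[0.85, 1.15] * ref_sbp` or
#' the diastolic value outside `[0.85, 1.15] * ref_dbp` (boundary values are
#' normal).
#'
#' @param sbp,dbp measured pressures in mmHg.
#' @param cal a [bp_calibration()].
#' @return `"normal"` or `"abnormal"`.
#' @export
label_from_reference <- function(sbp, dbp, cal = bp_calibration()) {
  stopifnot(sbp > 0, dbp > 0)
  lo <- 1 - cal$tolerance; hi <- 1 + cal$tolerance
  out_s <- sbp < lo * cal$ref_sbp | sbp > hi * cal$ref_sbp
  out_d <- dbp < lo * cal$ref_dbp | dbp > hi * cal$ref_dbp
  ifelse(out_s | out_d, "abnormal", "normal")
}

#' Train the shallow blood-pressure network
#'
#' A fully connected 64-500-300-1 network with logistic activations
#' throughout and a cross-entropy loss, trained full-batch with scaled
#' conjugate gradient (SCG). The scalar output is read as a flag: values in
#' `[0, 0.5]` mean pressure within the norm, values above 0.5 abnormal.
#'
#' @param X numeric matrix (rows = phi vectors, 64 columns).
#' @param y labels: factor/character with values `normal`/`abnormal`, or 0/1.
#' @param hidden hidden layer widths.
#' @param max_iter SCG iteration cap.
#' @param seed integer seed for initialization.
#' @return object of class `snn_model`.
#' @export
train_snn <- function(X, y, hidden = c(500L, 300L), max_iter = 120L, seed = 1L) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) y <- as.integer(as.character(y) == "abnormal")
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  stopifnot(nrow(X) == length(y))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  sizes <- c(ncol(X), hidden, 1L)
  params <- with_seed(seed, lapply(seq_len(length(sizes) - 1L), function(l) {
    s <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    list(W = matrix(stats::runif(sizes[l] * sizes[l + 1L], -s, s), sizes[l]),
         b = rep(0, sizes[l + 1L]))
  }))
  flat <- snn_flatten(params)
  loss_fn <- function(w) snn_loss_grad(w, sizes, Xs, y)$loss
  grad_fn <- function(w) snn_loss_grad(w, sizes, Xs, y)$grad
  fit <- scg_optimize(flat, loss_fn, grad_fn, max_iter = max_iter)
  structure(list(par = fit$par, sizes = sizes, center = ctr, scale = scl,
                 loss = fit$loss, iterations = fit$iterations,
                 optimizer = "scaled conjugate gradient"),
            class = "snn_model")
}

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf("<snn_model> %s; %d SCG iterations, final loss %.4g\n",
              paste(x$sizes, collapse = "-"), x$iterations, x$loss))
  invisible(x)
}

#' Classify a phi vector (or matrix) with a trained network
#'
#' @param model an `snn_model`.
#' @param phi length-64 vector or matrix with 64 columns.
#' @return data frame with `output` (network value in `[0, 1]`), `flag`
#'   (1 = abnormal iff output > 0.5) and `label`.
#' @export
classify_bp <- function(model, phi) {
  stopifnot(inherits(model, "snn_model"))
  X <- if (is.matrix(phi)) phi else matrix(phi, nrow = 1L)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  out <- snn_forward(model$par, model$sizes, Xs)
  flag <- as.integer(out > 0.5)
  data.frame(output = out, flag = flag,
             label = ifelse(flag == 1L, "abnormal", "normal"))
}

# ---- internal: MLP forward/backward and SCG -------------------------------

snn_flatten <- function(params)
  unlist(lapply(params, function(l) c(l$W, l$b)), use.names = FALSE)

snn_unflatten <- function(w, sizes) {
  out <- list(); pos <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nW <- sizes[l] * sizes[l + 1L]
    W <- matrix(w[pos + seq_len(nW)], sizes[l]); pos <- pos + nW
    b <- w[pos + seq_len(sizes[l + 1L])]; pos <- pos + sizes[l + 1L]
    out[[l]] <- list(W = W, b = b)
  }
  out
}

snn_forward <- function(w, sizes, X) {
  params <- snn_unflatten(w, sizes)
  a <- X
  for (l in seq_along(params))
    a <- sigmoid(sweep(a %*% params[[l]]$W, 2L, params[[l]]$b, `+`))
  as.numeric(a)
}

snn_loss_grad <- function(w, sizes, X, y) {
  params <- snn_unflatten(w, sizes)
  acts <- list(X)
  a <- X
  for (l in seq_along(params)) {
    a <- sigmoid(sweep(a %*% params[[l]]$W, 2L, params[[l]]$b, `+`))
    acts[[l + 1L]] <- a
  }
  out <- as.numeric(a)
  n <- length(y)
  eps <- 1e-12
  loss <- -mean(y * log(out + eps) + (1 - y) * log(1 - out + eps))
  # logistic output + cross-entropy: delta at the output is (out - y)/n
  delta <- matrix((out - y) / n, ncol = 1L)
  grads <- vector("list", length(params))
  for (l in seq.int(length(params), 1L)) {
    grads[[l]] <- list(W = t(acts[[l]]) %*% delta, b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * acts[[l]] * (1 - acts[[l]])
    }
  }
  list(loss = loss, grad = snn_flatten(grads))
}

# Moller's scaled conjugate gradient for unconstrained minimization.
scg_optimize <- function(w, fn, gr, max_iter = 200L, tol = 1e-6) {
  sigma0 <- 1e-4
  lambda <- 1e-6; lambda_bar <- 0
  r <- -gr(w); p <- r
  fw <- fn(w)
  success <- TRUE
  delta <- 0
  n_par <- length(w)
  k_since_restart <- 0L
  for (k in seq_len(max_iter)) {
    p2 <- sum(p^2)
    if (p2 < 1e-20) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      s <- (gr(w + sigma * p) + r) / sigma  # r = -grad(w)
      delta <- sum(p * s)
    }
    delta_adj <- delta + (lambda - lambda_bar) * p2
    if (delta_adj <= 0) {
      lambda_bar <- 2 * (lambda - delta_adj / p2)
      delta_adj <- -delta_adj + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_adj
    f_new <- fn(w + alpha * p)
    Delta <- 2 * delta_adj * (fw - f_new) / mu^2
    if (Delta >= 0) {
      w <- w + alpha * p
      fw <- f_new
      r_new <- -gr(w)
      lambda_bar <- 0
      success <- TRUE
      k_since_restart <- k_since_restart + 1L
      if (k_since_restart >= n_par) {
        p <- r_new; k_since_restart <- 0L
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta_adj * (1 - Delta) / p2
    if (lambda > 1e10) lambda <- 1e10
    if (sqrt(sum(r^2)) < tol) break
  }
  list(par = w, loss = fw, iterations = k)
}

#' Phi feature matrix from a labeled beat cohort
#'
#' Forms consecutive same-class beat pairs, groups them in threes and
#' assembles one phi vector per group; the group label is the class of its
#' beats.
#'
#' @param waveforms list of `ppg_waveform`s with extrema.
#' @param labels parallel class labels.
#' @return list with `X` (matrix, 64 columns) and `y` (factor).
#' @export
phi_matrix <- function(waveforms, labels) {
  stopifnot(length(waveforms) == length(labels))
  labels <- as.character(labels)
  X <- NULL; y <- character(0)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    pairs <- lapply(seq_len(length(idx) - 1L), function(k)
      beat_pair_features(waveforms[[idx[k]]], waveforms[[idx[k + 1L]]]))
    grp <- split(pairs, (seq_along(pairs) - 1L) %/% 3L)
    for (g in grp) {
      X <- rbind(X, assemble_phi(g))
      y <- c(y, cls)
    }
  }
  list(X = X, y = factor(y))
}
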