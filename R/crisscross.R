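#' Criss-cross path of a grid position
#'
#' All positions sharing row or column with `u`, with `u` itself counted
#' exactly once: first the full row left-to-right, then the column
#' top-to-bottom excluding `u`. The path length is always `H + W - 1`.
#'
#' @param u integer pair `c(row, col)` (1-based).
#' @param H,W grid size.
#' @return a `(H + W - 1) x 2` matrix of (row, col) positions.
#' @export
criss_cross_path <- function(u, H, W) {
  r <- u[1L]; c <- u[2L]
  if (r < 1L || r > H || c < 1L || c > W)
    stop("position lies outside the grid", call. = FALSE)
  row_part <- cbind(r, seq_len(W))
  col_part <- if (H > 1L) cbind(seq_len(H)[-r], c) else NULL
  path <- rbind(row_part, col_part)
  dimnames(path) <- NULL
  path
}

# Linear (column-major) index of grid positions, consistent with R arrays.
grid_index <- function(pos, H) (pos[, 2L] - 1L) * H + pos[, 1L]

#' Affinity between query and key maps along criss-cross paths
#'
#' For every position `u`, the affinity `D[i, u]` is the inner product of the
#' query vector `F1[, u]` with the key vector at the i-th position of `u`'s
#' criss-cross path in `F2`.
#'
#' @param F1,F2 `C' x H x W` arrays (reduced-channel query/key maps).
#' @return a `(H + W - 1) x (H * W)` affinity matrix of class `affinity_map`.
#' @export
cc_affinity <- function(F1, F2) {
  if (!identical(dim(F1), dim(F2)))
    stop("query and key maps must share dimensions", call. = FALSE)
  d <- dim(F1); H <- d[2L]; W <- d[3L]
  D <- matrix(0, H + W - 1L, H * W)
  F1m <- matrix(F1, nrow = d[1L])  # C' x (H*W), column-major spatial index
  F2m <- matrix(F2, nrow = d[1L])
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    u <- (cc - 1L) * H + rr
    path <- criss_cross_path(c(rr, cc), H, W)
    idx <- grid_index(path, H)
    D[, u] <- crossprod(F2m[, idx, drop = FALSE], F1m[, u])
  }
  structure(D, class = "affinity_map", H = H, W = W)
}

#' Softmax attention map from affinities
#'
#' Softmax along the path axis, independently for every position, so each
#' position's `H + W - 1` attention weights sum to one.
#'
#' @param D an affinity matrix from [cc_affinity()].
#' @return matrix of the same shape with unit column sums.
#' @export
cc_attention_map <- function(D) {
  stopifnot(all(is.finite(D)))
  A <- apply(D, 2L, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
  A <- matrix(A, nrow = nrow(D))
  attributes(A)[c("H", "W")] <- attributes(D)[c("H", "W")]
  A
}

#' Aggregate the value map under the attention weights
#'
#' `H'[, u] = sum_i A[i, u] * theta[, path_i(u)] + H_in[, u]`: a weighted sum
#' of the value vectors along each position's criss-cross path, plus the
#' residual input feature.
#'
#' @param A attention map from [cc_attention_map()].
#' @param theta `C x H x W` value map.
#' @param H_in `C x H x W` input feature map (residual term).
#' @return `C x H x W` output array.
#' @export
cc_aggregate <- function(A, theta, H_in) {
  if (!identical(dim(theta), dim(H_in)))
    stop("value and input maps must share dimensions", call. = FALSE)
  d <- dim(theta); H <- d[2L]; W <- d[3L]
  if (nrow(A) != H + W - 1L || ncol(A) != H * W)
    stop("attention map does not match the grid", call. = FALSE)
  Tm <- matrix(theta, nrow = d[1L])
  out <- matrix(H_in, nrow = d[1L])
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    u <- (cc - 1L) * H + rr
    idx <- grid_index(criss_cross_path(c(rr, cc), H, W), H)
    out[, u] <- out[, u] + Tm[, idx, drop = FALSE] %*% A[, u]
  }
  array(out, dim = d)
}

#' Parameters of the criss-cross attention layer
#'
#' 1x1 convolutions producing the reduced query/key maps (`C' = max(1, C/8)`)
#' and the full-channel value map.
#'
#' @param C input channel count.
#' @param seed integer seed.
#' @return list with `W_q`, `W_k` (`C' x C`) and `W_v` (`C x C`).
#' @export
cc_params <- function(C, seed = 1L) {
  Cp <- max(1L, C %/% 8L)
  with_seed(seed, list(
    W_q = matrix(stats::rnorm(Cp * C, 0, 1 / sqrt(C)), Cp),
    W_k = matrix(stats::rnorm(Cp * C, 0, 1 / sqrt(C)), Cp),
    W_v = matrix(stats::rnorm(C * C, 0, 1 / sqrt(C)), C)))
}

# Apply a 1x1 convolution (channel mixing) to a C x H x W array.
conv1x1 <- function(Wm, A) {
  d <- dim(A)
  array(Wm %*% matrix(A, nrow = d[1L]), dim = c(nrow(Wm), d[2L], d[3L]))
}

#' One full criss-cross attention pass
#'
#' Query/key reduction, affinity, softmax, value remapping and residual
#' aggregation.
#'
#' @param H_in `C x H x W` feature map.
#' @param params from [cc_params()].
#' @return `C x H x W` output map.
#' @export
criss_cross_layer <- function(H_in, params) {
  F1 <- conv1x1(params$W_q, H_in)
  F2 <- conv1x1(params$W_k, H_in)
  theta <- conv1x1(params$W_v, H_in)
  A <- cc_attention_map(cc_affinity(F1, F2))
  cc_aggregate(A, theta, H_in)
}

#' Recurrent criss-cross attention
#'
#' Applies the full affinity/softmax/aggregation pass `R` times with shared
#' parameters. One pass propagates information along rows and columns only;
#' from `R = 2` every output position depends on every input position.
#'
#' @param H_in `C x H x W` feature map.
#' @param params from [cc_params()].
#' @param R number of unrolled passes (>= 1; the deployed setting is 2).
#' @return `C x H x W` output map.
#' @export
recurrent_cc <- function(H_in, params, R = 2L) {
  stopifnot(R >= 1L)
  h <- H_in
  for (i in seq_len(R)) h <- criss_cross_layer(h, params)
  h
}

#' Salience configuration and bounding-box filter
#'
#' A detection is a salient pedestrian iff at least one box dimension
#' strictly exceeds its threshold: height `> L1` (length) or width `> L2`.
#'
#' @param L1 length (height) threshold in pixels.
#' @param L2 width threshold in pixels.
#' @return object of class `salience_config`.
#' @export
salience_config <- function(L1, L2) {
  stopifnot(L1 > 0, L2 > 0)
  structure(list(L1 = L1, L2 = L2), class = "salience_config")
}

#' @rdname salience_config
#' @param boxes list of `bounding_box` objects (see [make_toy_boxes()]).
#' @param cfg a `salience_config`.
#' @return for `filter_salient_boxes`, the salient subset of `boxes`.
#' @export
filter_salient_boxes <- function(boxes, cfg) {
  stopifnot(inherits(cfg, "salience_config"))
  Filter(function(b) b$h > cfg$L1 || b$w > cfg$L2, boxes)
}
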