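# Internal numerical helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards. Every generator and trainer in the package routes its
#' randomness through this helper, so a fixed seed gives bit-identical
#' artifacts without disturbing the session stream.
#'
#' @param seed integer seed (`NULL` leaves the RNG untouched).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Softmax along rows of a matrix (or over a vector), numerically stabilized.
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window. Used for tachogram band
#' powers; segment length defaults to 120 s of samples (or the full series when
#' shorter) with 50% overlap.
#'
#' @param x numeric series (uniformly sampled).
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples; default `min(length(x), 120*fs)`.
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @keywords internal
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(120 * fs))
  seg_len <- min(seg_len, n)
  if (seg_len < 8) stop("series too short for spectral estimation", call. = FALSE)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  k <- seq_len(seg_len)
  w <- 0.5 - 0.5 * cos(2 * pi * (k - 1) / (seg_len - 1))  # Hann
  norm <- sum(w^2) * fs
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2 / norm
  }
  acc <- acc / length(starts)
  nf <- floor(seg_len / 2) + 1L
  psd <- acc[seq_len(nf)]
  if (nf > 2L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]  # fold negative freqs
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = psd)
}

# Trapezoidal integral of a PSD over [f_lo, f_hi].
band_integral <- function(freq, psd, f_lo, f_hi) {
  keep <- freq >= f_lo & freq <= f_hi
  if (sum(keep) < 2L) return(0)
  f <- freq[keep]; p <- psd[keep]
  sum(diff(f) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}

# Linear resampling of a series sampled at fs_in onto a grid at fs_out.
resample_linear <- function(x, fs_in, fs_out, duration = NULL) {
  t_in <- (seq_along(x) - 1L) / fs_in
  if (is.null(duration)) duration <- t_in[length(t_in)]
  t_out <- seq(0, duration, by = 1 / fs_out)
  t_out <- t_out[t_out <= t_in[length(t_in)] + 1e-12]
  stats::approx(t_in, x, xout = pmin(t_out, t_in[length(t_in)]))$y
}
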