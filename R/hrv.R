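#' Uniformly resampled tachogram from an IBI series
#'
#' Linearly interpolates the inter-beat intervals (assigned to the time of the
#' beat that closes each interval) onto a uniform grid and removes the mean,
#' producing the differential series whose spectrum carries the autonomic
#' LF/HF signature.
#'
#' @param ibi an [ibi_series()] with at least 8 intervals (after artifact
#'   correction).
#' @param target_fs resampling rate in Hz (default 4, comfortably above the
#'   0.4 Hz upper HRV band edge).
#' @param artifact_tol artifact-correction tolerance: intervals deviating
#'   from the median interval by more than this fraction (e.g. the
#'   double-length gap left by a discarded non-compliant beat) are excluded
#'   from the interpolation anchors, as in standard HRV artifact correction.
#'   `NULL` disables the correction.
#' @return object of class `tachogram`: `t` (s), `values` (ms, zero-mean),
#'   `fs`, `mean_ibi` (ms), `n_rejected`.
#' @export
tachogram <- function(ibi, target_fs = 4, artifact_tol = 0.25) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (any(ibi$intervals <= 0))
    stop("intervals must be positive", call. = FALSE)
  tb <- ibi$beat_times[-1L]  # interval assigned to its closing beat
  iv <- ibi$intervals
  n_rej <- 0L
  if (!is.null(artifact_tol)) {
    med <- stats::median(iv)
    keep <- abs(iv - med) <= artifact_tol * med
    n_rej <- sum(!keep)
    tb <- tb[keep]; iv <- iv[keep]
  }
  if (length(iv) < 8L)
    stop("need at least 8 intervals for a tachogram", call. = FALSE)
  grid <- seq(tb[1L], tb[length(tb)], by = 1 / target_fs)
  v <- stats::approx(tb, iv, xout = grid)$y
  mu <- mean(v)
  structure(list(t = grid, values = v - mu, fs = target_fs, mean_ibi = mu,
                 n_rejected = n_rej),
            class = "tachogram")
}

#' HRV band powers and LF/HF ratio
#'
#' Welch periodogram of the tachogram (Hann window, 120 s segments or the full
#' series when shorter, 50% overlap), integrated over the standard HRV bands:
#' LF 0.04-0.15 Hz, HF 0.15-0.4 Hz.
#'
#' @param tg a [tachogram()] spanning about a minute or more (>= 55 s after
#'   edge-beat loss, so that a 60-s analysis window of signal qualifies).
#' @param lf_band,hf_band band edges in Hz.
#' @return object of class `hrv_spectrum` with `freqs`, `psd` (ms^2/Hz),
#'   `lf_power`, `hf_power` (ms^2) and `ratio` (LF/HF; `NA` and flagged
#'   undefined when HF power is zero).
#' @export
band_powers <- function(tg, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(tg, "tachogram"))
  span <- tg$t[length(tg$t)] - tg$t[1L]
  if (span < 55)
    stop("tachogram must span about a minute for band powers", call. = FALSE)
  w <- welch_psd(tg$values, tg$fs)
  lf <- band_integral(w$freq, w$psd, lf_band[1], lf_band[2])
  hf <- band_integral(w$freq, w$psd, hf_band[1], hf_band[2])
  ratio <- if (hf > 0) lf / hf else NA_real_
  structure(list(freqs = w$freq, psd = w$psd, lf_power = lf, hf_power = hf,
                 ratio = ratio, ratio_defined = hf > 0),
            class = "hrv_spectrum")
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf("<hrv_spectrum> LF %.1f ms^2, HF %.1f ms^2, LF/HF = %s\n",
              x$lf_power, x$hf_power,
              if (x$ratio_defined) sprintf("%.3f", x$ratio) else "undefined"))
  invisible(x)
}

#' Classify attention state from the LF/HF ratio
#'
#' Sympathetic (LF) dominance accompanies engaged, wakeful driving; relative
#' parasympathetic (HF) dominance accompanies drowsiness. The subject is
#' therefore wakeful iff `ratio >= threshold` (boundary inclusive). Set
#' `invert = TRUE` if a deployment calibrates the opposite convention.
#'
#' @param spec an `hrv_spectrum`.
#' @param threshold decision threshold on LF/HF, e.g. from
#'   [calibrate_attention_threshold()].
#' @param invert reverse the mapping direction.
#' @return object of class `attention_state`: `state` (`"wakeful"` or
#'   `"drowsy"`), `ratio`, `threshold`.
#' @export
classify_attention <- function(spec, threshold = 1, invert = FALSE) {
  stopifnot(inherits(spec, "hrv_spectrum"))
  if (!isTRUE(spec$ratio_defined))
    stop("LF/HF ratio undefined (zero HF power)", call. = FALSE)
  wakeful <- spec$ratio >= threshold
  if (invert) wakeful <- !wakeful
  structure(list(state = if (wakeful) "wakeful" else "drowsy",
                 ratio = spec$ratio, threshold = threshold),
            class = "attention_state")
}

#' @export
print.attention_state <- function(x, ...) {
  cat(sprintf("<attention_state> %s (LF/HF %.3f vs threshold %.3f)\n",
              x$state, x$ratio, x$threshold))
  invisible(x)
}

#' Calibrate the LF/HF decision threshold from labeled recordings
#'
#' Midpoint of the two class means, taken on the log scale because LF/HF is a
#' ratio quantity whose within-class spread is multiplicative: the threshold
#' is the geometric midpoint `sqrt(gm(wakeful) * gm(drowsy))` of the class
#' geometric means.
#'
#' @param ratios numeric LF/HF ratios (positive).
#' @param labels factor/character with levels `wakeful` and `drowsy`.
#' @return the threshold.
#' @export
calibrate_attention_threshold <- function(ratios, labels) {
  labels <- as.character(labels)
  stopifnot(length(ratios) == length(labels), all(ratios > 0),
            all(labels %in% c("wakeful", "drowsy")),
            any(labels == "wakeful"), any(labels == "drowsy"))
  exp((mean(log(ratios[labels == "wakeful"])) +
         mean(log(ratios[labels == "drowsy"]))) / 2)
}
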