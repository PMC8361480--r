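#' A single PPG beat with optional fiducial points
#'
#' @param samples beat samples (a.u.), onset to next onset.
#' @param fs sampling rate in Hz.
#' @param start_time absolute time of the first sample in seconds.
#' @param extrema optional data frame with columns `name` (m1..m4), `t`
#'   (absolute seconds) and `y` (a.u.).
#' @param compliant logical flag set by [detect_extrema()] /
#'   [compliance_score()]; `NA` until assessed.
#' @return an object of class `ppg_waveform`.
#' @export
ppg_waveform <- function(samples, fs, start_time = 0, extrema = NULL,
                         compliant = NA) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, fs > 0)
  if (!is.null(extrema)) {
    stopifnot(all(c("name", "t", "y") %in% names(extrema)))
    if (is.unsorted(extrema$t, strictly = TRUE))
      stop("extrema times must be strictly increasing", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time, extrema = extrema,
                 compliant = compliant),
            class = "ppg_waveform")
}

#' @export
print.ppg_waveform <- function(x, ...) {
  cat(sprintf("<ppg_waveform> %d samples at %g Hz from t=%.3f s; extrema %s; compliant=%s\n",
              length(x$samples), x$fs, x$start_time,
              if (is.null(x$extrema)) "unset" else "m1..m4 set",
              format(x$compliant)))
  invisible(x)
}

#' Zero-phase Butterworth band-pass for raw PPG
#'
#' Order-4 Butterworth with 0.5-10 Hz passband, applied forward-backward
#' (`signal::filtfilt`) so fiducial timing is not biased by filter phase. The
#' band isolates the pulsatile "AC" component, rejecting baseline drift from
#' respiration/thermoregulation below 0.5 Hz and high-frequency noise.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz; must exceed 20 Hz so the 10 Hz band edge is
#'   below Nyquist.
#' @param band passband edges in Hz.
#' @param order Butterworth order (of each of the low/high sections).
#' @return filtered signal, same length as the input.
#' @export
bandpass_filter <- function(x, fs, band = c(0.5, 10), order = 4L) {
  if (fs <= 20) stop("fs must exceed 20 Hz for a 10 Hz band edge", call. = FALSE)
  stopifnot_finite(x, "signal")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (the low band edge has a multi-second settle time)
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * fs))
  xp <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1L):(pad + n)]
}

# Local minima of x via negative-to-positive zero crossings of the first
# difference, gated on topographic prominence >= frac * peak-to-peak.
# Prominence of a minimum: walk outward until a strictly lower sample (or the
# series edge) is met on each side; the lower of the two intervening maxima,
# minus the minimum, is the prominence. A rising first sample is admitted as a
# leading onset; the trailing edge is never an onset (it cannot open a
# complete beat). Candidates closer than `refractory` seconds merge to the
# lowest; ties take the earliest sample.
find_onsets <- function(x, prominence_frac = 0.10, fs = NULL, refractory = 0.25) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  p2p <- diff(range(x))
  if (p2p == 0) return(integer(0))
  d <- diff(x)
  sgn <- sign(d)
  # earliest-sample convention: zero slopes inherit the following sign so a
  # flat-bottomed minimum is reported at its first sample
  for (i in seq.int(n - 1L, 1L)) if (sgn[i] == 0) sgn[i] <- if (i < n - 1L) sgn[i + 1L] else 1
  cand <- which(sgn[-1L] > 0 & sgn[-(n - 1L)] < 0) + 1L
  if (x[1] < x[2]) cand <- c(1L, cand)
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lo <- i; while (lo > 1L && x[lo - 1L] >= x[i]) lo <- lo - 1L
    hi <- i; while (hi < n && x[hi + 1L] >= x[i]) hi <- hi + 1L
    lmax <- if (lo == 1L && x[1] >= x[i]) Inf else max(x[lo:i])
    rmax <- max(x[i:hi])
    min(lmax, rmax) - x[i]
  }, numeric(1))
  cand <- cand[prom >= prominence_frac * p2p]
  if (!is.null(fs) && length(cand) > 1L) {
    gap <- round(refractory * fs)
    keep <- integer(0); cur <- cand[1L]
    for (i in cand[-1L]) {
      if (i - cur < gap) {
        if (x[i] < x[cur]) cur <- i
      } else {
        keep <- c(keep, cur); cur <- i
      }
    }
    cand <- c(keep, cur)
  }
  cand
}

#' Segment a filtered PPG signal into beats
#'
#' Beats are delimited onset-minimum to next onset-minimum. Onset minima are
#' negative-to-positive zero crossings of the first derivative, gated on a
#' prominence of 10% of the signal peak-to-peak to suppress noise-induced
#' crossings. Fewer than two onsets yields an empty list with a warning.
#'
#' @param x filtered signal.
#' @param fs sampling rate in Hz.
#' @param prominence_frac prominence gate as a fraction of peak-to-peak.
#' @return list of [ppg_waveform()] objects (possibly empty).
#' @export
segment_waveforms <- function(x, fs, prominence_frac = 0.10) {
  stopifnot_finite(x, "signal")
  # onset search runs on a lightly smoothed copy (stable prominence walks),
  # then each onset is refined to the local minimum of the raw signal
  xs <- if (length(x) >= 11L) signal::sgolayfilt(x, p = 2, n = 7) else x
  onsets <- find_onsets(xs, prominence_frac, fs = fs, refractory = 0.4)
  onsets <- vapply(onsets, function(i) {
    lo <- max(1L, i - 2L); hi <- min(length(x), i + 2L)
    (lo:hi)[which.min(x[lo:hi])][1L]
  }, integer(1))
  onsets <- sort(unique(onsets))
  if (length(onsets) < 2L) {
    warning("fewer than 2 onsets found; no complete beats", call. = FALSE)
    return(list())
  }
  lapply(seq_len(length(onsets) - 1L), function(k) {
    idx <- onsets[k]:onsets[k + 1L]
    w <- ppg_waveform(x[idx], fs, start_time = (onsets[k] - 1L) / fs)
    # sub-sample onset timing by parabolic interpolation through the minimum
    # (beat-to-beat interval precision matters for HRV spectra)
    w$onset_delta <- parabolic_offset(x, onsets[k])
    w
  })
}

#' Detect the four per-beat extreme points m1..m4
#'
#' Classifies first-derivative zero crossings by the sign of the second
#' derivative: m1 is the onset minimum (the beat's first sample), m2 the first
#' subsequent maximum (systolic peak), m3 the next minimum (dicrotic notch)
#' and m4 the next maximum (diastolic peak). A beat lacking this alternating
#' structure, or whose systolic peak is not its global maximum (e.g. a
#' time-reversed or artifact beat), is flagged non-compliant with extrema
#' unset.
#'
#' @param w a `ppg_waveform` with at least 8 samples.
#' @return the waveform with `extrema` filled and `compliant` set.
#' @export
detect_extrema <- function(w) {
  stopifnot(inherits(w, "ppg_waveform"))
  x <- w$samples
  n <- length(x)
  if (n < 8L) stop("beat must have at least 8 samples", call. = FALSE)
  # light zero-phase quadratic smoothing stabilizes the derivative analysis
  # against in-band noise without biasing extremum timing
  if (n >= 9L) x <- signal::sgolayfilt(w$samples, p = 2, n = 7)
  d <- diff(x)
  sgn <- sign(d)
  for (i in seq.int(length(sgn), 1L)) if (sgn[i] == 0) sgn[i] <- if (i < length(sgn)) sgn[i + 1L] else -1
  flips <- which(sgn[-1L] != sgn[-length(sgn)]) + 1L  # interior turning samples
  kind <- character(0)
  if (length(flips)) {
    # sign of the second derivative at the crossing classifies min vs max;
    # refine to the better of the flanking samples (within-1-sample choice)
    kind <- ifelse(sgn[flips] > 0, "min", "max")
    refine <- function(i, k) {
      cand <- c(i - 1L, i, i + 1L); cand <- cand[cand >= 2L & cand <= n - 1L]
      cand[if (k == "max") which.max(x[cand]) else which.min(x[cand])][1L]
    }
    flips <- as.integer(mapply(refine, flips, kind))
    ord <- order(flips)
    flips <- flips[ord]; kind <- kind[ord]
    dup <- duplicated(flips)
    flips <- flips[!dup]; kind <- kind[!dup]
    pr <- prune_turning_points(flips, kind, x, tol = 0.025 * diff(range(x)))
    flips <- pr$idx; kind <- pr$kind
  }
  # alternation after the onset minimum: systolic max, notch min, diastolic max
  seq_needed <- c("max", "min", "max")
  sel <- integer(0); want <- 1L
  for (j in seq_along(flips)) {
    if (want <= 3L && kind[j] == seq_needed[want]) {
      sel <- c(sel, flips[j]); want <- want + 1L
    }
  }
  if (length(sel) < 3L) {
    w$compliant <- FALSE
    w$extrema <- NULL
    return(w)
  }
  idx <- c(1L, sel[1:3])
  ys <- x[idx]
  # systolic peak must dominate the beat (rules out reversed/artifact beats)
  p2p <- diff(range(x))
  if (ys[2] < max(x) - 0.02 * p2p || ys[2] <= ys[4]) {
    w$compliant <- FALSE
    w$extrema <- NULL
    return(w)
  }
  # sub-sample timing refinement: the onset reuses the segmentation offset,
  # the interior fiducials use a parabola through their neighbours
  deltas <- c(w$onset_delta %||% 0,
              vapply(sel[1:3], function(i) parabolic_offset(x, i), numeric(1)))
  w$extrema <- data.frame(name = c("m1", "m2", "m3", "m4"),
                          t = w$start_time + (idx - 1L + deltas) / w$fs,
                          y = ys)
  w$compliant <- TRUE
  w
}

# Sub-sample offset of an extremum at index i via a parabola through its
# neighbours; 0 at the series edges, clamped to half a sample.
parabolic_offset <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(0)
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (abs(denom) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (x[i - 1L] - x[i + 1L]) / denom))
}

# Collapse noise-induced wiggles in an ordered turning-point sequence:
# same-kind neighbours are merged (keeping the more extreme) and adjacent
# min/max pairs whose amplitude excursion falls below `tol` are removed.
prune_turning_points <- function(idx, kind, x, tol) {
  repeat {
    j <- 2L
    while (j <= length(idx)) {
      if (length(kind) >= j && kind[j] == kind[j - 1L]) {
        drop <- if (kind[j] == "max") {
          if (x[idx[j]] >= x[idx[j - 1L]]) j - 1L else j
        } else {
          if (x[idx[j]] <= x[idx[j - 1L]]) j - 1L else j
        }
        idx <- idx[-drop]; kind <- kind[-drop]
      } else j <- j + 1L
    }
    if (length(idx) < 2L) return(list(idx = idx, kind = kind))
    amp <- abs(diff(x[idx]))
    small <- which(amp < tol)
    if (!length(small)) return(list(idx = idx, kind = kind))
    k <- small[which.min(amp[small])]
    idx <- idx[-c(k, k + 1L)]; kind <- kind[-c(k, k + 1L)]
  }
}

#' Compliance template for PPG beat gating
#'
#' A stored reference beat used to score how standard-compliant a detected
#' waveform is, by normalized cross-correlation at zero lag. The default
#' template is the clean two-lobe pulse itself.
#'
#' @param samples reference beat samples; stored zero-mean, unit-energy.
#' @param min_corr acceptance threshold in (0, 1].
#' @return object of class `compliance_template`.
#' @export
compliance_template <- function(samples = NULL, min_corr = 0.8) {
  stopifnot(min_corr > 0, min_corr <= 1)
  if (is.null(samples)) {
    s <- (0:99) / 100
    samples <- beat_pulse(s, beat_morphology())
  }
  stopifnot(length(samples) > 1L)
  samples <- samples - mean(samples)
  en <- sqrt(sum(samples^2))
  if (en == 0) stop("template has zero energy", call. = FALSE)
  structure(list(samples = samples / en, min_corr = min_corr),
            class = "compliance_template")
}

#' Score a beat against the compliance template
#'
#' The beat is linearly resampled to the template length, made zero-mean and
#' unit-energy, and correlated with the template at zero lag. A zero-energy
#' beat scores 0 and is flagged non-compliant.
#'
#' @param w a `ppg_waveform`.
#' @param tpl a [compliance_template()].
#' @return the correlation score in `[-1, 1]`, with attribute `compliant`
#'   (`score >= tpl$min_corr`).
#' @export
compliance_score <- function(w, tpl = compliance_template()) {
  stopifnot(inherits(w, "ppg_waveform"), inherits(tpl, "compliance_template"))
  m <- length(tpl$samples)
  b <- stats::approx(seq_along(w$samples), w$samples,
                     xout = seq(1, length(w$samples), length.out = m))$y
  b <- b - mean(b)
  en <- sqrt(sum(b^2))
  if (en == 0) {
    score <- 0
  } else {
    score <- sum((b / en) * tpl$samples)
  }
  attr(score, "compliant") <- score >= tpl$min_corr
  score
}

#' Beat onset times by template matched filtering
#'
#' Cross-correlates the (mean-removed) signal with a zero-mean template beat
#' and reads beat onsets off the correlation peaks, with sub-sample parabolic
#' refinement. Because the template spans the whole beat, the timing estimate
#' is driven by the steep systolic upstroke rather than the flat onset
#' valley, making it far more precise on noisy or reconstructed signals than
#' an argmin search; the template starts at the beat onset, so peak positions
#' are onset estimates directly.
#'
#' @param x signal (a.u.).
#' @param fs sampling rate in Hz.
#' @param morphology template beat shape, see [beat_morphology()].
#' @param period beat period in seconds; estimated from the signal
#'   autocorrelation (first peak between 0.4 and 2 s) when `NULL`.
#' @param refractory minimum peak separation as a fraction of the period.
#' @return numeric vector of onset times in seconds (possibly empty).
#' @export
beat_anchor_times <- function(x, fs, morphology = beat_morphology(),
                              period = NULL, refractory = 0.6) {
  stopifnot_finite(x, "signal")
  n <- length(x)
  xc <- x - mean(x)
  if (stats::sd(xc) < 1e-12) return(numeric(0))
  if (is.null(period)) {
    ac <- stats::acf(xc, lag.max = min(n - 1L, floor(2 * fs)), plot = FALSE)$acf[-1L]
    lo <- max(2L, floor(0.4 * fs))
    if (lo >= length(ac)) return(numeric(0))
    period <- (which.max(ac[lo:length(ac)]) + lo - 1L) / fs
  }
  ns <- round(period * fs)
  if (ns < 4L || ns >= n) return(numeric(0))
  tpl <- beat_pulse((seq_len(ns) - 1L) / ns, morphology)
  tpl <- tpl - mean(tpl)
  # valid cross-correlation via FFT: cc[k] = sum_t xc[k+t-1] * tpl[t]
  m <- n + ns
  cc <- Re(stats::fft(stats::fft(c(xc, rep(0, ns))) *
                        Conj(stats::fft(c(tpl, rep(0, n)))), inverse = TRUE)) / m
  cc <- cc[seq_len(n - ns + 1L)]
  d <- diff(cc)
  cand <- which(d[-1L] < 0 & d[-length(d)] > 0) + 1L
  cand <- cand[cc[cand] > 0]
  if (!length(cand)) return(numeric(0))
  gap <- round(refractory * period * fs)
  cand <- cand[order(cc[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) if (!length(keep) || all(abs(keep - i) >= gap)) keep <- c(keep, i)
  keep <- sort(keep)
  dt <- vapply(keep, function(i) parabolic_offset(cc, i), numeric(1))
  (keep - 1L + dt) / fs
}

#' Inter-beat-interval series from compliant beats
#'
#' Beat times are the m1 (onset-minimum) times of the supplied waveforms, per
#' the convention that HRV derives from the distance between the minimum
#' points of consecutive waveforms.
#'
#' @param waves list of `ppg_waveform` objects with extrema set.
#' @return object of class `ibi_series`: `beat_times` (s) and `intervals` (ms).
#' @export
extract_ibi <- function(waves) {
  waves <- Filter(function(w) !is.null(w$extrema), waves)
  if (length(waves) < 2L)
    stop("need at least 2 waveforms with m1 set", call. = FALSE)
  bt <- vapply(waves, function(w) w$extrema$t[w$extrema$name == "m1"], numeric(1))
  if (is.unsorted(bt, strictly = TRUE))
    stop("m1 times are not strictly increasing", call. = FALSE)
  ibi_series(bt)
}

#' @rdname extract_ibi
#' @param beat_times strictly increasing beat times in seconds.
#' @export
ibi_series <- function(beat_times) {
  stopifnot(length(beat_times) >= 2L, !is.unsorted(beat_times, strictly = TRUE))
  intervals <- diff(beat_times) * 1000
  if (any(intervals <= 0)) stop("intervals must be positive", call. = FALSE)
  structure(list(beat_times = beat_times, intervals = intervals),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals, mean %.0f ms (%.1f bpm)\n",
              length(x$intervals), mean(x$intervals),
              60000 / mean(x$intervals)))
  invisible(x)
}
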