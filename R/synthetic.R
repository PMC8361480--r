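#' Simulation configuration for synthetic PPG
#'
#' Bundles the pulse-train settings used by [simulate_ppg()]: recording
#' duration, sampling rate, mean inter-beat interval (IBI) and the two
#' autonomic modulation bands that drive beat-to-beat variability. Depths are
#' fractional IBI modulations and must lie in `[0, 0.5)`; the low-frequency
#' band must sit below the high-frequency band (defaults 0.1 Hz and 0.25 Hz,
#' the canonical sympathetic/parasympathetic markers).
#'
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz (nominal probe rate 1000).
#' @param mean_ibi mean inter-beat interval in seconds.
#' @param lf_mod `c(freq, depth)`: low-frequency IBI modulation (Hz, fraction).
#' @param hf_mod `c(freq, depth)`: high-frequency IBI modulation (Hz, fraction).
#' @param noise_sd additive Gaussian noise s.d. (arbitrary units).
#' @param drift_amp amplitude of a slow sinusoidal baseline drift (a.u.).
#' @param drift_freq drift frequency in Hz (well below the 0.5 Hz passband).
#' @param seed integer seed; all randomness in the simulation flows from it.
#' @param label optional attention-state tag carried by the record.
#' @param morphology beat-shape parameters, see [beat_morphology()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration = 60, fs = 1000, mean_ibi = 1.0,
                       lf_mod = c(freq = 0.1, depth = 0),
                       hf_mod = c(freq = 0.25, depth = 0),
                       noise_sd = 0, drift_amp = 0, drift_freq = 0.05,
                       seed = 1L, label = NA_character_,
                       morphology = beat_morphology()) {
  stopifnot(duration > 0, fs > 0, mean_ibi > 0, noise_sd >= 0, drift_amp >= 0)
  lf <- unname(lf_mod); hf <- unname(hf_mod)
  if (lf[2] < 0 || lf[2] >= 0.5 || hf[2] < 0 || hf[2] >= 0.5)
    stop("modulation depths must lie in [0, 0.5)", call. = FALSE)
  if (lf[1] >= hf[1])
    stop("lf_mod frequency must be below hf_mod frequency", call. = FALSE)
  structure(list(duration = duration, fs = fs, mean_ibi = mean_ibi,
                 lf_freq = lf[1], lf_depth = lf[2],
                 hf_freq = hf[1], hf_depth = hf[2],
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_freq = drift_freq, seed = seed, label = label,
                 morphology = morphology),
            class = "sim_config")
}

#' Two-lobe beat morphology parameters
#'
#' The synthetic pulse is the sum of two positive Gaussian lobes on the
#' normalized beat interval `[0, 1)`: a systolic lobe and a smaller, later
#' diastolic lobe. Their superposition produces the four canonical fiducials
#' per beat: onset minimum, systolic maximum, dicrotic-notch minimum and
#' diastolic maximum, with analytically computable locations.
#'
#' @param sys_amp,sys_center,sys_width systolic lobe amplitude (a.u.), center
#'   and s.d. in normalized beat time.
#' @param dia_amp,dia_center,dia_width diastolic lobe parameters.
#' @return a named list of morphology parameters.
#' @export
beat_morphology <- function(sys_amp = 1.0, sys_center = 0.28, sys_width = 0.07,
                            dia_amp = 0.38, dia_center = 0.58, dia_width = 0.14) {
  stopifnot(sys_amp > 0, dia_amp > 0, sys_width > 0, dia_width > 0,
            sys_center > 0, dia_center < 1, sys_center < dia_center)
  list(sys_amp = sys_amp, sys_center = sys_center, sys_width = sys_width,
       dia_amp = dia_amp, dia_center = dia_center, dia_width = dia_width)
}

# Pulse value at normalized beat time s in [0, 1).
beat_pulse <- function(s, m) {
  m$sys_amp * exp(-(s - m$sys_center)^2 / (2 * m$sys_width^2)) +
    m$dia_amp * exp(-(s - m$dia_center)^2 / (2 * m$dia_width^2))
}

# Interior extrema (systolic max, dicrotic min, diastolic max) of the
# two-lobe pulse, in normalized beat time, found on the closed form.
beat_pulse_extrema <- function(m) {
  mid <- (m$sys_center + m$dia_center) / 2
  sys <- stats::optimize(function(s) beat_pulse(s, m),
                         c(0, mid), maximum = TRUE, tol = 1e-10)
  dia <- stats::optimize(function(s) beat_pulse(s, m),
                         c(mid, 1), maximum = TRUE, tol = 1e-10)
  nt <- stats::optimize(function(s) beat_pulse(s, m),
                        c(sys$maximum, dia$maximum), tol = 1e-10)
  y_sys <- sys$objective; y_nt <- nt$objective; y_dia <- dia$objective
  if (!(y_sys > y_nt && y_dia > y_nt))
    stop("morphology has no dicrotic structure (lobes merge)", call. = FALSE)
  list(s = c(sys$maximum, nt$minimum, dia$maximum),
       y = c(y_sys, y_nt, y_dia))
}

#' Simulate a PPG pulse train with ground truth
#'
#' Renders a pulse train where each beat is the two-lobe pulse of
#' [beat_morphology()] on its own inter-beat interval. Beat-to-beat intervals
#' follow `mean_ibi * (1 + d_LF sin(2 pi f_LF t) + d_HF sin(2 pi f_HF t))`
#' evaluated at each beat onset, so the tachogram carries power in the chosen
#' autonomic bands. Gaussian noise and a slow sinusoidal drift are added after
#' the ground-truth extrema are recorded on the clean signal.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `ppg_record`: noisy `samples`, clean signal,
#'   time axis, `beat_onsets`, per-beat `ibis`, a `true_extrema` data frame
#'   (`beat`, `name` in m1..m4, `t` seconds, `y` a.u.) and the label.
#' @export
simulate_ppg <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  morph <- cfg$morphology
  onsets <- numeric(0); ibis <- numeric(0)
  t <- 0
  repeat {
    ibi <- cfg$mean_ibi * (1 + cfg$lf_depth * sin(2 * pi * cfg$lf_freq * t) +
                             cfg$hf_depth * sin(2 * pi * cfg$hf_freq * t))
    if (t + ibi > cfg$duration + 1e-9) break
    onsets <- c(onsets, t); ibis <- c(ibis, ibi)
    t <- t + ibi
  }
  if (length(onsets) < 2L)
    stop("duration too short: fewer than 2 beats fit", call. = FALSE)

  n <- floor(cfg$duration * cfg$fs)
  tt <- (seq_len(n) - 1L) / cfg$fs
  k <- findInterval(tt, onsets)
  k[k < 1L] <- 1L
  s <- (tt - onsets[k]) / ibis[k]
  clean <- beat_pulse(s, morph)

  ext <- beat_pulse_extrema(morph)
  nb <- length(onsets)
  true_extrema <- data.frame(
    beat = rep(seq_len(nb), each = 4L),
    name = rep(c("m1", "m2", "m3", "m4"), nb),
    t = as.vector(vapply(seq_len(nb), function(b)
      c(onsets[b], onsets[b] + ext$s * ibis[b]), numeric(4))),
    y = rep(c(beat_pulse(0, morph), ext$y), nb)
  )

  samples <- with_seed(cfg$seed, {
    clean +
      cfg$drift_amp * sin(2 * pi * cfg$drift_freq * tt) +
      stats::rnorm(n, 0, cfg$noise_sd)
  })

  structure(list(samples = samples, clean = clean, t = tt, fs = cfg$fs,
                 beat_onsets = onsets, ibis = ibis,
                 true_extrema = true_extrema, label = cfg$label, cfg = cfg),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %.1f s at %g Hz, %d beats, mean IBI %.0f ms%s\n",
              length(x$samples) / x$fs, x$fs, length(x$beat_onsets),
              1000 * mean(x$ibis),
              if (is.na(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Simulate facial-landmark intensity series coupled to a PPG record
#'
#' Emulates the per-landmark pixel-intensity time series a face tracker would
#' produce: `n_coupled` channels are `gain_i * PPG + drift + noise` (the PPG is
#' linearly resampled down to the camera frame rate), the remaining channels
#' are uncoupled nuisance noise. Ground-truth coupling is stored with the
#' result.
#'
#' @param ppg a `ppg_record`.
#' @param n_landmarks number of landmark channels (default 68).
#' @param n_coupled how many channels carry the cardiac signal.
#' @param gains numeric vector of length `n_coupled`.
#' @param noise_sd additive noise s.d. on coupled channels.
#' @param fps camera frame rate; must not exceed the PPG sampling rate.
#' @param seed integer seed.
#' @param drift_amp per-channel slow drift amplitude (random phase).
#' @param nuisance_sd s.d. of the uncoupled channels.
#' @return an object of class `landmark_series` with fields `intensities`
#'   (frames x landmarks), `coords`, `fps`, `coupled`, `gains`, `provider_id`.
#' @export
simulate_landmark_series <- function(ppg, n_landmarks = 68L, n_coupled = n_landmarks,
                                     gains = rep(1, n_coupled), noise_sd = 0,
                                     fps = 50, seed = 1L, drift_amp = 0,
                                     nuisance_sd = 1) {
  stopifnot(inherits(ppg, "ppg_record"), n_landmarks >= 1L,
            n_coupled >= 0L, n_coupled <= n_landmarks,
            length(gains) == n_coupled, noise_sd >= 0)
  if (fps > ppg$fs)
    stop("fps exceeds the PPG sampling rate; refusing to upsample", call. = FALSE)
  base <- resample_linear(ppg$samples, ppg$fs, fps)
  nf <- length(base)
  tt <- (seq_len(nf) - 1L) / fps
  with_seed(seed, {
    intens <- matrix(0, nrow = nf, ncol = n_landmarks)
    if (n_coupled > 0L) {
      phases <- stats::runif(n_coupled, 0, 2 * pi)
      for (j in seq_len(n_coupled)) {
        intens[, j] <- gains[j] * base +
          drift_amp * sin(2 * pi * 0.03 * tt + phases[j]) +
          stats::rnorm(nf, 0, noise_sd)
      }
    }
    if (n_coupled < n_landmarks) {
      idx <- (n_coupled + 1L):n_landmarks
      intens[, idx] <- matrix(stats::rnorm(nf * length(idx), 0, nuisance_sd),
                              nrow = nf)
    }
    coords <- cbind(x = round(stats::runif(n_landmarks, 1, 640)),
                    y = round(stats::runif(n_landmarks, 1, 480)))
    structure(list(intensities = intens, coords = coords, fps = fps,
                   n_frames = nf, n_landmarks = n_landmarks,
                   coupled = seq_len(n_landmarks) <= n_coupled,
                   gains = gains, provider_id = "synthetic"),
              class = "landmark_series")
  })
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("<landmark_series> %d frames x %d landmarks at %g fps (%d coupled, provider=%s)\n",
              x$n_frames, x$n_landmarks, x$fps, sum(x$coupled), x$provider_id))
  invisible(x)
}

#' Simulate 77x77 grayscale eye patches
#'
#' Renders schematic single-eye patches at the resolution the eye-state
#' classifier consumes. "open" draws a bright sclera ellipse with a dark iris
#' and pupil; "closed" draws a dark eyelid arc over skin. Position, scale and
#' contrast are jittered per patch; intensities lie in `[0, 1]`.
#'
#' @param n number of patches (>= 1).
#' @param state `"open"` or `"closed"`.
#' @param seed integer seed.
#' @return list with `images` (list of 77x77 matrices), `labels` (factor with
#'   levels `wakeful`/`drowsy`; open eyes are wakeful) and `state`.
#' @export
simulate_eye_patches <- function(n, state = c("open", "closed"), seed = 1L) {
  state <- match.arg(state)
  stopifnot(n >= 1L)
  px <- 77L
  xg <- matrix(rep(seq_len(px), each = px), nrow = px)   # column index
  yg <- matrix(rep(seq_len(px), times = px), nrow = px)  # row index
  with_seed(seed, {
    images <- vector("list", n)
    for (i in seq_len(n)) {
      cx <- 39 + stats::runif(1, -4, 4)
      cy <- 39 + stats::runif(1, -4, 4)
      sc <- stats::runif(1, 0.85, 1.15)
      contrast <- stats::runif(1, 0.85, 1.1)
      img <- matrix(0.55, px, px)
      if (state == "open") {
        inside <- ((xg - cx) / (26 * sc))^2 + ((yg - cy) / (13 * sc))^2 <= 1
        img[inside] <- 0.92
        iris <- (xg - cx)^2 + (yg - cy)^2 <= (6 * sc)^2
        img[iris & inside] <- 0.18
        pupil <- (xg - cx)^2 + (yg - cy)^2 <= (2.5 * sc)^2
        img[pupil & inside] <- 0.05
      } else {
        lid <- cy + 7 * ((xg - cx) / (26 * sc))^2
        band <- abs(yg - lid) <= 2.2 & abs(xg - cx) <= 28 * sc
        img[band] <- 0.20
      }
      img <- 0.5 + (img - 0.5) * contrast
      img <- img + matrix(stats::rnorm(px * px, 0, 0.02), px, px)
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
    labels <- factor(rep(if (state == "open") "wakeful" else "drowsy", n),
                     levels = c("wakeful", "drowsy"))
    list(images = images, labels = labels, state = state)
  })
}

#' Simulate a two-class cohort of single PPG beats for blood-pressure work
#'
#' Generates labeled beats whose morphology differs chiefly in the diastolic
#' lobe amplitude, so the modified augmentation index mAI (which depends on the
#' diastolic-peak amplitude relative to the notch-to-onset excursion) separates
#' the classes. Each beat carries its analytic ground-truth fiducials.
#'
#' @param n_beats_per_class beats per class.
#' @param class_params list with elements `normal` and `abnormal`, each a list
#'   of `dia_amp` (mean diastolic lobe amplitude) and `dia_amp_sd`.
#' @param seed integer seed.
#' @param fs beat sampling rate in Hz.
#' @return list with `waveforms` (list of `ppg_waveform`) and `labels`
#'   (factor `normal`/`abnormal`), interleaved in generation order.
#' @export
simulate_bp_cohort <- function(n_beats_per_class,
                               class_params = list(
                                 normal = list(dia_amp = 0.30, dia_amp_sd = 0.02),
                                 abnormal = list(dia_amp = 0.62, dia_amp_sd = 0.02)),
                               seed = 1L, fs = 250) {
  stopifnot(n_beats_per_class >= 1L,
            all(c("normal", "abnormal") %in% names(class_params)))
  with_seed(seed, {
    waves <- list(); labs <- character(0)
    for (cls in c("normal", "abnormal")) {
      p <- class_params[[cls]]
      prev_end <- 0
      for (b in seq_len(n_beats_per_class)) {
        morph <- beat_morphology(
          sys_amp = 1 + stats::rnorm(1, 0, 0.03),
          sys_center = 0.28 + stats::rnorm(1, 0, 0.004),
          sys_width = 0.07 + stats::rnorm(1, 0, 0.001),
          dia_amp = max(0.22, p$dia_amp + stats::rnorm(1, 0, p$dia_amp_sd)),
          dia_center = 0.58 + stats::rnorm(1, 0, 0.004),
          dia_width = 0.14 + stats::rnorm(1, 0, 0.002))
        ibi <- 1 + stats::rnorm(1, 0, 0.03)
        ns <- floor(ibi * fs)
        s <- (seq_len(ns) - 1L) / (ibi * fs)
        samples <- beat_pulse(s, morph)
        ext <- beat_pulse_extrema(morph)
        y1 <- beat_pulse(0, morph)
        if (abs(ext$y[2] - y1) < 1e-9)
          stop("degenerate morphology: notch amplitude equals onset amplitude (mAI undefined)",
               call. = FALSE)
        extrema <- data.frame(
          name = c("m1", "m2", "m3", "m4"),
          t = prev_end + c(0, ext$s * ibi),
          y = c(y1, ext$y))
        waves[[length(waves) + 1L]] <-
          ppg_waveform(samples, fs, start_time = prev_end, extrema = extrema,
                       compliant = TRUE)
        labs <- c(labs, cls)
        prev_end <- prev_end + ibi
      }
    }
    list(waveforms = waves, labels = factor(labs, levels = c("normal", "abnormal")))
  })
}

#' Toy feature map and bounding boxes for attention experiments
#'
#' @param C,H,W channel count and spatial size (all >= 1).
#' @param seed integer seed.
#' @param fill `"normal"` for seeded Gaussian values or a single number for a
#'   constant map.
#' @return a `C x H x W` array of class `feature_map`.
#' @export
make_toy_feature_map <- function(C, H, W, seed = 1L, fill = "normal") {
  stopifnot(C >= 1L, H >= 1L, W >= 1L)
  vals <- if (identical(fill, "normal")) {
    with_seed(seed, stats::rnorm(C * H * W))
  } else {
    rep(as.numeric(fill), C * H * W)
  }
  structure(array(vals, dim = c(C, H, W)), class = "feature_map")
}

#' @rdname make_toy_feature_map
#' @param boxes a list (or data frame) of `x`, `y`, `w`, `h` box geometries in
#'   pixels.
#' @return for `make_toy_boxes`, a list of `bounding_box` objects.
#' @export
make_toy_boxes <- function(boxes) {
  if (is.data.frame(boxes)) boxes <- split(boxes, seq_len(nrow(boxes)))
  out <- lapply(boxes, function(b) {
    b <- as.list(b)
    stopifnot(all(c("w", "h") %in% names(b)), b$w > 0, b$h > 0)
    structure(list(x = b$x %||% 0, y = b$y %||% 0, w = b$w, h = b$h),
              class = "bounding_box")
  })
  names(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
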