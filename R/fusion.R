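#' Risk inputs for the driving-safety decision
#'
#' The four boolean flags the fusion rules consume. Missing (`NA`) flags are
#' conservative-defaulted to `FALSE` — absent sensor data never escalates an
#' alert — with a warning.
#'
#' @param hrv_low_attention HRV analysis indicates low attention.
#' @param bp_abnormal blood-pressure network flags abnormal pressure.
#' @param eye_low_attention eye-state classifier indicates low attention.
#' @param salient_pedestrians salient pedestrians present in the scene.
#' @return object of class `risk_inputs`.
#' @export
risk_inputs <- function(hrv_low_attention, bp_abnormal, eye_low_attention,
                        salient_pedestrians) {
  flags <- list(hrv_low_attention = hrv_low_attention,
                bp_abnormal = bp_abnormal,
                eye_low_attention = eye_low_attention,
                salient_pedestrians = salient_pedestrians)
  for (nm in names(flags)) {
    if (is.na(flags[[nm]])) {
      warning(sprintf("flag '%s' unknown; defaulting to FALSE", nm),
              call. = FALSE)
      flags[[nm]] <- FALSE
    }
    stopifnot(is.logical(flags[[nm]]), length(flags[[nm]]) == 1L)
  }
  structure(flags, class = "risk_inputs")
}

#' Assess the driving-safety risk level
#'
#' Rule table, evaluated in precedence order:
#' \itemize{
#'   \item \strong{high}: HRV shows low attention AND (blood pressure
#'     abnormal OR eye state shows low attention) AND salient pedestrians
#'     are present;
#'   \item \strong{medium_low}: (HRV shows low attention OR eye state shows
#'     low attention) AND salient pedestrians are present;
#'   \item \strong{none} otherwise.
#' }
#' Every alert therefore requires salient pedestrians in the scene.
#'
#' @param r a [risk_inputs()].
#' @return object of class `risk_assessment` with `level`,
#'   `alert_intensity`, the echoed `inputs` and a `timestamp`.
#' @export
assess_risk <- function(r) {
  stopifnot(inherits(r, "risk_inputs"))
  level <- if (r$hrv_low_attention &&
               (r$bp_abnormal || r$eye_low_attention) &&
               r$salient_pedestrians) {
    "high"
  } else if ((r$hrv_low_attention || r$eye_low_attention) &&
             r$salient_pedestrians) {
    "medium_low"
  } else {
    "none"
  }
  intensity <- c(high = "high", medium_low = "medium-low", none = "off")[[level]]
  structure(list(level = level, alert_intensity = intensity, inputs = r,
                 timestamp = Sys.time()),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> level=%s (alert %s) [hrv_low=%s bp=%s eye_low=%s salient=%s]\n",
              x$level, x$alert_intensity,
              x$inputs$hrv_low_attention, x$inputs$bp_abnormal,
              x$inputs$eye_low_attention, x$inputs$salient_pedestrians))
  invisible(x)
}

#' Run the full monitoring pipeline over a session
#'
#' Orchestrates the per-window decision flow: PPG processing (or the
#' Vision2PPG fallback when the probe signal is marked unavailable), HRV
#' drowsiness scoring, blood-pressure flagging, eye-state classification and
#' pedestrian salience, fused by [assess_risk()] on every analysis window.
#'
#' The configuration is a list (or path to a YAML file) with elements:
#' \describe{
#'   \item{ppg}{a `ppg_record` (required).}
#'   \item{landmarks}{a `landmark_series` paired with the record; required
#'     when any window has the probe unavailable.}
#'   \item{v2p_model}{a calibrated [v2p_calibrate()] model for the fallback.}
#'   \item{ppg_available}{logical, recycled over windows (default `TRUE`).}
#'   \item{window, overlap}{analysis window and overlap in seconds
#'     (default 60/30).}
#'   \item{hrv_threshold}{LF/HF wakefulness threshold (default 1).}
#'   \item{snn_model, phi}{optional blood-pressure model and per-window phi
#'     matrix; alternatively `bp_flag` (logical, recycled).}
#'   \item{eye_model, eye_patches}{optional eye classifier and per-window
#'     patch lists; alternatively `eye_flag` (logical, recycled).}
#'   \item{boxes, salience}{per-window box lists and a [salience_config()];
#'     alternatively `salient_flag` (logical, recycled).}
#' }
#'
#' @param cfg configuration list or YAML path.
#' @return object of class `dsds_report`: a per-window data frame plus a log.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  if (is.null(cfg$ppg)) stop("missing asset: ppg record", call. = FALSE)
  ppg <- cfg$ppg
  if (is.character(ppg)) {  # CSV path from a YAML config
    raw <- read_ppg_csv(ppg)
    ppg <- structure(list(samples = raw$samples, fs = raw$fs, t = raw$t),
                     class = "ppg_record")
  }
  window <- cfg$window %||% 60
  overlap <- cfg$overlap %||% 30
  thr <- cfg$hrv_threshold %||% 1
  dur <- length(ppg$samples) / ppg$fs
  starts <- seq(0, max(0, dur - window), by = window - overlap)
  n_win <- length(starts)
  avail <- rep(cfg$ppg_available %||% TRUE, length.out = n_win)
  if (any(!avail)) {
    if (is.null(cfg$v2p_model))
      stop("missing asset: v2p_model (needed for PPG-unavailable windows)",
           call. = FALSE)
    if (is.null(cfg$landmarks))
      stop("missing asset: landmarks (needed for PPG-unavailable windows)",
           call. = FALSE)
    mu_full <- composite_signal(cfg$landmarks)
  }
  bp_flags <- rep(cfg$bp_flag %||% NA, length.out = n_win)
  eye_flags <- rep(cfg$eye_flag %||% NA, length.out = n_win)
  sal_flags <- rep(cfg$salient_flag %||% NA, length.out = n_win)
  rows <- list()
  for (k in seq_len(n_win)) {
    t0 <- starts[k]; t1 <- min(dur, t0 + window)
    source <- if (avail[k]) "ppg" else "vision"
    if (avail[k]) {
      say("window %d [%g, %g) s: native PPG available; Vision2PPG branch skipped",
          k, t0, t1)
      idx <- which(ppg$t >= t0 & ppg$t < t1)
      waves <- Filter(function(w) isTRUE(w$compliant),
                      lapply(segment_waveforms(
                        bandpass_filter(ppg$samples[idx], ppg$fs), ppg$fs),
                        detect_extrema))
      m1 <- vapply(waves, function(w) w$extrema$t[1L], numeric(1)) + t0
    } else {
      say("window %d [%g, %g) s: PPG unavailable; Vision2PPG fallback active",
          k, t0, t1)
      fidx <- which((seq_along(mu_full$values) - 1L) / mu_full$fps >= t0 &
                      (seq_along(mu_full$values) - 1L) / mu_full$fps < t1)
      mu_w <- mu_full; mu_w$values <- mu_full$values[fidx]
      rec <- v2p_reconstruct(cfg$v2p_model, mu_w)
      m1 <- rec$m1_times + t0
    }
    ratio <- NA_real_
    hrv_low <- NA
    if (length(m1) >= 10L) {
      sp <- try(band_powers(tachogram(ibi_series(m1))), silent = TRUE)
      if (!inherits(sp, "try-error") && isTRUE(sp$ratio_defined)) {
        ratio <- sp$ratio
        hrv_low <- classify_attention(sp, thr)$state == "drowsy"
      }
    }
    if (is.na(hrv_low)) {
      say("window %d: HRV undetermined; defaulting attention flag to FALSE", k)
      hrv_low <- FALSE
    }
    bp_k <- bp_flags[k]
    if (is.na(bp_k) && !is.null(cfg$snn_model) && !is.null(cfg$phi)) {
      bp_k <- classify_bp(cfg$snn_model, cfg$phi[[k]])$flag[1L] == 1L
    }
    eye_k <- eye_flags[k]
    if (is.na(eye_k) && !is.null(cfg$eye_model) && !is.null(cfg$eye_patches)) {
      pred <- classify_eye(cfg$eye_model, cfg$eye_patches[[k]])
      eye_k <- mean(pred$state == "drowsy") > 0.5
    }
    sal_k <- sal_flags[k]
    if (is.na(sal_k) && !is.null(cfg$boxes) && !is.null(cfg$salience)) {
      sal_k <- length(filter_salient_boxes(cfg$boxes[[k]], cfg$salience)) > 0L
    }
    if (is.na(bp_k)) say("window %d: blood-pressure flag unknown; defaulting to FALSE", k)
    if (is.na(eye_k)) say("window %d: eye-state flag unknown; defaulting to FALSE", k)
    if (is.na(sal_k)) say("window %d: salience flag unknown; defaulting to FALSE", k)
    inp <- suppressWarnings(risk_inputs(hrv_low, bp_k, eye_k, sal_k))
    risk <- assess_risk(inp)
    rows[[k]] <- data.frame(window = k, t_start = t0, t_end = t1,
                            source = source, lf_hf = ratio,
                            hrv_low = inp$hrv_low_attention,
                            bp_abnormal = inp$bp_abnormal,
                            eye_low = inp$eye_low_attention,
                            salient = inp$salient_pedestrians,
                            level = risk$level)
  }
  structure(list(windows = do.call(rbind, rows), log = log),
            class = "dsds_report")
}

#' @export
print.dsds_report <- function(x, ...) {
  cat(sprintf("<dsds_report> %d windows; levels: %s\n",
              nrow(x$windows),
              paste(sprintf("%s=%d", names(table(x$windows$level)),
                            table(x$windows$level)), collapse = ", ")))
  print(x$windows[, c("window", "t_start", "source", "lf_hf", "level")])
  invisible(x)
}
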