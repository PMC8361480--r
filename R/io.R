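#' Write and read PPG series as CSV
#'
#' Two-column CSV (`t` seconds, `value` a.u.).
#'
#' @param x a `ppg_record` or `ppg_waveform`.
#' @param path output file.
#' @export
write_ppg_csv <- function(x, path) {
  if (inherits(x, "ppg_record")) {
    df <- data.frame(t = x$t, value = x$samples)
  } else if (inherits(x, "ppg_waveform")) {
    df <- data.frame(t = x$start_time + (seq_along(x$samples) - 1L) / x$fs,
                     value = x$samples)
  } else stop("unsupported object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppg_csv
#' @return for `read_ppg_csv`, a list with `t`, `samples` and the sampling
#'   rate inferred from the time column.
#' @export
read_ppg_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "value") %in% names(df)))
  list(t = df$t, samples = df$value, fs = 1 / stats::median(diff(df$t)))
}

#' Export detected fiducials as CSV
#'
#' One row per fiducial: `beat_index`, `name` (m1..m4), `t` (s), `y` (a.u.).
#'
#' @param waves list of `ppg_waveform`s with extrema.
#' @param path output file.
#' @export
write_extrema_csv <- function(waves, path) {
  rows <- lapply(seq_along(waves), function(k) {
    w <- waves[[k]]
    if (is.null(w$extrema)) return(NULL)
    cbind(beat_index = k, w$extrema)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a landmark series as CSV with a JSON metadata sidecar
#'
#' The CSV holds one frame per row (`t` plus one column per landmark); the
#' sidecar (`<path>.json`) records the frame rate, provider id and coupling
#' ground truth.
#'
#' @param ls a `landmark_series`.
#' @param path output CSV file.
#' @export
write_landmarks_csv <- function(ls, path) {
  df <- data.frame((seq_len(ls$n_frames) - 1L) / ls$fps, ls$intensities)
  names(df) <- c("t", sprintf("l%02d", seq_len(ls$n_landmarks)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fps = ls$fps, n_landmarks = ls$n_landmarks,
               provider_id = ls$provider_id, coupled = ls$coupled,
               gains = ls$gains)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write eye patches to PNG files
#'
#' @param patches list of 77x77 matrices in `[0, 1]`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return the written paths.
#' @export
write_eye_patches_png <- function(patches, dir, prefix = "eye") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(seq_along(patches), function(i) {
    p <- file.path(dir, sprintf("%s_%03d.png", prefix, i))
    png::writePNG(patches[[i]], p)
    p
  }, character(1))
}

#' @rdname write_eye_patches_png
#' @param path a PNG file.
#' @return for `read_eye_patch_png`, a grayscale matrix (luminance for RGB
#'   input).
#' @export
read_eye_patch_png <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 3L)
    im <- 0.2126 * im[, , 1L] + 0.7152 * im[, , 2L] + 0.0722 * im[, , 3L]
  im
}

#' Bounding boxes to and from JSON
#'
#' @param boxes list of `bounding_box` objects.
#' @param path JSON file.
#' @export
write_boxes_json <- function(boxes, path) {
  jsonlite::write_json(lapply(boxes, unclass), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_boxes_json
#' @export
read_boxes_json <- function(path) {
  make_toy_boxes(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Phi feature matrix to and from CSV
#'
#' 64 feature columns plus a `label` column.
#'
#' @param X matrix with 64 columns.
#' @param labels class labels.
#' @param path CSV file.
#' @export
write_phi_csv <- function(X, labels, path) {
  df <- data.frame(X)
  names(df) <- sprintf("phi%02d", seq_len(ncol(X)))
  df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phi_csv
#' @export
read_phi_csv <- function(path) {
  df <- utils::read.csv(path)
  list(X = as.matrix(df[, grep("^phi", names(df))]), y = factor(df$label))
}

#' Serialize a trained model with a JSON sidecar
#'
#' The weights go to an RDS file; a human-readable `<path>.json` sidecar
#' records the model class and its configuration (including the seed) for
#' provenance.
#'
#' @param model a `v2p_model`, `snn_model` or `eye_cnn`.
#' @param path output RDS path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(class = class(model)[1L])
  if (inherits(model, "v2p_model")) {
    meta$kind <- model$kind
    meta$config <- unclass(model$cfg)
    meta$normalization <- list(mu = as.list(model$mu_norm),
                               target = as.list(model$target_norm))
  } else if (inherits(model, "snn_model")) {
    meta$sizes <- model$sizes
    meta$optimizer <- model$optimizer
  } else if (inherits(model, "eye_cnn")) {
    meta$config <- unclass(model$cfg)
    meta$trained <- model$trained
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
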