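# Shared fixture builders. Everything is generated in code under fixed seeds.

make_clean_record <- function(duration = 10, fs = 50, seed = 2, noise_sd = 0, ...) {
  simulate_ppg(sim_config(duration = duration, fs = fs, mean_ibi = 1,
                          seed = seed, noise_sd = noise_sd, ...))
}

# Run segmentation + fiducial detection and score compliant beats against
# generator truth; returns per-fiducial absolute errors in samples.
fiducial_errors <- function(record, signal, fs) {
  segs <- lapply(segment_waveforms(signal, fs), detect_extrema)
  segs <- Filter(function(w) isTRUE(w$compliant), segs)
  errs <- numeric(0)
  for (w in segs) {
    b <- which.min(abs(record$beat_onsets - w$start_time))
    if (abs(record$beat_onsets[b] - w$start_time) * fs > 3) next
    tb <- record$true_extrema[record$true_extrema$beat == b, ]
    errs <- c(errs, abs(w$extrema$t - tb$t) * fs)
  }
  list(errors = errs, n_compliant = length(segs))
}

# LF/HF ratio from the generator's true beat onsets of one simulated record.
true_lfhf <- function(duration, lf_depth, hf_depth, seed, mean_ibi = 0.8, fs = 100) {
  cfg <- sim_config(duration = duration, fs = fs, mean_ibi = mean_ibi, seed = seed,
                    lf_mod = c(0.1, lf_depth), hf_mod = c(0.25, hf_depth))
  r <- simulate_ppg(cfg)
  band_powers(tachogram(ibi_series(r$beat_onsets)))$ratio
}

# A hand-built beat waveform with extrema placed directly (no detection).
hand_beat <- function(start_time, ys, ts_rel = c(0, 0.28, 0.46, 0.62), fs = 50) {
  ppg_waveform(rep(0.1, 50), fs, start_time = start_time,
               extrema = data.frame(name = c("m1", "m2", "m3", "m4"),
                                    t = start_time + ts_rel, y = ys),
               compliant = TRUE)
}
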