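# Small fixtures built in code; no data files.

tiny_recording <- function(n = 300, fs = 100, muscles = c("quadriceps",
                                                          "hamstring"),
                           seed = 1, t0 = 0, amplitude = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * length(muscles), sd = amplitude),
              ncol = length(muscles))
  new_recording(m, fs, channel_meta(muscles, "right"), t0 = t0)
}

constant_recording <- function(value, n, fs = 1000,
                               muscle = "biceps") {
  new_recording(matrix(value, nrow = n, ncol = 1),
                fs, channel_meta(muscle, "right"))
}

tone_recording <- function(freq, fs = 1000, dur = 2, amp = 1,
                           muscle = "quadriceps") {
  t <- (seq_len(dur * fs) - 1) / fs
  new_recording(matrix(amp * sin(2 * pi * freq * t), ncol = 1),
                fs, channel_meta(muscle, "right"))
}

# Hand-built envelope series for detector unit tests (values are the object
# of study, so the container is assembled directly).
toy_envelope <- function(rms, step_s = 0.1, window_s = 0.2,
                         muscle = "quadriceps") {
  ch <- channel_meta(muscle, "right")
  structure(
    tibble::tibble(time_s = step_s * seq_along(rms), channel = ch$label,
                   rms_mv = as.numeric(rms), mav_mv = as.numeric(rms),
                   ptp_mv = 2 * as.numeric(rms)),
    window_s = window_s, step_s = step_s, sample_rate = 1000, t0 = 0,
    channels = ch,
    class = c("semg_envelope", class(tibble::tibble())))
}

toy_events <- function(start_s, end_s, channel = "right_quadriceps") {
  tibble::tibble(channel = channel, muscle = "quadriceps", side = "right",
                 start_s = start_s, end_s = end_s,
                 baseline_mv = 3, floor_mv = 1, fold_drop = 3,
                 matched_fog_onset_s = NA_real_, lead_s = NA_real_)
}

# amplitude ratio of a steady tone after filtering, measured away from edges
steady_ratio <- function(rec_out, rec_in) {
  n <- nrow(rec_in)
  mid <- seq.int(floor(n / 4), ceiling(3 * n / 4))
  x <- signal_matrix(rec_in)[mid, 1]
  y <- signal_matrix(rec_out)[mid, 1]
  sqrt(mean(y^2) / mean(x^2))
}

run_detection_chain <- function(ses, cfg = detector_config(),
                                min_channels = 2) {
  filt <- bandpass(ses$recording)
  env <- sliding_features(filt)
  ev <- detect_precursors(env, cfg, ses$annotations)
  fused <- fuse_events(ev, min_channels = min_channels, cfg = cfg)
  fused <- match_events(fused, ses$annotations)
  fused <- fold_change(fused, env, ses$annotations)
  fused <- event_amplitude_scale(fused, filt)
  list(filtered = filt, envelope = env, raw_events = ev, events = fused,
       report = evaluate_detection(fused, ses$annotations))
}
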