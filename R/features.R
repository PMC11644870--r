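#' Sliding-window envelope features
#'
#' Computes per-window root-mean-square (RMS), mean absolute value (MAV) and
#' peak-to-peak (PTP) amplitude for every channel, using a 200 ms window slid
#' in 10-50 ms steps. The first window starts at the first sample; window
#' times are reported at the window centre; partial trailing windows are
#' dropped.
#'
#' @param rec An `semg_recording` (normally bandpass-conditioned first).
#' @param window_s Window length in seconds (default 0.2).
#' @param step_s Step between window starts in seconds; the supported range
#'   is 0.010-0.050 s (default 0.01). Set `override_step = TRUE` to step
#'   outside it.
#' @param override_step Allow steps outside the supported range.
#' @return A long tibble of class `semg_envelope` with columns `time_s`
#'   (window centre), `channel`, `rms_mv`, `mav_mv`, `ptp_mv`; window/step,
#'   sampling rate, channel metadata and filter provenance are carried as
#'   attributes.
#' @examples
#' rec <- new_recording(matrix(rnorm(3000), ncol = 1), 1000,
#'                      channel_meta("biceps", "right"))
#' env <- sliding_features(rec)
#' @export
sliding_features <- function(rec, window_s = 0.2, step_s = 0.01,
                             override_step = FALSE) {
  fs <- sample_rate(rec)
  wn <- as.integer(round(window_s * fs))
  sn <- as.integer(round(step_s * fs))
  if (step_s > window_s) {
    abort("step_s must not exceed window_s (windows must tile without gaps)")
  }
  if (wn < 2L) abort("window must span at least 2 samples")
  if (sn < 1L) abort("step must span at least 1 sample")
  if (!override_step && (step_s < 0.010 - 1e-12 || step_s > 0.050 + 1e-12)) {
    abort("step_s outside the supported 0.010-0.050 s range; set override_step = TRUE to force")
  }
  n <- nrow(rec)
  empty <- tibble::tibble(time_s = numeric(0), channel = character(0),
                          rms_mv = numeric(0), mav_mv = numeric(0),
                          ptp_mv = numeric(0))
  if (wn > n) {
    warn("window longer than recording; returning an empty envelope series")
    return(as_envelope(empty, rec, window_s, step_s))
  }
  starts <- seq.int(1L, n - wn + 1L, by = sn)
  times <- rec$time_s[starts] + (wn - 1) / (2 * fs)
  m <- signal_matrix(rec)
  labels <- channel_labels(rec)
  out <- purrr::map(seq_along(labels), function(j) {
    x <- m[, j]
    f <- vapply(starts, function(i) {
      w <- x[i:(i + wn - 1L)]
      c(sqrt(mean(w * w)), mean(abs(w)), max(w) - min(w))
    }, numeric(3))
    tibble::tibble(time_s = times, channel = labels[j],
                   rms_mv = f[1, ], mav_mv = f[2, ], ptp_mv = f[3, ])
  })
  as_envelope(bind_rows(out), rec, window_s, step_s)
}

as_envelope <- function(df, rec, window_s, step_s) {
  structure(df,
            window_s = window_s, step_s = step_s,
            sample_rate = sample_rate(rec), t0 = recording_t0(rec),
            channels = recording_channels(rec),
            filter_spec = attr(rec, "filter_spec"),
            class = c("semg_envelope", class(tibble::tibble())))
}

#' Threshold-normalized training load
#'
#' Summarizes how much activity a session contained relative to a reference
#' isometric contraction: the time integral of the RMS envelope over the
#' annotated active intervals (curl sets and/or walking bouts), divided by
#' the isometric threshold amplitude. Units are threshold-normalized
#' activity-seconds; RMS held at the threshold for 30 active seconds gives a
#' load of 30.
#'
#' @param env An `semg_envelope`.
#' @param isometric_threshold_mv Reference contraction amplitude in mV (> 0).
#' @param track An `semg_annotations` track supplying the active intervals.
#' @param active Which interval kinds count as active (default set + walk).
#' @return Tibble with columns `channel`, `load`.
#' @export
training_load <- function(env, isometric_threshold_mv, track,
                          active = c("set", "walk")) {
  if (!is.numeric(isometric_threshold_mv) || isometric_threshold_mv <= 0) {
    abort("isometric_threshold_mv must be > 0")
  }
  iv <- bind_rows(lapply(active, function(k) annotation_intervals(track, k)))
  step_s <- attr(env, "step_s")
  keep <- in_intervals(env$time_s, iv)
  if (!any(keep)) {
    warn("no envelope windows fall in an active interval; load is 0")
  }
  env |>
    mutate(.active = keep) |>
    group_by(.data$channel) |>
    summarise(load = step_s * sum(.data$rms_mv[.data$.active]) /
                isometric_threshold_mv, .groups = "drop")
}
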