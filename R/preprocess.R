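#' Bandpass filter specification
#'
#' The default matches the standard sEMG conditioning chain: a 15-450 Hz
#' Butterworth bandpass of overall order 4, applied forward-backward
#' (zero phase). A causal single-pass mode is provided for simulated
#' real-time replay.
#'
#' @param low_hz Lower band edge in Hz (default 15).
#' @param high_hz Upper band edge in Hz (default 450).
#' @param order Overall filter order; even (default 4).
#' @param mode `"zero_phase"` (forward-backward, no group delay) or
#'   `"causal"` (single pass).
#' @param notch_hz Optional powerline notch frequency (off by default).
#' @return A list of class `semg_filter_spec`.
#' @export
filter_spec <- function(low_hz = 15, high_hz = 450, order = 4,
                        mode = c("zero_phase", "causal"), notch_hz = NULL) {
  mode <- match.arg(mode)
  if (!(low_hz > 0 && low_hz < high_hz)) abort("need 0 < low_hz < high_hz")
  if (order %% 2 != 0 || order < 2) abort("order must be a positive even integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 mode = mode, notch_hz = notch_hz),
            class = "semg_filter_spec")
}

# Odd-reflection padding then one (causal) or two (zero-phase) IIR passes.
filt_channel <- function(x, b, a, mode, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xp <- c(left, x, right)
  } else xp <- x
  y <- as.numeric(signal::filter(b, a, xp))
  if (mode == "zero_phase") y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

#' Bandpass-condition a recording
#'
#' Applies the Butterworth bandpass per channel (plus the optional notch when
#' `spec$notch_hz` is set). Zero-phase mode introduces no group delay; shape,
#' sampling rate and time base are unchanged.
#'
#' @param rec An `semg_recording`; its sampling rate must exceed
#'   `2 * spec$high_hz`.
#' @param spec A [filter_spec()].
#' @return The filtered recording, with the filter settings stored in
#'   attribute `"filter_spec"`.
#' @examples
#' rec <- new_recording(matrix(rnorm(2000), ncol = 1), 1000,
#'                      channel_meta("quadriceps", "right"))
#' filt <- bandpass(rec)
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  fs <- sample_rate(rec)
  if (fs <= 2 * spec$high_hz) {
    abort(sprintf(paste0("sample rate %g Hz violates the Nyquist requirement ",
                         "for a %g Hz band edge (need fs > %g Hz)"),
                  fs, spec$high_hz, 2 * spec$high_hz))
  }
  bf <- signal::butter(spec$order / 2L, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  pad <- as.integer(min(nrow(rec) - 1L, round(3 * fs / spec$low_hz)))
  m <- signal_matrix(rec)
  for (j in seq_len(ncol(m))) {
    m[, j] <- filt_channel(m[, j], bf$b, bf$a, spec$mode, pad)
  }
  out <- with_signals(rec, m, extra_attr = list(filter_spec = spec))
  if (!is.null(spec$notch_hz)) out <- notch(out, spec$notch_hz)
  out
}

#' Powerline notch filter
#'
#' Zero-phase biquad notch (constant-Q design) for removing a narrow
#' interference line, typically 60 Hz mains pickup, while leaving nearby
#' physiological frequencies essentially untouched.
#'
#' @param rec An `semg_recording`.
#' @param notch_hz Notch centre frequency in Hz (default 60); must be below
#'   Nyquist.
#' @param q Quality factor; bandwidth is `notch_hz / q` (default 30).
#' @return The filtered recording.
#' @export
notch <- function(rec, notch_hz = 60, q = 30) {
  fs <- sample_rate(rec)
  if (notch_hz >= fs / 2) abort("notch_hz must be below the Nyquist frequency")
  if (q <= 0) abort("q must be positive")
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  pad <- as.integer(min(nrow(rec) - 1L, round(3 * fs / notch_hz * q)))
  m <- signal_matrix(rec)
  for (j in seq_len(ncol(m))) {
    m[, j] <- filt_channel(m[, j], b, a, "zero_phase", pad)
  }
  with_signals(rec, m,
               extra_attr = list(filter_spec = attr(rec, "filter_spec")))
}
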