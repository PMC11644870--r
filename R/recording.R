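.semg_muscles <- c("quadriceps", "hamstring", "tibialis_anterior",
                   "gastrocnemius", "biceps")
.semg_sides <- c("left", "right")

#' Channel metadata for an sEMG recording
#'
#' Describes which muscle each electrode pair sits over. Labels default to
#' `"<side>_<muscle>"`; custom labels must keep that prefix so they remain
#' representable in the recording CSV dialect.
#'
#' @param muscle Character vector; one of `"quadriceps"`, `"hamstring"`,
#'   `"tibialis_anterior"`, `"gastrocnemius"`, `"biceps"`.
#' @param side `"left"` or `"right"` (recycled against `muscle`).
#' @param label Optional free-text channel labels; defaults to
#'   `"<side>_<muscle>"`.
#' @return A tibble with columns `muscle`, `side`, `label`.
#' @examples
#' channel_meta(c("quadriceps", "hamstring"), "right")
#' @export
channel_meta <- function(muscle, side, label = NULL) {
  ch <- tibble::tibble(muscle = as.character(muscle),
                       side = as.character(side))
  bad <- setdiff(unique(ch$muscle), .semg_muscles)
  if (length(bad) > 0) {
    abort(paste0("unknown muscle(s): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(ch$side), .semg_sides)
  if (length(bad) > 0) {
    abort(paste0("unknown side(s): ", paste(bad, collapse = ", ")))
  }
  ch$label <- if (is.null(label)) paste(ch$side, ch$muscle, sep = "_") else
    as.character(label)
  pre <- paste(ch$side, ch$muscle, sep = "_")
  if (any(substr(ch$label, 1, nchar(pre)) != pre)) {
    abort("channel labels must start with '<side>_<muscle>'")
  }
  if (anyDuplicated(ch$label) > 0 || anyDuplicated(ch[c("muscle", "side", "label")]) > 0) {
    abort("(muscle, side, label) must be unique within a recording")
  }
  ch
}

#' Construct an sEMG recording
#'
#' A recording is a tibble with a `time_s` column and one amplitude column
#' (mV) per channel, carrying the sampling rate, the session-clock offset
#' and the channel metadata as attributes.
#'
#' @param signals Numeric matrix (samples in rows, channels in columns) or a
#'   data frame of amplitudes in millivolts. `NaN`/`Inf` values are rejected.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param channels Channel metadata from [channel_meta()]; one row per
#'   column of `signals`.
#' @param t0 Session-clock time of the first sample, in seconds.
#' @return A tibble of class `semg_recording`.
#' @examples
#' rec <- new_recording(matrix(rnorm(200), ncol = 2), 100,
#'                      channel_meta(c("quadriceps", "hamstring"), "right"))
#' @export
new_recording <- function(signals, sample_rate, channels, t0 = 0) {
  m <- as.matrix(signals)
  storage.mode(m) <- "double"
  if (ncol(m) < 1L) abort("a recording needs at least one channel")
  if (nrow(m) < 1L) abort("a recording needs at least one sample")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be a single positive number (Hz)")
  }
  if (!is.finite(t0)) abort("t0 must be finite")
  if (!is.data.frame(channels) ||
      !all(c("muscle", "side", "label") %in% names(channels))) {
    abort("channels must come from channel_meta()")
  }
  if (nrow(channels) != ncol(m)) {
    abort("channels must have one row per signal column")
  }
  if (any(!is.finite(m))) {
    abort("signal amplitudes must be finite (no NaN/Inf)")
  }
  out <- tibble::tibble(time_s = t0 + (seq_len(nrow(m)) - 1) / sample_rate)
  for (j in seq_len(ncol(m))) out[[channels$label[j]]] <- m[, j]
  structure(out,
            sample_rate = sample_rate, t0 = t0,
            channels = tibble::as_tibble(channels),
            class = c("semg_recording", class(tibble::tibble())))
}

#' @rdname new_recording
#' @param rec An `semg_recording`.
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate")

#' @rdname new_recording
#' @export
recording_channels <- function(rec) attr(rec, "channels")

#' @rdname new_recording
#' @export
channel_labels <- function(rec) attr(rec, "channels")$label

#' @rdname new_recording
#' @export
recording_t0 <- function(rec) attr(rec, "t0")

#' Extract the channels-in-columns signal matrix of a recording
#'
#' @param rec An `semg_recording`.
#' @return Numeric matrix, samples in rows, one column per channel label.
#' @export
signal_matrix <- function(rec) {
  m <- as.matrix(as.data.frame(rec)[, channel_labels(rec), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Replace the signal columns, keeping time base and metadata.
with_signals <- function(rec, m, extra_attr = NULL) {
  out <- new_recording(m, sample_rate(rec), recording_channels(rec),
                       recording_t0(rec))
  out$time_s <- rec$time_s   # preserve stored times bit-for-bit
  for (nm in names(extra_attr)) attr(out, nm) <- extra_attr[[nm]]
  out
}

#' @export
print.semg_recording <- function(x, ...) {
  ch <- recording_channels(x)
  cat(sprintf("<semg_recording> %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              nrow(ch), nrow(x), sample_rate(x), recording_t0(x)))
  cat("channels:", paste(ch$label, collapse = ", "), "\n")
  NextMethod()
}
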