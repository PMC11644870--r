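.semg_labels <- c("walk_start", "walk_end", "fog_onset", "fog_end",
                  "pause_start", "pause_end", "set_start", "set_end")

#' Build an annotation track of timestamped session events
#'
#' Events (FOG onset/end, walk/pause/set boundaries) live on the session
#' clock in seconds; a `frame_index` records provenance when the timestamp
#' was taken from the synchronized video feed.
#'
#' @param label Character vector of event labels; one of `walk_start`,
#'   `walk_end`, `fog_onset`, `fog_end`, `pause_start`, `pause_end`,
#'   `set_start`, `set_end`.
#' @param start_s Event time in seconds (session clock).
#' @param end_s Optional event end time in seconds (`NA` for instantaneous
#'   events such as `fog_onset`).
#' @param frame_index Optional non-negative video frame index.
#' @param video_fps Video frame rate used for frame/clock conversion
#'   (frames per second, default 33).
#' @return A tibble of class `semg_annotations`, sorted by `start_s`.
#' @examples
#' annotations(c("walk_start", "fog_onset", "fog_end", "walk_end"),
#'             c(0, 12, 14.5, 50))
#' @export
annotations <- function(label, start_s, end_s = NA_real_,
                        frame_index = NA_integer_, video_fps = 33) {
  tr <- tibble::tibble(label = as.character(label),
                       start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s),
                       frame_index = as.integer(frame_index))
  bad <- setdiff(unique(tr$label), .semg_labels)
  if (length(bad) > 0) {
    abort(paste0("unknown event label(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(tr$start_s))) abort("start_s must be finite")
  if (any(!is.na(tr$frame_index) & tr$frame_index < 0)) {
    abort("frame_index must be >= 0")
  }
  if (!is.numeric(video_fps) || video_fps <= 0) abort("video_fps must be > 0")
  tr <- arrange(tr, .data$start_s, .data$label)
  onsets <- tr$start_s[tr$label == "fog_onset"]
  ends <- tr$start_s[tr$label == "fog_end"]
  if (length(ends) > length(onsets)) {
    abort("more fog_end events than fog_onset events")
  }
  if (length(ends) > 0 && any(ends < onsets[seq_along(ends)])) {
    abort("fog_end must not precede its matching fog_onset")
  }
  structure(tr, video_fps = video_fps,
            class = c("semg_annotations", class(tibble::tibble())))
}

#' Convert video frame indices to seconds
#'
#' @param frame_index Non-negative integer vector of frame indices.
#' @param fps Video frame rate in frames/s (default 33).
#' @return Time in seconds, `frame_index / fps`.
#' @examples
#' frame_to_seconds(33)    # 1 s of video at 33 frames/s
#' frame_to_seconds(99, 33)
#' @export
frame_to_seconds <- function(frame_index, fps = 33) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    abort("fps must be a single positive number")
  }
  if (any(!is.finite(frame_index)) || any(frame_index < 0)) {
    abort("frame_index must be non-negative")
  }
  as.numeric(frame_index) / fps
}

#' Shift an annotation track onto the sensor clock
#'
#' Reconciles the video/event clock with the sensor clock by adding a fixed
#' offset to every event time. Frame indices are left untouched.
#'
#' @param track An `semg_annotations` track.
#' @param offset_s Finite clock offset in seconds (added to all times).
#' @return The shifted track.
#' @export
align_clocks <- function(track, offset_s) {
  if (!is.numeric(offset_s) || length(offset_s) != 1L || !is.finite(offset_s)) {
    abort("offset_s must be a single finite number")
  }
  annotations(track$label, track$start_s + offset_s,
              track$end_s + offset_s, track$frame_index,
              video_fps = attr(track, "video_fps") %||% 33)
}

#' Paired annotation intervals of a given kind
#'
#' Pairs `<kind>_start`/`<kind>_end` (or `fog_onset`/`fog_end`) events in
#' time order into intervals.
#'
#' @param track An `semg_annotations` track.
#' @param kind One of `"walk"`, `"fog"`, `"pause"`, `"set"`.
#' @return Tibble with columns `start_s`, `end_s` (one row per interval).
#' @export
annotation_intervals <- function(track, kind = c("walk", "fog", "pause", "set")) {
  kind <- match.arg(kind)
  lab <- switch(kind, fog = c("fog_onset", "fog_end"),
                paste0(kind, c("_start", "_end")))
  s <- track$start_s[track$label == lab[1]]
  e <- track$start_s[track$label == lab[2]]
  k <- min(length(s), length(e))
  tibble::tibble(start_s = s[seq_len(k)], end_s = e[seq_len(k)])
}

# TRUE for each x inside any [start_s, end_s) interval of `iv`
in_intervals <- function(x, iv, closed_right = FALSE) {
  if (nrow(iv) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(iv))) {
    hit <- hit | if (closed_right) (x >= iv$start_s[i] & x <= iv$end_s[i]) else
      (x >= iv$start_s[i] & x < iv$end_s[i])
  }
  hit
}
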