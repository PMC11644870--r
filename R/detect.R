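#' Precursor-detector configuration
#'
#' A precursor alert opens when the window RMS falls below `drop_fraction`
#' of a causal rolling baseline and closes (with hysteresis) when it climbs
#' back above `drop_fraction + hysteresis` of the baseline. Candidate drops
#' separated by less than `refractory_s` are merged (so chatter at the close
#' threshold cannot fragment one sustained drop), then merged drops shorter
#' than `min_duration_s` are discarded -- the reported precursor signature
#' persists for more than 3 s.
#'
#' @param drop_fraction Alert threshold as a fraction of baseline, in (0, 1)
#'   (default 0.5: halfway between normal variation and the reported 3-fold
#'   drop).
#' @param min_duration_s Minimum sustained-drop duration in seconds
#'   (default 3).
#' @param baseline_window_s Trailing baseline window in seconds (default 10).
#' @param baseline_stat Rolling statistic: `"median"` (default) or
#'   `"trimmed_mean"` (20% trim).
#' @param refractory_s Merge events separated by less than this (default 2).
#' @param hysteresis Close-threshold margin above `drop_fraction`
#'   (default 0.1).
#' @return A list of class `semg_detector_config`.
#' @export
detector_config <- function(drop_fraction = 0.5, min_duration_s = 3,
                            baseline_window_s = 10,
                            baseline_stat = c("median", "trimmed_mean"),
                            refractory_s = 2, hysteresis = 0.1) {
  baseline_stat <- match.arg(baseline_stat)
  if (!(drop_fraction > 0 && drop_fraction < 1)) {
    abort("drop_fraction must be in (0, 1)")
  }
  if (min_duration_s <= 0) abort("min_duration_s must be > 0")
  if (baseline_window_s <= 0) abort("baseline_window_s must be > 0")
  if (refractory_s < 0) abort("refractory_s must be >= 0")
  if (hysteresis < 0) abort("hysteresis must be >= 0")
  structure(list(drop_fraction = drop_fraction,
                 min_duration_s = min_duration_s,
                 baseline_window_s = baseline_window_s,
                 baseline_stat = baseline_stat,
                 refractory_s = refractory_s, hysteresis = hysteresis),
            class = "semg_detector_config")
}

# Causal single pass over one channel segment: trailing-baseline with
# in-drop exclusion plus the open/close hysteresis state machine.
detector_pass <- function(time_s, rms, cfg, seed_baseline) {
  n <- length(rms)
  baseline <- numeric(n)
  in_drop <- logical(n)
  stat <- switch(cfg$baseline_stat,
                 median = stats::median,
                 trimmed_mean = function(v) mean(v, trim = 0.2))
  buf_t <- numeric(0)
  buf_v <- numeric(0)
  open <- FALSE
  thr_close <- cfg$drop_fraction + cfg$hysteresis
  for (i in seq_len(n)) {
    if (length(buf_t) > 0) {
      keep <- buf_t >= time_s[i] - cfg$baseline_window_s
      if (!keep[1]) {
        buf_t <- buf_t[keep]
        buf_v <- buf_v[keep]
      }
    }
    b <- if (time_s[i] - time_s[1] < cfg$baseline_window_s) seed_baseline
    else if (length(buf_v) == 0) baseline[i - 1]
    else stat(buf_v)
    baseline[i] <- b
    if (!open) {
      if (rms[i] < cfg$drop_fraction * b) open <- TRUE
    } else if (rms[i] >= thr_close * b) {
      open <- FALSE
    }
    in_drop[i] <- open
    if (!open) {
      buf_t <- c(buf_t, time_s[i])
      buf_v <- c(buf_v, rms[i])
    }
  }
  list(baseline = baseline, in_drop = in_drop)
}

# Active-interval table for detection: walk + set spans; whole series if the
# track is NULL or carries neither.
active_intervals <- function(track, env) {
  if (is.null(track)) {
    return(tibble::tibble(start_s = min(env$time_s) - 1,
                          end_s = max(env$time_s) + 1))
  }
  iv <- bind_rows(annotation_intervals(track, "walk"),
                  annotation_intervals(track, "set"))
  if (nrow(iv) == 0) {
    iv <- tibble::tibble(start_s = min(env$time_s) - 1,
                         end_s = max(env$time_s) + 1)
  }
  arrange(iv, .data$start_s)
}

#' Causal rolling baseline of the RMS envelope
#'
#' Trailing `baseline_window_s` statistic (median by default) of the window
#' RMS, excluding windows currently inside a candidate drop so the baseline
#' does not chase the drop itself; the first `baseline_window_s` is seeded
#' with the global active-period median.
#'
#' @param env An `semg_envelope`.
#' @param cfg A [detector_config()].
#' @param track Optional annotation track restricting the computation to
#'   active (walk/set) intervals.
#' @return Tibble with columns `time_s`, `channel`, `rms_mv`, `baseline_mv`,
#'   `in_drop`.
#' @export
rolling_baseline <- function(env, cfg = detector_config(), track = NULL) {
  if (nrow(env) == 0) abort("envelope series is empty")
  iv <- active_intervals(track, env)
  out <- lapply(split(tibble::as_tibble(env), env$channel), function(ch) {
    act <- ch[in_intervals(ch$time_s, iv, closed_right = TRUE), ]
    if (nrow(act) == 0) return(NULL)
    seed <- median(act$rms_mv)
    seg_id <- cumsum(c(TRUE, diff(act$time_s) > 2 * attr(env, "step_s") + 1e-9))
    bind_rows(lapply(split(seq_len(nrow(act)), seg_id), function(idx) {
      s <- act[idx, ]
      p <- detector_pass(s$time_s, s$rms_mv, cfg, seed)
      tibble::tibble(time_s = s$time_s, channel = s$channel,
                     segment = seg_id[idx], rms_mv = s$rms_mv,
                     baseline_mv = p$baseline, in_drop = p$in_drop)
    }))
  })
  bind_rows(out)
}

#' Detect sustained envelope drops (FOG precursors)
#'
#' Scans the RMS envelope of each channel for spans that stay below
#' `drop_fraction` of the causal rolling baseline for at least
#' `min_duration_s`. Event `start_s`/`end_s` give the signal-time support of
#' the below-threshold windows (first window centre minus half a window,
#' etc.), matching the convention that the lead time runs from the start of
#' the low-activity span.
#'
#' @inheritParams rolling_baseline
#' @return A tibble of class `semg_events` with columns `channel`, `muscle`,
#'   `side`, `start_s`, `end_s`, `baseline_mv` (baseline at opening),
#'   `floor_mv` (mean in-event RMS), `fold_drop` (`baseline_mv / floor_mv`),
#'   `matched_fog_onset_s`, `lead_s` (both `NA` until [match_events()]).
#' @export
detect_precursors <- function(env, cfg = detector_config(), track = NULL) {
  rb <- rolling_baseline(env, cfg, track)
  half_w <- attr(env, "window_s") / 2
  step_s <- attr(env, "step_s")
  meta <- attr(env, "channels")
  out <- lapply(split(rb, paste(rb$channel, rb$segment)), function(ch) {
    r <- rle(ch$in_drop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) == 0) return(NULL)
    ev <- tibble::tibble(
      s = starts[runs], e = ends[runs],
      start_s = ch$time_s[starts[runs]] - half_w,
      end_s = ch$time_s[ends[runs]] + half_w,
      baseline_mv = ch$baseline_mv[starts[runs]])
    # refractory merge first so threshold chatter inside one sustained drop
    # cannot fragment it below the persistence limit; a lone short dip still
    # fails the duration filter afterwards
    merged <- ev[1, ]
    if (nrow(ev) > 1) {
      for (i in 2:nrow(ev)) {
        last <- nrow(merged)
        if (ev$start_s[i] - merged$end_s[last] < cfg$refractory_s) {
          merged$end_s[last] <- ev$end_s[i]
          merged$e[last] <- ev$e[i]
        } else {
          merged <- bind_rows(merged, ev[i, ])
        }
      }
    }
    merged <- merged[merged$end_s - merged$start_s >= cfg$min_duration_s, ]
    if (nrow(merged) == 0) return(NULL)
    merged$floor_mv <- vapply(seq_len(nrow(merged)), function(i) {
      mean(ch$rms_mv[merged$s[i]:merged$e[i]])
    }, 0)
    merged$channel <- ch$channel[1]
    merged |>
      mutate(fold_drop = .data$baseline_mv / .data$floor_mv) |>
      select(-"s", -"e")
  })
  ev <- bind_rows(out)
  if (nrow(ev) == 0) {
    ev <- tibble::tibble(channel = character(0), start_s = numeric(0),
                         end_s = numeric(0), baseline_mv = numeric(0),
                         floor_mv = numeric(0), fold_drop = numeric(0))
  }
  ev <- left_join(ev, meta[c("label", "muscle", "side")],
                  by = c(channel = "label"))
  ev <- ev[ev$fold_drop > 1 | is.na(ev$fold_drop), ]
  ev$matched_fog_onset_s <- NA_real_
  ev$lead_s <- NA_real_
  structure(arrange(ev, .data$start_s, .data$channel),
            cfg = cfg, window_s = attr(env, "window_s"), step_s = step_s,
            class = c("semg_events", class(tibble::tibble())))
}

#' Fuse per-channel events into session-level events
#'
#' The consistent precursor signature sits on the thigh channels, so a
#' session-level event requires the drop to co-occur on at least
#' `min_channels` of the named muscles (default quadriceps + hamstring).
#' The fused interval is the span where the per-channel events overlap.
#'
#' @param events An `semg_events` tibble from [detect_precursors()].
#' @param min_channels Minimum number of distinct channels that must be in a
#'   drop simultaneously (default 2; use 1 for single-channel mode).
#' @param muscles Muscles eligible for fusion.
#' @param cfg The [detector_config()] (for the persistence filter on the
#'   fused interval); defaults to the config stored on `events`.
#' @return An `semg_events` tibble whose `channel` concatenates the fused
#'   labels.
#' @export
fuse_events <- function(events, min_channels = 2,
                        muscles = c("quadriceps", "hamstring"),
                        cfg = NULL) {
  cfg <- cfg %||% attr(events, "cfg") %||% detector_config()
  ev <- events[events$muscle %in% muscles, ]
  empty <- structure(
    tibble::tibble(channel = character(0), muscle = character(0),
                   side = character(0), start_s = numeric(0),
                   end_s = numeric(0), baseline_mv = numeric(0),
                   floor_mv = numeric(0), fold_drop = numeric(0),
                   matched_fog_onset_s = numeric(0), lead_s = numeric(0)),
    cfg = cfg, window_s = attr(events, "window_s"),
    step_s = attr(events, "step_s"),
    class = c("semg_events", class(tibble::tibble())))
  if (nrow(ev) == 0) return(empty)
  pts <- sort(unique(c(ev$start_s, ev$end_s)))
  if (length(pts) < 2) return(empty)
  mids <- (pts[-1] + pts[-length(pts)]) / 2
  cover <- vapply(mids, function(m) {
    length(unique(ev$channel[ev$start_s <= m & ev$end_s >= m]))
  }, 0L)
  hit <- cover >= min_channels
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  fused <- tibble::tibble(start_s = pts[starts[keep]],
                          end_s = pts[ends[keep] + 1L])
  fused <- fused[fused$end_s - fused$start_s >= cfg$min_duration_s, ]
  if (nrow(fused) == 0) return(empty)
  fused <- purrr::pmap(fused, function(start_s, end_s) {
    part <- ev[ev$start_s <= end_s & ev$end_s >= start_s, ]
    tibble::tibble(
      channel = paste(sort(unique(part$channel)), collapse = "+"),
      muscle = "fused", side = NA_character_,
      start_s = start_s, end_s = end_s,
      baseline_mv = mean(part$baseline_mv),
      floor_mv = mean(part$floor_mv),
      fold_drop = mean(part$baseline_mv) / mean(part$floor_mv),
      matched_fog_onset_s = NA_real_, lead_s = NA_real_)
  }) |> bind_rows()
  structure(fused, cfg = cfg, window_s = attr(events, "window_s"),
            step_s = attr(events, "step_s"),
            class = c("semg_events", class(tibble::tibble())))
}

#' Match detected events to annotated FOG onsets
#'
#' Each event is matched, in time order, to the earliest still-unmatched
#' `fog_onset` lying in `(start_s, start_s + horizon_s]`; an onset is claimed
#' by at most one event (the earliest event wins). The lead time is
#' `matched_fog_onset_s - start_s`.
#'
#' @param events An `semg_events` tibble.
#' @param track An `semg_annotations` track containing `fog_onset` events.
#' @param horizon_s Matching horizon in seconds (default 10).
#' @return `events` with `matched_fog_onset_s` and `lead_s` filled where a
#'   match exists.
#' @export
match_events <- function(events, track, horizon_s = 10) {
  onsets <- sort(track$start_s[track$label == "fog_onset"])
  taken <- rep(FALSE, length(onsets))
  events <- arrange(events, .data$start_s)
  events$matched_fog_onset_s <- NA_real_
  events$lead_s <- NA_real_
  for (i in seq_len(nrow(events))) {
    cand <- which(!taken & onsets > events$start_s[i] &
                    onsets <= events$start_s[i] + horizon_s)
    if (length(cand) > 0) {
      j <- cand[1]
      taken[j] <- TRUE
      events$matched_fog_onset_s[i] <- onsets[j]
      events$lead_s[i] <- onsets[j] - events$start_s[i]
    }
  }
  events
}

#' Fold change of normal activity over a detected event
#'
#' Ratio of the mean RMS envelope over normal-walking reference windows
#' (active intervals excluding every detected event span and every annotated
#' FOG span, with one window-length guard margin) to the mean RMS inside the
#' event -- the "nearly 3-fold drop" statistic. The peak-to-peak ratio is
#' reported alongside.
#'
#' @param events An `semg_events` tibble (fused or per-channel).
#' @param env The `semg_envelope` the events were detected on.
#' @param track The annotation track (for active and FOG intervals).
#' @return `events` with `fold_change` and `ptp_fold_change` columns added;
#'   `NA` with a warning if no reference windows remain.
#' @export
fold_change <- function(events, env, track) {
  act <- active_intervals(track, env)
  guard <- attr(env, "window_s") %||% 0.2
  excl <- bind_rows(
    tibble::tibble(start_s = events$start_s - guard,
                   end_s = events$end_s + guard),
    annotation_intervals(track, "fog"))
  events$fold_change <- NA_real_
  events$ptp_fold_change <- NA_real_
  for (i in seq_len(nrow(events))) {
    chans <- strsplit(events$channel[i], "+", fixed = TRUE)[[1]]
    e <- env[env$channel %in% chans, ]
    ref <- e[in_intervals(e$time_s, act, closed_right = TRUE) &
               !in_intervals(e$time_s, excl, closed_right = TRUE), ]
    inside <- e[e$time_s >= events$start_s[i] & e$time_s <= events$end_s[i], ]
    if (nrow(ref) == 0 || nrow(inside) == 0) {
      warn("no reference windows available for fold change")
      next
    }
    events$fold_change[i] <- mean(ref$rms_mv) / mean(inside$rms_mv)
    events$ptp_fold_change[i] <- mean(ref$ptp_mv) / mean(inside$ptp_mv)
  }
  events
}

#' Amplitude scale inside detected events
#'
#' The 95th-percentile absolute amplitude of the (filtered) signal within
#' each event interval, pooled over the event's channels -- the +/- mV scale
#' language of the precursor regime.
#'
#' @param events An `semg_events` tibble.
#' @param rec The (typically bandpass-filtered) `semg_recording`.
#' @param prob Quantile probability (default 0.95).
#' @return `events` with an `amp_scale_mv` column added.
#' @export
event_amplitude_scale <- function(events, rec, prob = 0.95) {
  m <- signal_matrix(rec)
  labels <- channel_labels(rec)
  events$amp_scale_mv <- vapply(seq_len(nrow(events)), function(i) {
    chans <- strsplit(events$channel[i], "+", fixed = TRUE)[[1]]
    chans <- intersect(chans, labels)
    rows <- rec$time_s >= events$start_s[i] & rec$time_s <= events$end_s[i]
    if (!any(rows) || length(chans) == 0) return(NA_real_)
    quantile(abs(as.numeric(m[rows, chans])), prob, names = FALSE)
  }, 0)
  events
}

#' Evaluate detection against ground-truth annotations
#'
#' @param events An `semg_events` tibble, after [match_events()].
#' @param track The ground-truth annotation track.
#' @return An object of class `semg_detection_report`: sensitivity (fraction
#'   of annotated onsets preceded by a matched event; `NA` when the track
#'   has no onsets), false alarms per active minute, and min/mean/max lead
#'   time. [glance()] returns the one-row metric tibble; [tidy()] the event
#'   table.
#' @export
evaluate_detection <- function(events, track) {
  onsets <- track$start_s[track$label == "fog_onset"]
  matched <- events[!is.na(events$lead_s), ]
  act <- bind_rows(annotation_intervals(track, "walk"),
                   annotation_intervals(track, "set"))
  active_min <- sum(act$end_s - act$start_s) / 60
  structure(list(
    events = events,
    n_onsets = length(onsets),
    n_matched = nrow(matched),
    n_false_alarms = nrow(events) - nrow(matched),
    sensitivity = if (length(onsets) == 0) NA_real_ else
      nrow(matched) / length(onsets),
    false_alarms_per_min = if (active_min > 0)
      (nrow(events) - nrow(matched)) / active_min else NA_real_,
    lead_min_s = if (nrow(matched) > 0) min(matched$lead_s) else NA_real_,
    lead_mean_s = if (nrow(matched) > 0) mean(matched$lead_s) else NA_real_,
    lead_max_s = if (nrow(matched) > 0) max(matched$lead_s) else NA_real_,
    active_minutes = active_min), class = "semg_detection_report")
}

#' @exportS3Method generics::glance
glance.semg_detection_report <- function(x, ...) {
  tibble::tibble(n_onsets = x$n_onsets, n_matched = x$n_matched,
                 n_false_alarms = x$n_false_alarms,
                 sensitivity = x$sensitivity,
                 false_alarms_per_min = x$false_alarms_per_min,
                 lead_min_s = x$lead_min_s, lead_mean_s = x$lead_mean_s,
                 lead_max_s = x$lead_max_s,
                 active_minutes = x$active_minutes)
}

#' @exportS3Method generics::tidy
tidy.semg_detection_report <- function(x, ...) tibble::as_tibble(x$events)

#' @export
print.semg_detection_report <- function(x, ...) {
  cat(sprintf(paste0("<semg_detection_report> %d/%d onsets matched ",
                     "(sensitivity %.2f), %.2f false alarms/min\n"),
              x$n_matched, x$n_onsets, x$sensitivity,
              x$false_alarms_per_min))
  if (x$n_matched > 0) {
    cat(sprintf("lead time (s): min %.2f / mean %.2f / max %.2f\n",
                x$lead_min_s, x$lead_mean_s, x$lead_max_s))
  }
  invisible(x)
}
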