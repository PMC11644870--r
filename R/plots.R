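#' Plot an sEMG recording
#'
#' One amplitude trace per channel, faceted, optionally overlaid with
#' annotated FOG spans.
#'
#' @param object An `semg_recording`.
#' @param track Optional `semg_annotations`; FOG intervals are shaded.
#' @param downsample Keep every k-th sample for plotting speed (default:
#'   chosen so ~5000 points per channel remain).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.semg_recording <- function(object, track = NULL, downsample = NULL,
                                    ...) {
  k <- downsample %||% max(1L, nrow(object) %/% 5000L)
  df <- tibble::as_tibble(object)[seq(1, nrow(object), by = k), ] |>
    tidyr::pivot_longer(-"time_s", names_to = "channel",
                        values_to = "amplitude_mv")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude_mv)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "#2166ac") +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "sEMG amplitude (mV)")
  if (!is.null(track)) {
    fog <- annotation_intervals(track, "fog")
    if (nrow(fog) > 0) {
      p <- p + ggplot2::geom_rect(
        data = fog, inherit.aes = FALSE, alpha = 0.2, fill = "red",
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf))
    }
  }
  p
}

#' Plot an envelope series with detected events
#'
#' RMS envelope per channel; detected precursor events are shaded red and
#' matched FOG onsets marked with green lines (the red-window / green-arrow
#' reading of a session).
#'
#' @param object An `semg_envelope`.
#' @param events Optional `semg_events` tibble to overlay.
#' @param baseline Optional output of [rolling_baseline()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.semg_envelope <- function(object, events = NULL, baseline = NULL,
                                   ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time_s, .data$rms_mv)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#2166ac") +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "window RMS (mV)")
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_line(
      data = tibble::as_tibble(baseline), linetype = "dashed",
      colour = "grey40",
      ggplot2::aes(.data$time_s, .data$baseline_mv))
  }
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(events)[c("start_s", "end_s")],
      inherit.aes = FALSE, alpha = 0.2, fill = "red",
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf))
    onsets <- events$matched_fog_onset_s
    onsets <- onsets[!is.na(onsets)]
    if (length(onsets) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = onsets,
                                   colour = "darkgreen")
    }
  }
  p
}

#' Plot a median-frequency series with its trend line
#'
#' @param object An `semg_mdf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.semg_mdf <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$mdf_hz), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mdf_hz)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "median frequency (Hz)")
}
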