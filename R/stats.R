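#' Classical one-way fixed-effects ANOVA
#'
#' F is the ratio of the between-group to the within-group mean square, with
#' the p-value from the F distribution. Needs at least two groups with at
#' least two values each. When every group has zero within-group variance
#' the statistic is degenerate: the result carries `degenerate = TRUE` with
#' `p_value = 0`.
#'
#' @param data A data frame of per-window (or per-episode) values.
#' @param value Column holding the response (e.g. window RMS in mV).
#' @param group Column holding the group label (e.g. activity state).
#' @return A one-row tibble: `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, `degenerate`.
#' @examples
#' d <- tibble::tibble(x = c(2, 3, 4, 6, 7, 8),
#'                     g = rep(c("a", "b"), each = 3))
#' one_way_anova(d, x, g)   # F = 24
#' @export
one_way_anova <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]
  g <- droplevels(g[ok])
  k <- nlevels(g)
  ni <- tabulate(g)
  if (k < 2) abort("one_way_anova needs at least 2 groups")
  if (any(ni < 2)) abort("every group needs at least 2 values")
  n <- length(v)
  gm <- mean(v)
  mi <- tapply(v, g, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((v - mi[g])^2)
  dfb <- k - 1L
  dfw <- n - k
  if (ssw == 0) {
    return(tibble::tibble(statistic = Inf, p_value = 0,
                          df_between = dfb, df_within = dfw,
                          degenerate = TRUE))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  tibble::tibble(statistic = f, p_value = pf(f, dfb, dfw, lower.tail = FALSE),
                 df_between = dfb, df_within = dfw, degenerate = FALSE)
}

#' Compare envelope activity between annotated states
#'
#' Assigns envelope windows to states by interval membership (windows
#' straddling an interval boundary are excluded), runs the one-way ANOVA
#' over the window populations, and reports the ratio of state means -- the
#' fold statistic behind the "3-fold drop" comparison. With
#' `unit = "episode"` the windows of each interval are first aggregated to
#' one mean RMS per interval, the sampling unit matching a per-episode
#' reading of n = 8.
#'
#' @param env An `semg_envelope`.
#' @param intervals Tibble with columns `state`, `start_s`, `end_s` defining
#'   the two (or more) state interval sets. Build it from
#'   [annotation_intervals()] (e.g. active vs pause) or from detected event
#'   spans (precursor vs normal).
#' @param unit `"window"` (default) or `"episode"`.
#' @param channels Optional channel labels to restrict to.
#' @return An object of class `semg_state_comparison`: the sample table, the
#'   ANOVA row and `fold` = mean(first state) / mean(second state), states
#'   ordered as first encountered in `intervals`. [tidy()] returns the
#'   samples, [glance()] the one-row summary.
#' @export
state_comparison <- function(env, intervals, unit = c("window", "episode"),
                             channels = NULL) {
  unit <- match.arg(unit)
  stopifnot(all(c("state", "start_s", "end_s") %in% names(intervals)))
  df <- tibble::as_tibble(env)
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  half_w <- (attr(env, "window_s") %||% 0.2) / 2
  samples <- purrr::pmap(
    list(intervals$state, intervals$start_s, intervals$end_s,
         seq_len(nrow(intervals))),
    function(state, s, e, id) {
      w <- df[df$time_s - half_w >= s & df$time_s + half_w <= e, ]
      if (nrow(w) == 0) return(NULL)
      tibble::tibble(state = state, interval_id = id,
                     channel = w$channel, time_s = w$time_s,
                     rms_mv = w$rms_mv)
    }) |> bind_rows()
  states <- unique(intervals$state)
  if (!all(states %in% samples$state)) {
    abort("a state has no envelope windows inside its intervals")
  }
  values <- if (unit == "episode") {
    samples |>
      group_by(.data$state, .data$interval_id) |>
      summarise(rms_mv = mean(.data$rms_mv), .groups = "drop")
  } else samples
  counts <- table(values$state)
  if (any(counts < 2)) {
    abort(paste0("state with fewer than 2 ", unit, "s: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  av <- one_way_anova(values, rms_mv, state)
  means <- tapply(values$rms_mv, factor(values$state, levels = states), mean)
  fold <- if (length(states) == 2) unname(means[1] / means[2]) else NA_real_
  structure(list(samples = samples, values = values, unit = unit,
                 states = states, anova = av, group_means = means,
                 fold = fold),
            class = "semg_state_comparison")
}

#' @exportS3Method generics::glance
glance.semg_state_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(unit = x$unit, fold = x$fold,
                   n_values = nrow(x$values)), x$anova)
}

#' @exportS3Method generics::tidy
tidy.semg_state_comparison <- function(x, ...) x$samples

#' @export
print.semg_state_comparison <- function(x, ...) {
  cat(sprintf(
    "<semg_state_comparison> %s vs %s (%s unit): F = %.3g, p = %.3g, fold = %.3g\n",
    x$states[1], paste(x$states[-1], collapse = "/"), x$unit,
    x$anova$statistic, x$anova$p_value, x$fold))
  invisible(x)
}

#' Interval table for a precursor-vs-normal comparison
#'
#' Detected event spans become the `precursor` state; the active intervals,
#' minus event and FOG spans (with one window guard margin), become the
#' `normal` state.
#'
#' @param events An `semg_events` tibble.
#' @param track The annotation track.
#' @param guard_s Guard margin subtracted around excluded spans (default
#'   0.2 s).
#' @return Tibble with columns `state`, `start_s`, `end_s`.
#' @export
precursor_intervals <- function(events, track, guard_s = 0.2) {
  act <- bind_rows(annotation_intervals(track, "walk"),
                   annotation_intervals(track, "set"))
  excl <- bind_rows(
    tibble::tibble(start_s = events$start_s - guard_s,
                   end_s = events$end_s + guard_s),
    annotation_intervals(track, "fog")) |>
    arrange(.data$start_s)
  normal <- act
  for (i in seq_len(nrow(excl))) {
    pieces <- list()
    for (j in seq_len(nrow(normal))) {
      s <- normal$start_s[j]; e <- normal$end_s[j]
      if (excl$end_s[i] <= s || excl$start_s[i] >= e) {
        pieces[[length(pieces) + 1]] <- c(s, e)
      } else {
        if (excl$start_s[i] > s) {
          pieces[[length(pieces) + 1]] <- c(s, excl$start_s[i])
        }
        if (excl$end_s[i] < e) {
          pieces[[length(pieces) + 1]] <- c(excl$end_s[i], e)
        }
      }
    }
    normal <- if (length(pieces) == 0) {
      tibble::tibble(start_s = numeric(0), end_s = numeric(0))
    } else {
      m <- do.call(rbind, pieces)
      tibble::tibble(start_s = m[, 1], end_s = m[, 2])
    }
  }
  # normal listed first so the comparison fold reads normal/precursor ~ 3
  bind_rows(
    tibble::tibble(state = "normal", start_s = normal$start_s,
                   end_s = normal$end_s),
    tibble::tibble(state = "precursor", start_s = events$start_s,
                   end_s = events$end_s))
}
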