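#' Median frequency of a signal window
#'
#' Estimates the frequency that splits the in-band power of a window's
#' Hann-tapered periodogram into equal halves, with linear interpolation
#' between frequency bins. When the cumulative power sits exactly at the
#' half-power level over a plateau (e.g. two well-separated spectral lines of
#' equal power), the midpoint of the plateau is returned, so an equal-power
#' 50 + 150 Hz pair yields ~100 Hz.
#'
#' @param x Numeric amplitude vector (>= 16 samples). The window mean is
#'   removed before the FFT.
#' @param fs Sampling rate in Hz.
#' @param band Analysis band in Hz; power outside it is ignored
#'   (default `c(15, 450)`, clipped to Nyquist).
#' @return Median frequency in Hz, or `NA_real_` for a window with no
#'   in-band power (the "no-power" sentinel, excluded from trends).
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)[-1]
#' median_frequency(sin(2 * pi * 100 * t), 1000)   # ~100 Hz
#' @export
median_frequency <- function(x, fs, band = c(15, 450)) {
  n <- length(x)
  if (n < 16L) abort("median_frequency needs at least 16 samples")
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  X <- fft(x * h)
  nf <- floor(n / 2)
  freq <- (1:nf) * fs / n
  P <- Mod(X[2:(nf + 1)])^2
  keep <- freq >= band[1] & freq <= min(band[2], fs / 2)
  freq <- freq[keep]; P <- P[keep]
  tot <- sum(P)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  cum <- cumsum(P)
  H <- tot / 2
  tol <- 1e-8 * tot
  interp_at <- function(i) {
    # crossing of level H inside the step up to bin i
    c0 <- if (i == 1L) 0 else cum[i - 1L]
    f0 <- if (i == 1L) freq[1] - fs / n else freq[i - 1L]
    if (cum[i] <= c0) return(freq[i])
    f0 + (H - c0) / (cum[i] - c0) * (freq[i] - f0)
  }
  lo <- which(cum >= H - tol)[1]       # first reach (ties count)
  hi <- which(cum > H + tol)[1]        # first strict exceed
  if (is.na(hi)) hi <- length(cum)
  (interp_at(lo) + interp_at(hi)) / 2
}

#' Sliding-window median-frequency series
#'
#' Windows the recording exactly as [sliding_features()] does, but with a
#' longer default window (1 s) so that the frequency bins are fine enough
#' near typical sEMG median frequencies (~80-120 Hz); 200 ms would give 5 Hz
#' bins. All-zero windows yield the `NA` no-power sentinel.
#'
#' @param rec An `semg_recording`.
#' @param window_s Spectral window length in seconds (default 1).
#' @param step_s Step in seconds (default 0.05).
#' @param band In-band power restriction in Hz (default `c(15, 450)`).
#' @return Long tibble of class `semg_mdf`: `time_s` (window centre),
#'   `channel`, `mdf_hz`.
#' @export
mdf_series <- function(rec, window_s = 1, step_s = 0.05, band = c(15, 450)) {
  fs <- sample_rate(rec)
  wn <- as.integer(round(window_s * fs))
  sn <- as.integer(round(step_s * fs))
  if (wn < 16L) abort("MDF window must span at least 16 samples")
  if (sn < 1L) abort("step must span at least 1 sample")
  n <- nrow(rec)
  empty <- tibble::tibble(time_s = numeric(0), channel = character(0),
                          mdf_hz = numeric(0))
  if (wn > n) {
    warn("window longer than recording; returning an empty MDF series")
    return(structure(empty, window_s = window_s, step_s = step_s, band = band,
                     channels = recording_channels(rec),
                     class = c("semg_mdf", class(tibble::tibble()))))
  }
  starts <- seq.int(1L, n - wn + 1L, by = sn)
  times <- rec$time_s[starts] + (wn - 1) / (2 * fs)
  m <- signal_matrix(rec)
  labels <- channel_labels(rec)
  out <- purrr::map(seq_along(labels), function(j) {
    x <- m[, j]
    mdf <- vapply(starts, function(i) {
      median_frequency(x[i:(i + wn - 1L)], fs, band)
    }, 0)
    tibble::tibble(time_s = times, channel = labels[j], mdf_hz = mdf)
  })
  structure(bind_rows(out), window_s = window_s, step_s = step_s, band = band,
            channels = recording_channels(rec),
            class = c("semg_mdf", class(tibble::tibble())))
}

#' Fatigue trend over a median-frequency series
#'
#' Ordinary least-squares line of MDF against time over an interval; a
#' declining median frequency indicates emerging muscle fatigue. Fatigue is
#' flagged when the slope is negative with two-sided p < 0.05.
#'
#' @param mdf An `semg_mdf` series.
#' @param interval Optional `c(start_s, end_s)` restricting the fit.
#' @param channel Optional channel label restricting the fit.
#' @return An object of class `semg_fatigue_trend`; see [tidy()] for the
#'   coefficient table and [glance()] for the one-row summary
#'   (`slope_hz_per_s`, `intercept_hz`, `p_value`, `fatigue`, `n_windows`).
#' @export
fatigue_trend <- function(mdf, interval = NULL, channel = NULL) {
  df <- tibble::as_tibble(mdf)
  if (!is.null(channel)) df <- df[df$channel %in% channel, ]
  if (!is.null(interval)) {
    df <- df[df$time_s >= interval[1] & df$time_s <= interval[2], ]
  }
  df <- df[is.finite(df$mdf_hz), ]
  if (nrow(df) < 5L) abort("fatigue_trend needs at least 5 valid MDF windows")
  fit <- lm(mdf_hz ~ time_s, data = df)
  # a noiseless series triggers the harmless perfect-fit warning
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) == 2L && !is.nan(sm[2, 4])) sm[2, 4] else NA_real_
  slope <- unname(coef(fit)[2])
  structure(list(model = fit, slope_hz_per_s = slope,
                 intercept_hz = unname(coef(fit)[1]), p_value = p,
                 fatigue = isTRUE(slope < 0 && !is.na(p) && p < 0.05),
                 n_windows = nrow(df), interval = interval, channel = channel),
            class = "semg_fatigue_trend")
}

#' @exportS3Method generics::tidy
tidy.semg_fatigue_trend <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
}

#' @exportS3Method generics::glance
glance.semg_fatigue_trend <- function(x, ...) {
  tibble::tibble(slope_hz_per_s = x$slope_hz_per_s,
                 intercept_hz = x$intercept_hz, p_value = x$p_value,
                 fatigue = x$fatigue, n_windows = x$n_windows)
}

#' @export
print.semg_fatigue_trend <- function(x, ...) {
  cat(sprintf(
    "<semg_fatigue_trend> slope %.3f Hz/s (p = %.3g, n = %d) -> %s\n",
    x$slope_hz_per_s, x$p_value, x$n_windows,
    if (x$fatigue) "fatigue" else "no fatigue flagged"))
  invisible(x)
}
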