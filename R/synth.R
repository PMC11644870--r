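#' Specify one synthetic freezing-of-gait episode
#'
#' The envelope attenuation begins `lead_s` seconds before the annotated FOG
#' onset (the precursor) and persists through the episode itself.
#'
#' @param onset_s FOG onset time in seconds (session clock).
#' @param duration_s Episode duration in seconds (> 0).
#' @param lead_s Precursor lead: the drop begins this many seconds before
#'   onset (>= 0).
#' @param attenuation Envelope multiplier in (0, 1] during precursor and
#'   episode; `NULL` (default) means `precursor_amplitude_mv /
#'   normal_amplitude_mv` of the session spec (1/3 at the defaults, i.e. a
#'   3-fold drop).
#' @return A list of class `semg_fog_episode`.
#' @export
fog_episode <- function(onset_s, duration_s, lead_s, attenuation = NULL) {
  if (duration_s <= 0) abort("duration_s must be > 0")
  if (lead_s < 0) abort("lead_s must be >= 0")
  if (!is.null(attenuation) && !(attenuation > 0 && attenuation <= 1)) {
    abort("attenuation must be in (0, 1]")
  }
  structure(list(onset_s = onset_s, duration_s = duration_s, lead_s = lead_s,
                 attenuation = attenuation), class = "semg_fog_episode")
}

#' Specify a synthetic walking session
#'
#' The generated signal is zero-mean Gaussian noise shaped to a 20-400 Hz
#' band (the standard sEMG surrogate), multiplied by a periodic gait-cycle
#' envelope, and scaled so that the 95th percentile of the absolute signal
#' during normal walking equals `normal_amplitude_mv` -- i.e. normal activity
#' oscillates within about +/-3 mV at the defaults, dropping to about
#' +/-1 mV during precursor/FOG spans when `attenuation = 1/3`.
#'
#' @param duration_s Session length in seconds.
#' @param sample_rate Sampling rate in Hz (default 1000; must exceed 900 so
#'   the 450 Hz analysis band edge stays below Nyquist).
#' @param channels Channel metadata (default: right quadriceps + hamstring,
#'   the thigh pair the detector fuses).
#' @param gait_cycle_s Stride period in seconds (default 1.1).
#' @param burst_duty Fraction of the cycle occupied by the activity burst
#'   (default 0.4).
#' @param burst_floor Tonic envelope level between bursts, as a fraction of
#'   the burst peak (default 0.7); models co-activation and keeps normal
#'   window RMS well separated from the precursor regime.
#' @param normal_amplitude_mv Normal-walking amplitude scale in mV
#'   (95th percentile of `|signal|`; default 3).
#' @param precursor_amplitude_mv Amplitude scale during precursor spans in mV
#'   (default 1); sets the default episode attenuation.
#' @param episodes List of [fog_episode()] specs (non-overlapping, inside the
#'   session).
#' @param powerline_mv 60 Hz interference amplitude in mV (default 0.05).
#' @param drift_mv Slow baseline-wander amplitude in mV (default 0.2;
#'   removed by the 15 Hz filter edge).
#' @param fatigue_compression_rate Per-second fractional decay of the upper
#'   spectral corner (default 0 = none).
#' @param seed RNG seed; identical specs generate bit-identical sessions.
#' @return A list of class `semg_session_spec`.
#' @export
session_spec <- function(duration_s, sample_rate = 1000,
                         channels = channel_meta(c("quadriceps", "hamstring"),
                                                 "right"),
                         gait_cycle_s = 1.1, burst_duty = 0.4,
                         burst_floor = 0.7,
                         normal_amplitude_mv = 3, precursor_amplitude_mv = 1,
                         episodes = list(), powerline_mv = 0.05,
                         drift_mv = 0.2, fatigue_compression_rate = 0,
                         seed = 1L) {
  spec <- structure(list(duration_s = duration_s, sample_rate = sample_rate,
                         channels = channels, gait_cycle_s = gait_cycle_s,
                         burst_duty = burst_duty, burst_floor = burst_floor,
                         normal_amplitude_mv = normal_amplitude_mv,
                         precursor_amplitude_mv = precursor_amplitude_mv,
                         episodes = episodes, powerline_mv = powerline_mv,
                         drift_mv = drift_mv,
                         fatigue_compression_rate = fatigue_compression_rate,
                         seed = as.integer(seed)),
                    class = "semg_session_spec")
  validate_session_spec(spec)
  spec
}

validate_session_spec <- function(spec) {
  if (spec$duration_s <= 0) abort("duration_s must be > 0")
  if (spec$sample_rate <= 900) {
    abort("sample_rate must exceed 900 Hz (450 Hz band edge below Nyquist)")
  }
  if (!(spec$burst_duty > 0 && spec$burst_duty < 1)) {
    abort("burst_duty must be in (0, 1)")
  }
  if (!(spec$burst_floor >= 0 && spec$burst_floor < 1)) {
    abort("burst_floor must be in [0, 1)")
  }
  eps <- spec$episodes
  if (length(eps) > 0) {
    default_att <- any(vapply(eps, function(e) is.null(e$attenuation), TRUE))
    if (default_att &&
        spec$precursor_amplitude_mv >= spec$normal_amplitude_mv) {
      abort("precursor_amplitude_mv must be < normal_amplitude_mv")
    }
    span <- t(vapply(eps, function(e) {
      c(e$onset_s - e$lead_s, e$onset_s + e$duration_s)
    }, numeric(2)))
    span <- span[order(span[, 1]), , drop = FALSE]
    if (any(span[, 1] <= 0) || any(span[, 2] >= spec$duration_s)) {
      abort("episodes (including precursor lead) must lie inside (0, duration_s)")
    }
    if (nrow(span) > 1 && any(span[-1, 1] < span[-nrow(span), 2])) {
      abort("episodes must not overlap")
    }
  }
  invisible(spec)
}

# Gaussian noise shaped to [low, corner] Hz; `corner` may be a per-sample
# vector (spectral fatigue compression), realized by overlap-added 1 s blocks
# filtered from one continuous white-noise stream.
shaped_noise <- function(n, fs, low = 20, corner = 400) {
  white <- rnorm(n)
  band_filter <- function(hi, len) {
    hi <- max(min(hi, 0.45 * fs), low + 10)
    signal::butter(2, c(low, hi) / (fs / 2), type = "pass")
  }
  one_pass <- function(x, bf) {
    filt_channel(x, bf$b, bf$a, "zero_phase",
                 pad = as.integer(min(length(x) - 1, round(3 * fs / low))))
  }
  if (length(corner) == 1L) return(one_pass(white, band_filter(corner)))
  stopifnot(length(corner) == n)
  L <- as.integer(round(fs)); hop <- L %/% 2L
  if (n <= L) return(one_pass(white, band_filter(mean(corner))))
  y <- numeric(n); wsum <- numeric(n)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 0.5) / L))
  for (s in seq.int(1L, n, by = hop)) {
    e <- min(s + L - 1L, n)
    mid <- s + (e - s) %/% 2L
    f <- one_pass(white[s:e], band_filter(corner[mid]))
    w <- win[seq_len(e - s + 1L)]
    y[s:e] <- y[s:e] + f * w
    wsum[s:e] <- wsum[s:e] + w
  }
  y / pmax(wsum, 0.05)
}

# Periodic gait envelope: tonic floor plus Hann-shaped bursts.
gait_envelope <- function(t, cycle_s, duty, floor_level, phase = 0) {
  u <- (t / cycle_s + phase) %% 1
  burst <- ifelse(u < duty, 0.5 * (1 - cos(2 * pi * u / duty)), 0)
  floor_level + (1 - floor_level) * burst
}

# Gait phase offsets by muscle: antagonists fire at different stride phases.
.gait_phase <- c(quadriceps = 0, hamstring = 0.5, tibialis_anterior = 0.25,
                 gastrocnemius = 0.75, biceps = 0)

#' Generate a synthetic walking session with embedded FOG episodes
#'
#' @param spec A [session_spec()].
#' @return A list with elements `recording` (an `semg_recording`),
#'   `annotations` (walk boundaries plus `fog_onset`/`fog_end` per episode)
#'   and `episodes` (a tibble of ground-truth onset, duration, lead and
#'   attenuation for parameter-recovery checks).
#' @examples
#' ses <- generate_session(session_spec(20, seed = 7))
#' @export
generate_session <- function(spec) {
  validate_session_spec(spec)
  set.seed(spec$seed)
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  att <- rep(1, n)
  eps <- spec$episodes
  default_att <- spec$precursor_amplitude_mv / spec$normal_amplitude_mv
  ep_tbl <- tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                           lead_s = numeric(0), attenuation = numeric(0))
  for (e in eps) {
    a <- e$attenuation %||% default_att
    att[t >= e$onset_s - e$lead_s & t < e$onset_s + e$duration_s] <- a
    ep_tbl <- bind_rows(ep_tbl, tibble::tibble(
      onset_s = e$onset_s, duration_s = e$duration_s, lead_s = e$lead_s,
      attenuation = a))
  }
  corner <- if (spec$fatigue_compression_rate > 0) {
    400 * exp(-spec$fatigue_compression_rate * t)
  } else 400
  ch <- spec$channels
  m <- matrix(0, n, nrow(ch))
  for (j in seq_len(nrow(ch))) {
    carrier <- shaped_noise(n, fs, 20, corner)
    env <- gait_envelope(t, spec$gait_cycle_s, spec$burst_duty,
                         spec$burst_floor, .gait_phase[[ch$muscle[j]]])
    raw <- carrier * env
    scale <- spec$normal_amplitude_mv /
      quantile(abs(raw[att == 1]), 0.95, names = FALSE)
    x <- raw * scale * att
    x <- x + spec$powerline_mv * sin(2 * pi * 60 * t + runif(1, 0, 2 * pi))
    x <- x + spec$drift_mv * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi))
    m[, j] <- x
  }
  track <- annotations(
    label = c("walk_start",
              rep(c("fog_onset", "fog_end"), nrow(ep_tbl)), "walk_end"),
    start_s = c(0, as.numeric(rbind(ep_tbl$onset_s,
                                    ep_tbl$onset_s + ep_tbl$duration_s)),
                spec$duration_s))
  list(recording = new_recording(m, fs, ch, t0 = 0),
       annotations = track, episodes = ep_tbl, spec = spec)
}

#' Specify a synthetic bicep-curl protocol session
#'
#' Mirrors the benchmarking routine used for healthy-subject testing:
#' 10 s pause, 30 s of curls, 30 s pause, then a second set of curls; burst
#' activity occurs only inside sets, pauses sit near the noise floor, and a
#' positive `fatigue_compression_rate` shrinks the upper spectral corner
#' exponentially with accumulated active time, driving the median frequency
#' down across the second set.
#'
#' @param pause1_s,set1_s,pause2_s,set2_s Phase durations in seconds
#'   (defaults 10, 30, 30, 30).
#' @param rep_period_s Curl repetition period in seconds (default 4).
#' @param fatigue_compression_rate Per-active-second fractional decay of the
#'   spectral corner (default 0.01).
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param amplitude_mv Active-burst amplitude scale in mV (default 3).
#' @param noise_floor_mv Pause-phase noise amplitude in mV (default 0.05).
#' @return A list of class `semg_curl_spec`.
#' @export
curl_spec <- function(pause1_s = 10, set1_s = 30, pause2_s = 30, set2_s = 30,
                      rep_period_s = 4, fatigue_compression_rate = 0.01,
                      sample_rate = 1000, amplitude_mv = 3,
                      noise_floor_mv = 0.05) {
  d <- c(pause1_s, set1_s, pause2_s, set2_s)
  if (any(d <= 0)) abort("all protocol durations must be > 0")
  if (rep_period_s <= 0) abort("rep_period_s must be > 0")
  structure(list(pause1_s = pause1_s, set1_s = set1_s, pause2_s = pause2_s,
                 set2_s = set2_s, rep_period_s = rep_period_s,
                 fatigue_compression_rate = fatigue_compression_rate,
                 sample_rate = sample_rate, amplitude_mv = amplitude_mv,
                 noise_floor_mv = noise_floor_mv),
            class = "semg_curl_spec")
}

#' Generate a synthetic bicep-curl session
#'
#' @param spec A [curl_spec()].
#' @param seed RNG seed.
#' @return A list with `recording` (right-biceps channel), `annotations`
#'   (pause/set boundaries) and `protocol` (interval tibble).
#' @export
generate_curl_session <- function(spec = curl_spec(), seed = 1L) {
  set.seed(as.integer(seed))
  fs <- spec$sample_rate
  b <- cumsum(c(0, spec$pause1_s, spec$set1_s, spec$pause2_s, spec$set2_s))
  duration <- b[5]
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  active <- (t >= b[2] & t < b[3]) | (t >= b[4] & t < b[5])
  rate <- spec$fatigue_compression_rate
  corner <- if (rate > 0) 400 * exp(-rate * cumsum(active) / fs) else 400
  carrier <- shaped_noise(n, fs, 20, corner)
  u <- (t / spec$rep_period_s) %% 1
  rep_env <- 0.1 + 0.9 * ifelse(u < 0.5, 0.5 * (1 - cos(2 * pi * u / 0.5)), 0)
  env <- ifelse(active, rep_env, 0)
  raw <- carrier * env
  scale <- spec$amplitude_mv / quantile(abs(raw[active]), 0.95, names = FALSE)
  floor_noise <- shaped_noise(n, fs, 20, 450)
  floor_noise <- floor_noise * spec$noise_floor_mv /
    quantile(abs(floor_noise), 0.95, names = FALSE)
  x <- raw * scale + floor_noise
  ch <- channel_meta("biceps", "right")
  track <- annotations(
    label = c("pause_start", "pause_end", "set_start", "set_end",
              "pause_start", "pause_end", "set_start", "set_end"),
    start_s = c(b[1], b[2], b[2], b[3], b[3], b[4], b[4], b[5]))
  list(recording = new_recording(matrix(x, ncol = 1), fs, ch, t0 = 0),
       annotations = track,
       protocol = tibble::tibble(
         phase = c("pause1", "set1", "pause2", "set2"),
         start_s = b[1:4], end_s = b[2:5]),
       spec = spec)
}

#' The default three-session synthetic cohort
#'
#' Three fixed-seed walking sessions carrying 4, 2 and 2 FOG episodes (eight
#' in total), each with the default 1/3 envelope attenuation (3 mV normal
#' scale dropping to 1 mV) and precursor leads drawn uniformly from
#' 3-4.5 s. Regeneration is bit-identical.
#'
#' @return A list of three session lists as returned by [generate_session()].
#' @export
default_cohort <- function() {
  seeds <- c(101L, 202L, 303L)
  n_eps <- c(4L, 2L, 2L)
  purrr::map2(seeds, n_eps, function(seed, k) {
    set.seed(seed + 7L)
    onsets <- 25 + 30 * (seq_len(k) - 1)
    leads <- runif(k, 3, 4.5)
    durs <- runif(k, 2, 6)
    eps <- purrr::pmap(list(onsets, durs, leads), fog_episode)
    generate_session(session_spec(
      duration_s = max(onsets + durs) + 12, episodes = eps, seed = seed))
  })
}
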