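test_that("sessions are deterministic under a seed and differ across seeds", {
  spec <- session_spec(4, seed = 11)
  a <- generate_session(spec)
  b <- generate_session(spec)
  expect_identical(signal_matrix(a$recording), signal_matrix(b$recording))
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
  c <- generate_session(session_spec(4, seed = 12))
  expect_false(identical(signal_matrix(a$recording),
                         signal_matrix(c$recording)))
})

test_that("normal walking amplitude is calibrated to the target scale", {
  ses <- generate_session(session_spec(20, powerline_mv = 0, drift_mv = 0,
                                       seed = 5))
  p95 <- apply(abs(signal_matrix(ses$recording)), 2, quantile, 0.95)
  expect_true(all(abs(p95 - 3) / 3 < 0.10))
})

test_that("realized envelope scale is proportional to normal_amplitude_mv", {
  scales <- c(1.5, 3, 6)
  rms <- vapply(scales, function(a) {
    ses <- generate_session(session_spec(
      10, normal_amplitude_mv = a, precursor_amplitude_mv = a / 3,
      powerline_mv = 0, drift_mv = 0, seed = 21,
      channels = channel_meta("quadriceps", "right")))
    sqrt(mean(signal_matrix(ses$recording)^2))
  }, 0)
  slope <- rms / scales
  expect_true(all(abs(slope / slope[2] - 1) < 0.05))
})

test_that("attenuation 1.0 leaves precursor spans indistinguishable", {
  diffs <- vapply(1:20, function(s) {
    ses <- generate_session(session_spec(
      16, episodes = list(fog_episode(12, 2, 2, attenuation = 1.0)),
      powerline_mv = 0, drift_mv = 0, seed = 300 + s,
      channels = channel_meta("quadriceps", "right")))
    env <- sliding_features(ses$recording, step_s = 0.05)
    pre <- env$rms_mv[env$time_s >= 10 & env$time_s < 14]
    norm <- env$rms_mv[env$time_s >= 2 & env$time_s < 10]
    mean(pre) - mean(norm)
  }, 0)
  # Monte-Carlo error band around zero for the mean difference over seeds
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("invalid episode layouts are rejected", {
  expect_error(generate_session(session_spec(
    30, episodes = list(fog_episode(10, 5, 3), fog_episode(13, 5, 3)))),
    "overlap")
  expect_error(generate_session(session_spec(
    20, episodes = list(fog_episode(18, 5, 3)))), "inside")
  expect_error(session_spec(10, normal_amplitude_mv = 1,
                            precursor_amplitude_mv = 2,
                            episodes = list(fog_episode(5, 2, 1))),
               "precursor_amplitude_mv")
  expect_error(fog_episode(10, 2, 1, attenuation = 1.5), "attenuation")
})

test_that("curl protocol produces the documented phase boundaries", {
  cs <- generate_curl_session(curl_spec(), seed = 2)
  starts <- cs$annotations$start_s[cs$annotations$label %in%
                                     c("pause_start", "set_start")]
  expect_equal(sort(unique(starts)), c(0, 10, 40, 70))
  expect_equal(cs$protocol$end_s[4], 100)
  # bursts confined to sets; pauses near the noise floor
  env <- sliding_features(bandpass(cs$recording), step_s = 0.05)
  set_rms <- mean(env$rms_mv[in_intervals(
    env$time_s, annotation_intervals(cs$annotations, "set"))])
  pause_rms <- mean(env$rms_mv[in_intervals(
    env$time_s, annotation_intervals(cs$annotations, "pause"))])
  expect_gt(set_rms / pause_rms, 10)
})

test_that("curl fatigue compression drives median frequency down", {
  # no-fatigue control: set2 slope consistent with zero
  cs0 <- generate_curl_session(curl_spec(fatigue_compression_rate = 0),
                               seed = 4)
  mdf0 <- mdf_series(bandpass(cs0$recording), step_s = 0.25)
  tr0 <- fatigue_trend(mdf0, interval = c(70, 100))
  expect_gt(tr0$p_value, 0.05)
  expect_false(tr0$fatigue)
  # fatigued arm declines from early set1 to late set2
  cs1 <- generate_curl_session(curl_spec(), seed = 4)
  mdf1 <- tibble::as_tibble(mdf_series(bandpass(cs1$recording), step_s = 0.25))
  early <- mean(mdf1$mdf_hz[mdf1$time_s >= 10 & mdf1$time_s < 15],
                na.rm = TRUE)
  late <- mean(mdf1$mdf_hz[mdf1$time_s >= 95 & mdf1$time_s < 100],
               na.rm = TRUE)
  expect_lt(late, early)
})

test_that("the default cohort embeds eight episodes with 3-4.5 s leads", {
  cohort <- default_cohort()
  eps <- dplyr::bind_rows(lapply(cohort, `[[`, "episodes"))
  expect_equal(vapply(cohort, function(s) nrow(s$episodes), 0L), c(4L, 2L, 2L))
  expect_equal(nrow(eps), 8L)
  expect_true(all(eps$lead_s >= 3 & eps$lead_s <= 4.5))
  expect_true(all(eps$attenuation == 1 / 3))
  onsets <- vapply(cohort, function(s) {
    sum(s$annotations$label == "fog_onset")
  }, 0L)
  expect_equal(sum(onsets), 8L)
  # regeneration is bit-identical
  again <- default_cohort()
  for (i in 1:3) {
    expect_identical(signal_matrix(cohort[[i]]$recording),
                     signal_matrix(again[[i]]$recording))
  }
})
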