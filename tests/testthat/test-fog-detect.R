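test_that("rolling baseline tracks constant envelopes and excludes drops", {
  cfg <- detector_config(baseline_window_s = 1, min_duration_s = 0.5)
  # constant envelope
  rb <- rolling_baseline(toy_envelope(rep(3, 30)), cfg)
  expect_true(all(rb$baseline_mv == 3))
  expect_true(all(!rb$in_drop))

  # hand-simulated 30-window toy: 3 mV, step down to 1 mV, back to 3 mV.
  # The global median seeds the first second; afterwards the trailing median
  # excludes in-drop windows, so the baseline holds at 3 mV throughout.
  env <- toy_envelope(c(rep(3, 12), rep(1, 8), rep(3, 10)))
  rb <- rolling_baseline(env, cfg)
  expect_equal(rb$baseline_mv, rep(3, 30))
  expect_equal(which(rb$in_drop), 13:20)

  # all-zero envelope: zero baseline, nothing detected downstream
  rb0 <- rolling_baseline(toy_envelope(rep(0, 30)), cfg)
  expect_true(all(rb0$baseline_mv == 0))
  ev0 <- detect_precursors(toy_envelope(rep(0, 30)), cfg)
  expect_equal(nrow(ev0), 0)
})

test_that("only sustained drops become events", {
  cfg <- detector_config()   # min duration 3 s
  expect_equal(nrow(detect_precursors(toy_envelope(rep(3, 200)), cfg)), 0)
  # 2 s dip: persistence filter discards it (2 < 3 s)
  dip2 <- toy_envelope(c(rep(3, 120), rep(1, 20), rep(3, 60)))
  expect_equal(nrow(detect_precursors(dip2, cfg)), 0)
  # 4.5 s dip: one event with the documented geometry
  dip45 <- toy_envelope(c(rep(3, 120), rep(1, 45), rep(3, 35)))
  ev <- detect_precursors(dip45, cfg)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$end_s - ev$start_s, 3)
  expect_equal(ev$fold_drop, 3, tolerance = 1e-9)
  expect_equal(ev$start_s, 12.1 - 0.1)   # support of first low window
})

test_that("hand-simulated detector run matches the state-machine output", {
  cfg <- detector_config(baseline_window_s = 1, min_duration_s = 0.5)
  env <- toy_envelope(c(rep(3, 12), rep(1, 8), rep(3, 10)))
  ev <- detect_precursors(env, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 1.2)   # window 13 center 1.3 minus half window
  expect_equal(ev$end_s, 2.1)     # window 20 center 2.0 plus half window
  expect_equal(ev$baseline_mv, 3)
  expect_equal(ev$floor_mv, 1)
  expect_equal(ev$fold_drop, 3)
})

test_that("every synthetic episode yields exactly one event per channel", {
  ses <- generate_session(session_spec(
    70, episodes = list(fog_episode(25, 5, 4), fog_episode(55, 5, 4)),
    seed = 44))
  chain <- run_detection_chain(ses)
  per_channel <- table(chain$raw_events$channel)
  expect_true(all(per_channel == 2))
  expect_equal(nrow(chain$events), 2)      # fused across the thigh pair
  expect_true(all(chain$events$end_s - chain$events$start_s >= 3))
  expect_equal(chain$report$sensitivity, 1)
  expect_equal(chain$report$n_false_alarms, 0)
})

test_that("event matching pairs each onset with the earliest event once", {
  track <- annotations(c("walk_start", "fog_onset", "walk_end"),
                       c(0, 13.5, 60))
  ev <- match_events(toy_events(10, 13.2), track)
  expect_equal(ev$lead_s, 3.5)
  expect_equal(ev$matched_fog_onset_s, 13.5)
  # no onset within the horizon
  ev <- match_events(toy_events(40, 45), track)
  expect_true(is.na(ev$lead_s))
  # two events competing for one onset: the earlier wins
  ev <- match_events(toy_events(c(6, 10), c(9.5, 13.2)), track)
  expect_equal(ev$matched_fog_onset_s, c(13.5, NA))
  # three-event enumeration with two onsets
  track2 <- annotations(c("walk_start", "fog_onset", "fog_onset", "walk_end"),
                        c(0, 13.5, 24, 60))
  ev <- match_events(toy_events(c(6, 10, 21), c(9.5, 13.2, 23.5)), track2)
  expect_equal(ev$matched_fog_onset_s, c(13.5, NA, 24))
  expect_equal(ev$lead_s, c(7.5, NA, 3))
})

test_that("fold change compares the event floor against clean reference", {
  env <- toy_envelope(c(rep(3, 100), rep(1, 40), rep(3, 100)))
  track <- annotations(c("walk_start", "walk_end"), c(0, 25))
  ev <- toy_events(10.05, 14.05)   # support of the low windows only
  out <- fold_change(ev, env, track)
  expect_equal(out$fold_change, 3, tolerance = 0.01)
  # null control: flat envelope gives a ratio of 1
  out1 <- fold_change(ev, toy_envelope(rep(2, 240)), track)
  expect_equal(out1$fold_change, 1, tolerance = 1e-9)
})

test_that("detection report arithmetic is exact", {
  track <- annotations(c("walk_start", "fog_onset", "fog_onset", "walk_end"),
                       c(0, 20, 40, 60))
  ev <- match_events(toy_events(c(16, 50), c(19.5, 54)), track)
  rep1 <- evaluate_detection(ev, track)
  expect_equal(rep1$sensitivity, 0.5)
  expect_equal(rep1$n_false_alarms, 1)
  expect_equal(rep1$false_alarms_per_min, 1)
  expect_equal(rep1$lead_mean_s, 4)
  empty <- evaluate_detection(toy_events(numeric(0), numeric(0)), track)
  expect_equal(empty$sensitivity, 0)
  no_onsets <- evaluate_detection(
    toy_events(numeric(0), numeric(0)),
    annotations(c("walk_start", "walk_end"), c(0, 60)))
  expect_true(is.na(no_onsets$sensitivity))
})

test_that("stricter drop fractions never add events", {
  env <- toy_envelope(c(rep(3, 120), rep(1.4, 45), rep(3, 40),
                        rep(0.8, 40), rep(3, 40)))
  counts <- vapply(c(0.6, 0.5, 0.4, 0.3), function(df) {
    nrow(detect_precursors(env, detector_config(drop_fraction = df)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("emitted events always satisfy their invariants", {
  set.seed(17)
  for (k in 1:20) {
    rms <- abs(3 + cumsum(rnorm(300, sd = 0.4)))
    if (k %% 2 == 0) rms[sample(50:250, 1) + 0:39] <- runif(1, 0, 0.5)
    cfg <- detector_config(min_duration_s = 2)
    ev <- detect_precursors(toy_envelope(rms), cfg)
    if (nrow(ev) > 0) {
      expect_true(all(ev$end_s - ev$start_s >= cfg$min_duration_s))
      expect_true(all(ev$fold_drop > 1))
      expect_true(all(ev$floor_mv < ev$baseline_mv))
    }
  }
})

test_that("null sessions with unit attenuation stay silent", {
  quiet <- vapply(1:5, function(s) {
    ses <- generate_session(session_spec(
      30, episodes = list(fog_episode(20, 3, 3, attenuation = 1.0)),
      seed = 600 + s))
    chain <- run_detection_chain(ses)
    nrow(chain$events) == 0
  }, TRUE)
  expect_true(all(quiet))
})

test_that("fold change recovers the generator attenuation", {
  folds <- vapply(1:5, function(s) {
    ses <- generate_session(session_spec(
      50, episodes = list(fog_episode(25, 5, 4, attenuation = 0.5)),
      seed = 700 + s))
    chain <- run_detection_chain(ses)
    if (nrow(chain$events) == 0) return(NA_real_)
    mean(chain$events$fold_change)
  }, 0)
  expect_true(all(is.finite(folds)))
  expect_lt(abs(mean(folds) - 2) / 2, 0.15)
})
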