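test_that("constant signals have closed-form window features", {
  rec <- constant_recording(2, 1000)
  env <- sliding_features(rec)
  expect_true(all(env$rms_mv == 2))
  expect_true(all(env$mav_mv == 2))
  expect_true(all(env$ptp_mv == 0))
})

test_that("the window count follows the tiling formula", {
  rec <- tiny_recording(n = 10000, fs = 1000, muscles = "quadriceps")
  env <- sliding_features(rec, 0.2, 0.01)
  expect_equal(nrow(env), 981)          # floor((10 - 0.2)/0.01) + 1
  expect_equal(diff(env$time_s)[1], 0.01)
  expect_true(all(abs(diff(env$time_s) - 0.01) < 1e-12))
})

test_that("windowed features match an independent brute-force loop exactly", {
  set.seed(99)
  for (k in 1:30) {
    fs <- sample(c(100, 200, 250), 1)
    n <- sample(100:400, 1)
    rec <- tiny_recording(n = n, fs = fs, muscles = "gastrocnemius",
                          seed = 1000 + k)
    window_s <- 0.2
    step_s <- sample(c(0.01, 0.02, 0.05), 1)
    env <- sliding_features(rec, window_s, step_s)
    x <- signal_matrix(rec)[, 1]
    wn <- round(window_s * fs); sn <- round(step_s * fs)
    i <- 1; rms <- mav <- ptp <- numeric(0)
    while (i + wn - 1 <= n) {
      w <- x[i:(i + wn - 1)]
      rms <- c(rms, sqrt(mean(w^2)))
      mav <- c(mav, mean(abs(w)))
      ptp <- c(ptp, max(w) - min(w))
      i <- i + sn
    }
    expect_identical(env$rms_mv, rms)
    expect_identical(env$mav_mv, mav)
    expect_identical(env$ptp_mv, ptp)
  }
})

test_that("feature inequalities and amplitude equivariance hold", {
  for (k in 1:10) {
    rec <- tiny_recording(n = 600, fs = 500, seed = 200 + k)
    env <- sliding_features(rec, 0.2, 0.05)
    expect_true(all(env$rms_mv >= env$mav_mv))
    expect_true(all(env$mav_mv >= 0 & env$ptp_mv >= 0))
    scaled <- new_recording(-2 * signal_matrix(rec), 500,
                            recording_channels(rec))
    env2 <- sliding_features(scaled, 0.2, 0.05)
    expect_identical(env2$rms_mv, 2 * env$rms_mv)
    expect_identical(env2$mav_mv, 2 * env$mav_mv)
    expect_identical(env2$ptp_mv, 2 * env$ptp_mv)
  }
})

test_that("window configuration is validated", {
  rec <- tiny_recording(n = 500, fs = 100, muscles = "biceps")
  expect_error(sliding_features(rec, 0.2, 0.3), "tile")
  expect_error(sliding_features(rec, 0.2, 0.2), "supported")
  expect_silent(sliding_features(rec, 0.2, 0.2, override_step = TRUE))
  expect_warning(env <- sliding_features(rec, 10, 0.05), "longer than")
  expect_equal(nrow(env), 0)
})

test_that("training load integrates threshold-normalized RMS over active time", {
  rec <- constant_recording(1.5, 40000)   # 40 s at 1.5 mV
  env <- sliding_features(rec)
  track <- annotations(c("set_start", "set_end"), c(5, 35))
  load <- training_load(env, 1.5, track)
  expect_equal(load$load, 30)              # RMS at threshold for 30 s
  expect_equal(training_load(env, 3, track)$load, 15)
  expect_warning(
    load0 <- training_load(env, 1.5,
                           annotations(c("set_start", "set_end"),
                                       c(100, 101))),
    "no envelope windows|active")
  expect_equal(load0$load, 0)
})

test_that("curl sessions accumulate load in sets, not pauses", {
  cs <- generate_curl_session(curl_spec(), seed = 6)
  env <- sliding_features(bandpass(cs$recording), step_s = 0.05)
  set1 <- annotations(c("set_start", "set_end"), c(10, 40))
  pause1 <- annotations(c("set_start", "set_end"), c(0, 10))
  expect_gt(training_load(env, 1, set1)$load,
            10 * training_load(env, 1, pause1)$load)
})
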