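test_that("one-way ANOVA reproduces hand-computed tables", {
  d <- tibble::tibble(x = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  res <- one_way_anova(d, x, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # hand ANOVA table: groups {2,3,4} vs {6,7,8}; MSB = 24, MSW = 1
  d <- tibble::tibble(x = c(2, 3, 4, 6, 7, 8), g = rep(c("a", "b"), each = 3))
  res <- one_way_anova(d, x, g)
  expect_equal(res$statistic, 24)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$p_value, pf(24, 1, 4, lower.tail = FALSE))
})

test_that("ANOVA agrees with the reference linear-model decomposition", {
  set.seed(23)
  for (k in 1:20) {
    ng <- sample(2:4, 1)
    d <- tibble::tibble(
      g = rep(letters[1:ng], times = sample(4:9, ng, replace = TRUE)))
    d$x <- rnorm(nrow(d), mean = as.integer(factor(d$g)))
    res <- one_way_anova(d, x, g)
    ref <- stats::anova(stats::lm(x ~ g, data = d))
    expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(res$df_between, ref$Df[1])
    expect_equal(res$df_within, ref$Df[2])
  }
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(29)
  for (k in 1:10) {
    d <- tibble::tibble(x = rnorm(24), g = rep(c("a", "b"), each = 12))
    res <- one_way_anova(d, x, g)
    tt <- stats::t.test(x ~ g, data = d, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("F is invariant to shifting and common scaling", {
  set.seed(31)
  d <- tibble::tibble(x = rnorm(30, mean = rep(c(0, 1, 3), each = 10)),
                      g = rep(c("a", "b", "c"), each = 10))
  f0 <- one_way_anova(d, x, g)$statistic
  expect_equal(one_way_anova(dplyr::mutate(d, x = x + 100), x, g)$statistic,
               f0, tolerance = 1e-8)
  expect_equal(one_way_anova(dplyr::mutate(d, x = 7 * x), x, g)$statistic,
               f0, tolerance = 1e-8)
})

test_that("degenerate and invalid group structures are handled", {
  d <- tibble::tibble(x = c(1, 1, 1, 5, 5, 5), g = rep(c("a", "b"), each = 3))
  res <- one_way_anova(d, x, g)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  expect_error(one_way_anova(tibble::tibble(x = 1:4, g = "a"), x, g),
               "2 groups")
  expect_error(
    one_way_anova(tibble::tibble(x = 1:3, g = c("a", "a", "b")), x, g),
    "at least 2 values")
})

test_that("windows straddling interval boundaries are excluded", {
  env <- toy_envelope(rep(c(3, 1), each = 50))   # step 0.1, window 0.2
  iv <- tibble::tibble(state = c("hi", "lo"),
                       start_s = c(0, 5.0), end_s = c(5.0, 10.1))
  sc <- state_comparison(env, iv)
  # window centered at 5.0 spans 4.9-5.1 and belongs to neither state
  expect_false(5.0 %in% sc$samples$time_s)
  expect_equal(sc$fold, 3, tolerance = 1e-9)
  expect_equal(sort(unique(sc$samples$state)), c("hi", "lo"))
})

test_that("episode-level aggregation uses one value per interval", {
  env <- toy_envelope(rep(c(3, 1, 3, 1), each = 25))
  iv <- tibble::tibble(state = c("hi", "lo", "hi", "lo"),
                       start_s = c(0, 2.5, 5.0, 7.5),
                       end_s = c(2.5, 5.0, 7.5, 10.1))
  sc <- state_comparison(env, iv, unit = "episode")
  expect_equal(nrow(sc$values), 4)
  expect_equal(sc$fold, 3, tolerance = 0.01)
})

test_that("active and pause states separate sharply in curl sessions", {
  for (s in 1:3) {
    cs <- generate_curl_session(curl_spec(), seed = 40 + s)
    env <- sliding_features(bandpass(cs$recording), step_s = 0.05)
    iv <- dplyr::bind_rows(
      dplyr::mutate(annotation_intervals(cs$annotations, "set"),
                    state = "active"),
      dplyr::mutate(annotation_intervals(cs$annotations, "pause"),
                    state = "pause"))
    sc <- state_comparison(env, iv)
    expect_lt(sc$anova$p_value, 0.05)
    expect_gt(sc$fold, 10)
  }
})

test_that("null sessions give calibrated window-level p values", {
  # non-overlapping windows so the ANOVA's independence assumption holds
  ps <- vapply(1:15, function(s) {
    ses <- generate_session(session_spec(
      16, episodes = list(fog_episode(12, 2, 2, attenuation = 1.0)),
      seed = 900 + s, channels = channel_meta("quadriceps", "right")))
    env <- sliding_features(ses$recording, 0.2, 0.2, override_step = TRUE)
    iv <- tibble::tibble(state = c("precursor", "normal"),
                         start_s = c(10, 1), end_s = c(14, 9))
    state_comparison(env, iv)$anova$p_value
  }, 0)
  expect_lte(sum(ps < 0.05), 4)   # ~0.75 expected under the null
  expect_gt(min(ps), 0)
})
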