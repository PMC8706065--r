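# Head-speed compliance pipeline.

test_that("smoothing: identity cases and variance reduction", {
  s <- head_angle_series(seq(0, 10, 0.1), rep(7, 101), "yaw", "synthetic")
  expect_equal(smooth_series(s, 0.5)$angles, s$angles)
  r <- head_angle_series(seq(0, 10, 0.1), rnorm(101), "yaw", "synthetic")
  expect_identical(smooth_series(r, 0)$angles, r$angles)
  # white noise at 30 fps, 0.15 s window ~ 5-sample mean: variance ~ /5
  set.seed(1)
  n <- 3000
  w <- head_angle_series((0:(n - 1)) / 30, rnorm(n), "yaw", "synthetic")
  ratio <- var(smooth_series(w, 0.15)$angles) / var(w$angles)
  expect_equal(ratio, 1 / 5, tolerance = 0.15)
})

test_that("pure sinusoid yields alternating full-height extrema", {
  s <- simulate_head_motion(clean_config(120, fps = 40))
  ex <- detect_extrema(s)
  expect_equal(nrow(ex), 60)
  expect_true(all(ex$kind == rep(c("peak", "valley"), 30)))
  expect_equal(abs(ex$height), rep(15, 60), tolerance = 1e-9)
  expect_true(all(ex$prominence >= abs(ex$height) - 1e-12))
  expect_true(all(diff(ex$time) > 0))
})

test_that("a 3-degree sinusoid falls under the 4-degree threshold", {
  s <- simulate_head_motion(clean_config(120, amplitude_deg = 3))
  expect_equal(nrow(detect_extrema(s)), 0L)
  # and exactly at the boundary the extremum is kept (>= threshold)
  s4 <- simulate_head_motion(clean_config(120, amplitude_deg = 4, fps = 40))
  expect_gt(nrow(detect_extrema(s4)), 0L)
})

test_that("only the largest maximum survives in a two-lobed positive region", {
  # main lobe 15 deg with a 10 deg shoulder, no baseline crossing between
  t <- seq(0, 10, by = 0.02)
  lobe <- function(t0, a, w) a * exp(-((t - t0) / w)^2)
  y <- lobe(3, 15, 0.4) + lobe(4.2, 10, 0.4) - lobe(7.5, 18, 0.6)
  s <- head_angle_series(t, y, "yaw", "synthetic")
  ex <- detect_extrema(s)
  pk <- ex[ex$kind == "peak", ]
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time, 3, tolerance = 0.05)
  expect_extrema_equal(as.data.frame(ex)[c("time", "height", "kind")],
                       oracle_extrema(t, y))
})

test_that("detect_extrema matches the brute-force oracle on random signals", {
  for (seed in 1:60) {
    s <- rand_signal(seed)
    got <- detect_extrema(s)
    expect_extrema_equal(as.data.frame(got)[c("time", "height", "kind")],
                         oracle_extrema(s$times, s$angles))
  }
})

test_that("extrema alternate strictly for arbitrary inputs", {
  for (seed in 101:140) {
    ex <- detect_extrema(rand_signal(seed))
    if (nrow(ex) >= 2) {
      expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
      expect_true(all(abs(ex$height) >= 4))
      expect_true(all(ex$prominence >= abs(ex$height) - 1e-9))
    }
  }
})

test_that("interval_bpm converts time differences to tempo", {
  expect_equal(interval_bpm(1.0), 120)
  expect_equal(interval_bpm(1.5), 80)
  expect_equal(interval_bpm(0.375, "adjacent_extrema"), 160)
  expect_error(interval_bpm(0), "dt_s")
  expect_error(interval_bpm(-1), "dt_s")
})

test_that("interval classification applies the +/- delta window", {
  mk_ex <- function(bpms) {
    # construct alternating extrema whose peak-to-peak intervals hit the bpms
    t <- 0
    times <- 0
    for (b in bpms) { t <- t + 120 / b; times <- c(times, t) }
    full <- sort(c(times, times + 60 / mean(bpms) / 2))[1:(2 * length(times))]
    df <- data.frame(time = full,
                     height = rep(c(15, -15), length.out = 2 * length(times)),
                     prominence = 15,
                     kind = rep(c("peak", "valley"), length.out = 2 * length(times)))
    structure(df, class = c("extrema_list", "data.frame"), baseline = 0,
              min_peak_height_deg = 4)
  }
  rx <- prescription("horizontal", 120)
  rep <- classify_intervals(mk_ex(c(130, 136, 104, 120)), rx)
  pk <- rep$intervals[seq(1, nrow(rep$intervals), by = 2), ]  # peak intervals
  expect_equal(pk$label, c("correct", "fast", "slow", "correct"))
  expect_equal(pk$measured_bpm, c(130, 136, 104, 120), tolerance = 1e-9)
})

test_that("noise-free compliant trial scores 100 percent", {
  for (g in c(80, 120, 160)) {
    s <- simulate_head_motion(clean_config(g))
    rep <- classify_intervals(detect_extrema(smooth_series(s)),
                              prescription("horizontal", g))
    expect_equal(rep$percent_correct, 100)
    # every interval bpm within sampling quantization of the goal
    dt_q <- 1 / 30
    worst <- max(abs(rep$intervals$measured_bpm - g))
    expect_lte(worst, abs(interval_bpm(120 / g - dt_q) - g) + 1e-9)
  }
})

test_that("fewer than two extrema flags the report instead of erroring", {
  s <- head_angle_series(seq(0, 10, 0.1), rep(0, 101), "yaw", "synthetic")
  rep <- classify_intervals(detect_extrema(s), prescription("horizontal", 120))
  expect_true(rep$flagged)
  expect_true(is.na(rep$percent_correct))
  expect_equal(nrow(rep$intervals), 0L)
})

test_that("percent_correct is monotone in compliant intervals and in delta", {
  mk <- function(tt) {
    df <- data.frame(time = tt, height = rep(c(15, -15), length.out = length(tt)),
                     prominence = 15,
                     kind = rep(c("peak", "valley"), length.out = length(tt)))
    structure(df, class = c("extrema_list", "data.frame"), baseline = 0,
              min_peak_height_deg = 4)
  }
  # adjacent-extrema spacings: 0.5 s <=> 120 bpm compliant, 0.9 s slow
  times <- cumsum(c(rep(0.5, 6), rep(0.9, 5), rep(0.5, 4)))
  ex <- mk(times)
  p1 <- classify_intervals(ex, prescription("horizontal", 120,
                                            compliance_delta_bpm = 15))$percent_correct
  p2 <- classify_intervals(ex, prescription("horizontal", 120,
                                            compliance_delta_bpm = 40))$percent_correct
  expect_gte(p2, p1)  # widening the window never lowers the score
  # extending the compliant tail adds only correct intervals
  ext <- c(times, max(times) + cumsum(rep(0.5, 6)))
  p3 <- classify_intervals(mk(ext), prescription("horizontal", 120))$percent_correct
  expect_gte(p3, p1)
})

test_that("gaze compliance is the on-target frame percentage", {
  expect_equal(gaze_compliance(gaze_series(1:10 / 30, rep(TRUE, 10))), 100)
  expect_equal(gaze_compliance(simulate_gaze_sequence(200, 0.25, seed = 2)), 25)
  expect_equal(gaze_compliance(gaze_series(1:10, rep(c(TRUE, FALSE), 5))), 50)
  expect_error(gaze_series(numeric(0), logical(0)), "non-empty")
})

test_that("reward coins follow the 5 + 0-5 + 0-5 rule", {
  expect_equal(compute_rewards(TRUE, 0, 0), 5L)
  expect_equal(compute_rewards(TRUE, 100, 100), 15L)
  expect_equal(compute_rewards(FALSE, 100, 100), 10L)
  expect_equal(compute_rewards(TRUE, 50, 0), 5L + 3L)  # 2.5 rounds half up
  expect_error(compute_rewards(TRUE, 120, 0), "percent")
  # integer-valued, bounded, monotone in each percent argument
  grid <- seq(0, 100, by = 5)
  coins <- vapply(grid, function(p) compute_rewards(TRUE, p, 0), integer(1))
  expect_true(all(coins >= 0 & coins <= 15))
  expect_true(all(diff(coins) >= 0))
  coins_g <- vapply(grid, function(p) compute_rewards(FALSE, 40, p), integer(1))
  expect_true(all(diff(coins_g) >= 0))
})
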