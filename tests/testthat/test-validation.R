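# Camera-vs-IMU validation harness.

test_that("aligning a series with itself gives zero lag and zero DC", {
  s <- simulate_head_motion(sim_config(seed = 21))
  al <- align_series(s, s)
  expect_equal(al$lag_s, 0)
  expect_equal(al$dc_applied_deg, 0, tolerance = 1e-9)
  expect_equal(al$aligned$angles, s$angles, tolerance = 1e-9)
})

test_that("DC compensation restores the camera mean", {
  s <- simulate_head_motion(sim_config(seed = 22, dc_offset_deg = 6))
  ref <- head_angle_series(s$times, s$angles - mean(s$angles),
                           plane = s$plane, source = "imu")
  al <- align_series(s, ref)
  expect_equal(al$dc_applied_deg, mean(s$angles), tolerance = 1e-9)
  expect_equal(al$lag_s, 0)
})

test_that("insufficient overlap is rejected", {
  s <- simulate_head_motion(sim_config(duration_s = 30, seed = 1))
  short <- head_angle_series(s$times[1:60], s$angles[1:60], s$plane, "imu")
  expect_error(align_series(s, short), "overlap")
})

test_that("injected lags are recovered within one resample interval", {
  for (lag in c(-0.4, 0.15)) {
    p <- simulate_paired_trial(paired_trial_config(sim_config(seed = 31),
                                                   lag_s = lag))
    al <- align_series(p$camera, p$imu)
    expect_lte(abs(al$lag_s - lag), al$grid_dt_s)
  }
})

test_that("match_peaks: identity, dropped interior peak, zero tolerance", {
  s <- smooth_series(simulate_head_motion(sim_config(seed = 23)))
  ex <- detect_extrema(s)
  m <- match_peaks(ex, ex, tol_s = 0.25)
  expect_equal(nrow(m$pairs), nrow(ex))
  expect_equal(m$n_dropped_a + m$n_dropped_b, 0)
  expect_equal(m$pairs$time_a, m$pairs$time_b)

  # remove one interior peak from b: its partner in a is dropped,
  # remaining pairs keep their order
  pk_rows <- which(ex$kind == "peak")
  b <- ex[-pk_rows[3], , drop = FALSE]
  class(b) <- class(ex)
  m2 <- match_peaks(ex, b, tol_s = 0.1)
  expect_equal(m2$n_dropped_a, 1)
  expect_equal(m2$n_dropped_b, 0)
  expect_false(ex$time[pk_rows[3]] %in% m2$pairs$time_a)
  expect_true(all(diff(m2$pairs$time_b) > 0))

  m0 <- match_peaks(ex, b, tol_s = 0)
  expect_equal(nrow(m0$pairs), nrow(ex) - 1)  # exact coincidences only
})

test_that("interpeak_errors: identity, constant offset, hand-computed fixture", {
  mk <- function(ta, tb, kind = "peak") {
    structure(list(pairs = data.frame(time_a = ta, time_b = tb, kind = kind),
                   n_dropped_a = 0, n_dropped_b = 0),
              class = "peak_matching")
  }
  id <- interpeak_errors(mk(0:5, 0:5))
  expect_equal(id$mean_abs_error_s, 0)
  expect_equal(id$rmse_s, 0)

  # b's intervals uniformly 0.05 s longer
  co <- interpeak_errors(mk(cumsum(c(0, rep(1, 5))),
                            cumsum(c(0, rep(1.05, 5)))))
  expect_equal(co$mean_abs_error_s, 0.05, tolerance = 1e-12)
  expect_equal(co$rmse_s, 0.05, tolerance = 1e-12)

  # |errors| = {0.02, 0.04, 0.06}: mean 0.04, rmse sqrt(0.0056/3)
  ta <- c(0, 1, 2, 3)
  tb <- c(0, 1.02, 1.98, 3.04)
  hc <- interpeak_errors(mk(ta, tb))
  expect_equal(sort(abs(diff(ta) - diff(tb))), c(0.02, 0.04, 0.06),
               tolerance = 1e-12)
  expect_equal(hc$mean_abs_error_s, 0.04, tolerance = 1e-12)
  expect_equal(hc$rmse_s, sqrt(0.0056 / 3), tolerance = 1e-12)

  one <- interpeak_errors(mk(1, 1))
  expect_true(one$flagged)
})

test_that("frequency_error matches the closed form and its algebraic identity", {
  expect_equal(frequency_error(120, 0)$err_bpm, 0)
  expect_equal(frequency_error(160, 0.05)$err_bpm, -10, tolerance = 1e-12)
  expect_equal(frequency_error(120, 0.25)$err_bpm, -24, tolerance = 1e-12)
  expect_error(frequency_error(120, -1), "err_interval")
  set.seed(9)
  for (i in 1:200) {
    g <- runif(1, 40, 200)
    e <- runif(1, -0.8 * 120 / g, 1)
    fe <- frequency_error(g, e)$err_bpm
    expect_equal(fe, 120 / (120 / g + e) - g, tolerance = 1e-9)
  }
})

test_that("a fixed interval error magnifies with the goal tempo", {
  for (e in c(0.02, 0.05, 0.1)) {
    errs <- vapply(c(60, 80, 120, 160, 200), function(g) {
      abs(frequency_error(g, e)$err_bpm)
    }, numeric(1))
    expect_true(all(diff(errs) > 0))
  }
})

test_that("trial_report on an identical pair (plus DC) returns exact zeros", {
  s <- simulate_head_motion(sim_config(seed = 24, dc_offset_deg = 4))
  ref <- head_angle_series(s$times, s$angles - mean(s$angles), s$plane, "imu")
  tr <- trial_report(s, ref, prescription("horizontal", 120))
  expect_equal(tr$mean_abs_head_angle_error_deg, 0, tolerance = 1e-9)
  expect_equal(tr$head_angle_rmse_deg, 0, tolerance = 1e-9)
  expect_equal(tr$n_peaks_reference, tr$n_peaks_camera)
  expect_equal(tr$mean_matched_interpeak_time_error_s, 0, tolerance = 1e-12)
  expect_equal(tr$interpeak_time_rmse_s, 0, tolerance = 1e-12)
  expect_equal(tr$percent_correct_difference, 0)
  expect_equal(tr$lag_s, 0)
})

test_that("the prescribed goal moves compliance metrics but not angle errors", {
  p <- simulate_paired_trial(paired_trial_config(sim_config(seed = 25)))
  t120 <- trial_report(p$camera, p$imu, prescription("horizontal", 120))
  t80 <- trial_report(p$camera, p$imu, prescription("horizontal", 80))
  expect_equal(t80$mean_abs_head_angle_error_deg,
               t120$mean_abs_head_angle_error_deg)
  expect_equal(t80$head_angle_rmse_deg, t120$head_angle_rmse_deg)
  expect_false(isTRUE(all.equal(t80$percent_correct_camera,
                                t120$percent_correct_camera)))
  expect_false(isTRUE(all.equal(t80$mean_abs_head_turn_frequency_error_bpm,
                                t120$mean_abs_head_turn_frequency_error_bpm)))
})

test_that("classification metrics handle degenerate denominators explicitly", {
  m <- classification_metrics(confusion_matrix(tn = 10, fp = 0, fn = 0, tp = 0))
  expect_equal(m$accuracy, 1)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_setequal(m$undefined, c("precision", "recall", "f1"))
  expect_error(confusion_matrix(0, 0, 0, 0), "total")
  expect_error(confusion_matrix(-1, 0, 0, 5), "tn")
})

test_that("classification metrics agree with a textbook implementation", {
  set.seed(10)
  for (i in 1:300) {
    cm <- as.list(sample(0:40, 4, replace = TRUE))
    names(cm) <- c("tn", "fp", "fn", "tp")
    if (Reduce(`+`, cm) == 0) next
    got <- classification_metrics(do.call(confusion_matrix, cm))
    want <- do.call(oracle_metrics, cm)
    for (k in c("accuracy", "precision", "recall", "f1")) {
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12, label = k)
    }
  }
})
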