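# Independent oracles, deliberately written along different routes than the
# package implementation.

# Brute-force extrema oracle. Works on the zero-padded centred signal:
# enumerate strict local maxima, compute topographic prominence by direct
# scan, retain iff prominence >= height and height >= thresh. Valleys via
# negation; alternation resolved by the documented keep-larger rule.
oracle_extrema <- function(times, angles, thresh = 4) {
  baseline <- mean(angles)
  one_side <- function(y) {
    yp <- c(0, y, 0)
    n <- length(yp)
    keep <- integer(0)
    for (i in 2:(n - 1L)) {
      if (!(yp[i] > yp[i - 1L] && yp[i] > yp[i + 1L])) next
      h <- yp[i]
      if (h <= 0) next
      lmin <- Inf
      for (j in (i - 1L):1L) {
        if (yp[j] > h) break
        lmin <- min(lmin, yp[j])
      }
      rmin <- Inf
      for (j in (i + 1L):n) {
        if (yp[j] > h) break
        rmin <- min(rmin, yp[j])
      }
      prom <- h - max(lmin, rmin)
      if (prom >= h && h >= thresh) keep <- c(keep, i - 1L)
    }
    keep
  }
  y <- angles - baseline
  pk <- one_side(y)
  vl <- one_side(-y)
  df <- rbind(
    if (length(pk)) data.frame(time = times[pk], height = y[pk], kind = "peak"),
    if (length(vl)) data.frame(time = times[vl], height = y[vl], kind = "valley")
  )
  if (is.null(df)) {
    return(data.frame(time = numeric(0), height = numeric(0),
                      kind = character(0)))
  }
  df <- df[order(df$time), , drop = FALSE]
  # alternation: within a same-kind run keep the largest |height|, ties earlier
  while (nrow(df) >= 2L) {
    same <- which(df$kind[-1L] == df$kind[-nrow(df)])
    if (!length(same)) break
    i <- same[1L]
    drop <- if (abs(df$height[i + 1L]) > abs(df$height[i])) i else i + 1L
    df <- df[-drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# Textbook classification metrics from expanded label vectors.
oracle_metrics <- function(tn, fp, fn, tp) {
  truth <- c(rep(FALSE, tn + fp), rep(TRUE, fn + tp))
  pred <- c(rep(FALSE, tn), rep(TRUE, fp), rep(FALSE, fn), rep(TRUE, tp))
  prec <- if (sum(pred) > 0) sum(pred & truth) / sum(pred) else NA_real_
  rec <- if (sum(truth) > 0) sum(pred & truth) / sum(truth) else NA_real_
  list(accuracy = mean(pred == truth), precision = prec, recall = rec,
       f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
         2 * prec * rec / (prec + rec)
       } else NA_real_)
}

# Rotation-matrix-trace route to the geodesic angle, degrees.
oracle_geodesic_trace <- function(rt1, rt2) {
  R1 <- rotation_matrix(rt1)
  R2 <- rotation_matrix(rt2)
  acos(min(1, max(-1, (sum(diag(t(R1) %*% R2)) - 1) / 2))) * 180 / pi
}

# Random piecewise-smooth test signal with baseline crossings and peaks
# straddling the 4-degree threshold.
rand_signal <- function(seed, n = NULL) {
  set.seed(seed)
  n <- if (is.null(n)) sample(20:200, 1) else n
  t <- cumsum(runif(n, 0.02, 0.08))
  a <- runif(1, 2, 12)
  f <- runif(1, 0.5, 2.5)
  y <- a * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
    runif(1, 1, 4) * sin(2 * pi * f * 2.7 * t) +
    cumsum(rnorm(n, 0, 0.2)) + rnorm(n, 0, 0.5) + rnorm(1, 0, 3)
  head_angle_series(t, y, plane = "yaw", source = "synthetic")
}

# Noise-free simulator config (pure metronome-locked sinusoid).
clean_config <- function(goal_bpm, duration_s = 30, amplitude_deg = 15,
                         fps = 30, dc = 0, decay = 0) {
  sim_config(goal_bpm = goal_bpm, duration_s = duration_s,
             amplitude_deg = amplitude_deg, amplitude_decay_per_bpm = decay,
             nominal_fps = fps, frame_jitter_sd_s = 0,
             angle_noise_sd_deg = 0, speed_drift_sd_bpm = 0,
             dc_offset_deg = dc)
}

expect_extrema_equal <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(want)) {
    expect_equal(got$time, want$time)
    expect_equal(got$height, want$height)
    expect_equal(got$kind, want$kind)
  }
}
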