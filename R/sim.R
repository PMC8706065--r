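# Synthetic VORx1 signal generator.
#
# The generator stands in for recorded exercise trials: a patient oscillates
# the head in one plane, paced by a metronome at `goal_bpm` beats per minute.
# One beat corresponds to one sweep to an extreme, so a full oscillation
# (peak to peak) spans two beats and the full-cycle period is 120/goal_bpm
# seconds. The latent motion is a phase-modulated sinusoid: the instantaneous
# tempo performs a reflected Gaussian random walk around the goal, frame
# times jitter around the nominal camera grid, and additive Gaussian noise
# models angle-estimation error.

#' Simulation configuration for a single VORx1 trial
#'
#' Defaults describe a realistic tablet-camera recording of a cooperative
#' subject: a 30 s trial, a 15 degree half-sweep (30 degree total sweep),
#' 30 fps sampling with millisecond-scale frame jitter, about a degree of
#' angle noise and a couple of bpm of tempo drift.
#'
#' @param goal_bpm prescribed metronome rate, beats per minute (> 0).
#' @param duration_s trial length in seconds (> 0).
#' @param amplitude_deg peak displacement from neutral, degrees (>= 0).
#' @param amplitude_decay_per_bpm linear range-of-motion loss per bpm above
#'   80 bpm, degrees/bpm (>= 0); the effective amplitude
#'   `amplitude_deg - amplitude_decay_per_bpm * (goal_bpm - 80)` is clamped
#'   at zero. Emulates the reduced sweep subjects show at faster tempi.
#' @param nominal_fps nominal camera frame rate, frames/second (> 0).
#' @param frame_jitter_sd_s standard deviation of Gaussian frame-time
#'   jitter, seconds (>= 0). Sampled times are sorted and de-tied.
#' @param angle_noise_sd_deg additive angle noise s.d., degrees (>= 0).
#' @param speed_drift_sd_bpm s.d. of the per-sqrt-second random-walk step on
#'   instantaneous tempo, bpm (>= 0); the walk is reflected at
#'   `goal_bpm +/- 3 * speed_drift_sd_bpm`.
#' @param dc_offset_deg constant neutral-pose bias, degrees.
#' @param seed integer RNG seed or `NULL`.
#' @return a list of class `sim_config`.
#' @examples
#' cfg <- sim_config(goal_bpm = 120, duration_s = 30, seed = 7)
#' @export
sim_config <- function(goal_bpm = 120, duration_s = 30, amplitude_deg = 15,
                       amplitude_decay_per_bpm = 0.05, nominal_fps = 30,
                       frame_jitter_sd_s = 0.004, angle_noise_sd_deg = 1,
                       speed_drift_sd_bpm = 2, dc_offset_deg = 2,
                       seed = NULL) {
  check_scalar(goal_bpm, "goal_bpm", positive = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(amplitude_deg, "amplitude_deg", nonneg = TRUE)
  check_scalar(amplitude_decay_per_bpm, "amplitude_decay_per_bpm", nonneg = TRUE)
  check_scalar(nominal_fps, "nominal_fps", positive = TRUE)
  check_scalar(frame_jitter_sd_s, "frame_jitter_sd_s", nonneg = TRUE)
  check_scalar(angle_noise_sd_deg, "angle_noise_sd_deg", nonneg = TRUE)
  check_scalar(speed_drift_sd_bpm, "speed_drift_sd_bpm", nonneg = TRUE)
  check_scalar(dc_offset_deg, "dc_offset_deg")
  if (!is.null(seed)) check_scalar(seed, "seed", integerish = TRUE)
  structure(list(goal_bpm = goal_bpm, duration_s = duration_s,
                 amplitude_deg = amplitude_deg,
                 amplitude_decay_per_bpm = amplitude_decay_per_bpm,
                 nominal_fps = nominal_fps,
                 frame_jitter_sd_s = frame_jitter_sd_s,
                 angle_noise_sd_deg = angle_noise_sd_deg,
                 speed_drift_sd_bpm = speed_drift_sd_bpm,
                 dc_offset_deg = dc_offset_deg, seed = seed),
            class = "sim_config")
}

# Effective amplitude after tempo-dependent range-of-motion loss.
effective_amplitude <- function(config) {
  max(0, config$amplitude_deg -
        config$amplitude_decay_per_bpm * (config$goal_bpm - 80))
}

# Latent phase path on a fine uniform grid covering [t0, t1].
# Returns list(times, phase) with phase(0) = 0 and
# dphi/dt = 2*pi * bpm(t) / 120 (full cycle = two metronome beats).
latent_phase_path <- function(config, t0, t1, grid_dt = 0.005) {
  n_back <- if (t0 < 0) ceiling(-t0 / grid_dt) else 0L
  n_fwd <- ceiling(max(t1, 0) / grid_dt)
  tg <- seq(-n_back, n_fwd) * grid_dt
  n <- length(tg)
  sd <- config$speed_drift_sd_bpm
  if (sd > 0) {
    steps <- stats::rnorm(n - 1L, 0, sd * sqrt(grid_dt))
    lo <- config$goal_bpm - 3 * sd
    hi <- config$goal_bpm + 3 * sd
    bpm <- numeric(n)
    bpm[1L] <- config$goal_bpm
    for (i in 2:n) {
      b <- bpm[i - 1L] + steps[i - 1L]
      # reflect into [lo, hi]
      while (b < lo || b > hi) b <- ifelse(b < lo, 2 * lo - b, 2 * hi - b)
      bpm[i] <- b
    }
  } else {
    bpm <- rep(config$goal_bpm, n)
  }
  omega <- 2 * pi * bpm / 120
  # trapezoidal phase integration, anchored so that phase(t = 0) = 0
  phase <- c(0, cumsum((omega[-1L] + omega[-n]) / 2 * grid_dt))
  i0 <- n_back + 1L  # index of t = 0
  phase <- phase - phase[i0]
  list(times = tg, phase = phase)
}

# Camera-style sample times: nominal grid plus Gaussian jitter, sorted,
# strictly increasing.
sample_times <- function(duration_s, fps, jitter_sd, t_offset = 0) {
  t <- seq(0, duration_s, by = 1 / fps) + t_offset
  if (jitter_sd > 0) t <- make_strictly_increasing(t + stats::rnorm(length(t), 0, jitter_sd))
  t
}

#' Simulate a single head-motion trial
#'
#' Generates `theta(t) = dc + A * sin(phi(t)) + noise`, where the phase
#' `phi` advances at the instantaneous tempo (goal plus reflected
#' random-walk drift) and one full oscillation spans `120 / goal_bpm`
#' seconds. Deterministic for a fixed `seed`.
#'
#' @param config a [sim_config()].
#' @param plane rotation plane label for the output series.
#' @return a [head_angle_series()] with `source = "synthetic"`.
#' @examples
#' s <- simulate_head_motion(sim_config(goal_bpm = 120, duration_s = 10, seed = 1))
#' @export
simulate_head_motion <- function(config, plane = "yaw") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    t <- sample_times(config$duration_s, config$nominal_fps,
                      config$frame_jitter_sd_s)
    path <- latent_phase_path(config, min(t, 0), max(t, config$duration_s))
    phi <- stats::approx(path$times, path$phase, xout = t)$y
    a <- effective_amplitude(config)
    y <- config$dc_offset_deg + a * sin(phi)
    if (config$angle_noise_sd_deg > 0) {
      y <- y + stats::rnorm(length(t), 0, config$angle_noise_sd_deg)
    }
    head_angle_series(t, y, plane = plane, source = "synthetic",
                      meta = list(config = unclass(config)))
  })
}

#' Paired-trial configuration (camera + IMU view of one motion)
#'
#' @param base a [sim_config()] describing the latent motion and the camera
#'   sampling/noise.
#' @param lag_s camera delay relative to the IMU, seconds; the camera sees
#'   the motion `lag_s` late. Must satisfy `|lag_s| < duration_s / 4`.
#' @param imu_fps IMU sampling rate, frames/second (> 0); IMU grids are
#'   uniform (hardware-clocked).
#' @param camera_extra_noise_sd_deg extra camera angle noise on top of the
#'   base noise, degrees (>= 0); pose-from-landmarks is noisier than an IMU.
#' @return a list of class `paired_trial_config`.
#' @export
paired_trial_config <- function(base = sim_config(), lag_s = 0.2,
                                imu_fps = 100,
                                camera_extra_noise_sd_deg = 0.5) {
  stopifnot(inherits(base, "sim_config"))
  check_scalar(lag_s, "lag_s")
  check_scalar(imu_fps, "imu_fps", positive = TRUE)
  check_scalar(camera_extra_noise_sd_deg, "camera_extra_noise_sd_deg",
               nonneg = TRUE)
  if (abs(lag_s) >= base$duration_s / 4) {
    stop(sprintf("lag_s: |lag| must be < duration_s/4 = %g s",
                 base$duration_s / 4), call. = FALSE)
  }
  structure(list(base = base, lag_s = lag_s, imu_fps = imu_fps,
                 camera_extra_noise_sd_deg = camera_extra_noise_sd_deg),
            class = "paired_trial_config")
}

#' Simulate a paired camera/IMU trial
#'
#' Both series sample the same latent motion. The camera series keeps its
#' DC offset, carries the camera noise, and is delayed by `lag_s`; the IMU
#' series is sampled on its own uniform grid, gets the base angle noise,
#' and has its empirical mean removed (IMU-derived angles carry no DC
#' component). The injected truth is returned for test assertions.
#'
#' @param config a [paired_trial_config()].
#' @param plane rotation plane label.
#' @return a list with elements `camera` and `imu` (both
#'   [head_angle_series()]) and `truth` (list with `lag_s`,
#'   `dc_offset_deg`, `imu_mean_removed_deg`).
#' @examples
#' p <- simulate_paired_trial(paired_trial_config(sim_config(seed = 3)))
#' @export
simulate_paired_trial <- function(config, plane = "yaw") {
  stopifnot(inherits(config, "paired_trial_config"))
  base <- config$base
  with_seed(base$seed, {
    lag <- config$lag_s
    t_cam <- sample_times(base$duration_s, base$nominal_fps,
                          base$frame_jitter_sd_s)
    t_imu <- seq(0, base$duration_s, by = 1 / config$imu_fps)
    path <- latent_phase_path(base, min(t_cam - lag, t_imu, 0),
                              max(t_cam - lag, t_imu, base$duration_s))
    a <- effective_amplitude(base)
    latent <- function(tt) a * sin(stats::approx(path$times, path$phase,
                                                 xout = tt)$y)
    noise_cam <- sqrt(base$angle_noise_sd_deg^2 +
                        config$camera_extra_noise_sd_deg^2)
    y_cam <- base$dc_offset_deg + latent(t_cam - lag)
    if (noise_cam > 0) y_cam <- y_cam + stats::rnorm(length(t_cam), 0, noise_cam)
    y_imu <- latent(t_imu)
    if (base$angle_noise_sd_deg > 0) {
      y_imu <- y_imu + stats::rnorm(length(t_imu), 0, base$angle_noise_sd_deg)
    }
    imu_mean <- mean(y_imu)
    y_imu <- y_imu - imu_mean
    list(
      camera = head_angle_series(t_cam, y_cam, plane = plane,
                                 source = "camera",
                                 meta = list(config = unclass(base),
                                             lag_s = lag)),
      imu = head_angle_series(t_imu, y_imu, plane = plane, source = "imu"),
      truth = list(lag_s = lag, dc_offset_deg = base$dc_offset_deg,
                   imu_mean_removed_deg = imu_mean)
    )
  })
}

#' Canonical 3D face model
#'
#' A fixed six-point rigid landmark model (outer/inner eye corners, nose
#' tip, mouth corners) in arbitrary length units, centred at its centroid.
#' The nose tip sits off the eye/mouth plane so the centred coordinates
#' have rank 3. Coordinate frame: x to the subject's left, y up, z toward
#' the camera.
#'
#' @param points optional named list of length-3 numeric vectors to replace
#'   the built-in model; coordinates are centred automatically.
#' @return matrix of class `canonical_face_model`, one named row per
#'   landmark, columns `x`, `y`, `z`.
#' @examples
#' m <- canonical_face_model()
#' rownames(m)
#' @export
canonical_face_model <- function(points = NULL) {
  if (is.null(points)) {
    points <- list(
      left_eye_outer  = c( 45,  35, -15),
      left_eye_inner  = c( 18,  35, -10),
      right_eye_inner = c(-18,  35, -10),
      right_eye_outer = c(-45,  35, -15),
      nose_tip        = c(  0, -10,  30),
      mouth_left      = c( 28, -45, -12),
      mouth_right     = c(-28, -45, -12)
    )
  }
  if (is.null(names(points)) || any(!nzchar(names(points)))) {
    stop("face model points must be named", call. = FALSE)
  }
  m <- do.call(rbind, lapply(points, as.numeric))
  if (ncol(m) != 3L) stop("face model points must be 3D", call. = FALSE)
  colnames(m) <- c("x", "y", "z")
  m <- sweep(m, 2, colMeans(m))
  if (qr(m)$rank < 3L) {
    stop("degenerate face model: centred coordinates must have rank 3",
         call. = FALSE)
  }
  structure(m, class = c("canonical_face_model", "matrix"))
}

#' Project the face model to 2D landmarks under a given pose
#'
#' Scaled-orthographic projection: rotate the canonical model by the pose,
#' keep the x/y coordinates, scale to pixels, add isotropic Gaussian pixel
#' noise. The inverse operation is [estimate_pose()].
#'
#' @param pose a [rotation_triple()] (yaw/pitch/roll, degrees).
#' @param model a [canonical_face_model()].
#' @param scale pixels per model unit (> 0).
#' @param noise_sd_px pixel noise s.d. (>= 0).
#' @param seed RNG seed or `NULL`.
#' @return data.frame with columns `name`, `x`, `y` (pixels).
#' @examples
#' lm <- simulate_landmarks(rotation_triple(20, -10, 5))
#' estimate_pose(lm)
#' @export
simulate_landmarks <- function(pose, model = canonical_face_model(),
                               scale = 1, noise_sd_px = 0, seed = NULL) {
  stopifnot(inherits(pose, "rotation_triple"),
            inherits(model, "canonical_face_model"))
  check_scalar(scale, "scale", positive = TRUE)
  check_scalar(noise_sd_px, "noise_sd_px", nonneg = TRUE)
  R <- rotation_matrix(pose)
  p <- scale * (unclass(model) %*% t(R))[, 1:2, drop = FALSE]
  with_seed(seed, {
    if (noise_sd_px > 0) {
      p <- p + matrix(stats::rnorm(length(p), 0, noise_sd_px), ncol = 2)
    }
    data.frame(name = rownames(model), x = p[, 1], y = p[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a binary gaze on/off-target frame sequence
#'
#' Produces exactly `round(n_frames * on_target_fraction)` on-target frames
#' (base R round, i.e. round-half-to-even), shuffled by the seed.
#'
#' @param n_frames number of frames (>= 1).
#' @param on_target_fraction fraction of on-target frames in `[0, 1]`.
#' @param seed RNG seed or `NULL`.
#' @param fps nominal frame rate used for the frame times (> 0).
#' @return a [gaze_series()].
#' @examples
#' g <- simulate_gaze_sequence(200, 0.25, seed = 1)
#' gaze_compliance(g)
#' @export
simulate_gaze_sequence <- function(n_frames, on_target_fraction, seed = NULL,
                                   fps = 30) {
  check_scalar(n_frames, "n_frames", positive = TRUE, integerish = TRUE)
  check_scalar(on_target_fraction, "on_target_fraction")
  check_scalar(fps, "fps", positive = TRUE)
  if (on_target_fraction < 0 || on_target_fraction > 1) {
    stop("on_target_fraction: must lie in [0, 1]", call. = FALSE)
  }
  n_on <- round(n_frames * on_target_fraction)
  labels <- c(rep(TRUE, n_on), rep(FALSE, n_frames - n_on))
  labels <- with_seed(seed, sample(labels))
  gaze_series(times = (seq_len(n_frames) - 1L) / fps, on_target = labels)
}
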