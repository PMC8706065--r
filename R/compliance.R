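# Head-speed compliance scoring.
#
# Pipeline: smooth the head-angle signal, subtract its mean (the baseline;
# camera-derived angles carry a DC component), find the single largest
# local maximum inside each positive region bounded by baseline crossings
# (equivalently: retain local maxima whose topographic prominence is at
# least their height above baseline), drop extrema shorter than the
# 4-degree threshold, do the same on the negated signal for valleys,
# enforce strict peak/valley alternation, convert same-kind intervals to
# bpm via 120/dt, and classify each interval against the prescribed tempo
# window.

#' Exercise prescription
#'
#' @param direction movement direction: `"horizontal"` (yaw plane) or
#'   `"vertical"` (pitch plane).
#' @param goal_bpm prescribed metronome rate, beats/minute (> 0).
#' @param duration_s prescribed duration, seconds (> 0).
#' @param compliance_delta_bpm half-width of the compliance window, bpm;
#'   an interval is "correct" when its measured bpm lies within this
#'   distance of the goal. Default 15.
#' @param min_peak_height_deg minimum extremum height above/below baseline,
#'   degrees; smaller perturbations are not counted as head turns.
#'   Default 4.
#' @return a list of class `prescription`.
#' @examples
#' rx <- prescription("horizontal", goal_bpm = 120, duration_s = 30)
#' @export
prescription <- function(direction = c("horizontal", "vertical"),
                         goal_bpm, duration_s = 30,
                         compliance_delta_bpm = 15,
                         min_peak_height_deg = 4) {
  direction <- match.arg(direction)
  check_scalar(goal_bpm, "goal_bpm", positive = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(compliance_delta_bpm, "compliance_delta_bpm", nonneg = TRUE)
  check_scalar(min_peak_height_deg, "min_peak_height_deg", nonneg = TRUE)
  if (goal_bpm <= compliance_delta_bpm) {
    stop("goal_bpm: must exceed compliance_delta_bpm", call. = FALSE)
  }
  structure(list(direction = direction,
                 plane = if (direction == "horizontal") "yaw" else "pitch",
                 goal_bpm = goal_bpm, duration_s = duration_s,
                 compliance_delta_bpm = compliance_delta_bpm,
                 min_peak_height_deg = min_peak_height_deg),
            class = "prescription")
}

# Scan one direction from peak i: minimum value encountered before the
# first sample strictly higher than y[i], with a padded 0 at the signal end.
prominence_scan <- function(y, i, step) {
  h <- y[i]
  m <- Inf
  j <- i + step
  n <- length(y)
  while (j >= 1L && j <= n) {
    if (y[j] > h) return(m)
    m <- min(m, y[j])
    j <- j + step
  }
  min(m, 0)  # ran off the end: padded baseline sample
}

# Peaks of a centred signal y: the largest sample inside each maximal run
# of y > 0, kept when its height reaches `thresh`. Regions touching the
# signal ends are bounded by the conceptual baseline padding. Returns a
# data.frame(idx, height, prominence).
region_peaks <- function(y, thresh) {
  r <- rle(as.vector(y > 0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_idx <- integer(0)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    j <- idx[which.max(y[idx])]
    if (y[j] >= thresh) keep_idx <- c(keep_idx, j)
  }
  if (!length(keep_idx)) {
    return(data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(keep_idx, function(i) {
    y[i] - max(prominence_scan(y, i, -1L), prominence_scan(y, i, 1L))
  }, numeric(1))
  data.frame(idx = keep_idx, height = y[keep_idx], prominence = prom)
}

#' Detect filtered, alternating peaks and valleys
#'
#' The whole-signal mean is subtracted as the baseline. Peaks are local
#' maxima retained iff (a) the prominence is at least the height above
#' baseline — equivalently, the maximum is the single largest one in its
#' positive region bounded by baseline crossings (signal endpoints count
#' as baseline returns) — and (b) the height reaches
#' `min_peak_height_deg`. Valleys come from the identical procedure on the
#' negated signal. The merged list strictly alternates: when two same-kind
#' extrema survive consecutively, the one with larger absolute height is
#' kept (ties: the earlier).
#'
#' The caller is expected to smooth first (see [smooth_series()]).
#'
#' @param series a [head_angle_series()] with at least 3 samples.
#' @param min_peak_height_deg height threshold in degrees (default 4).
#' @return an `extrema_list`: data.frame with columns `time`, `height`
#'   (signed, relative to baseline; negative for valleys), `prominence`,
#'   `kind` (`"peak"`/`"valley"`), with attribute `baseline` (the
#'   subtracted mean). Zero retained extrema gives an empty frame, not an
#'   error.
#' @examples
#' s <- simulate_head_motion(sim_config(goal_bpm = 120, duration_s = 10,
#'   frame_jitter_sd_s = 0, angle_noise_sd_deg = 0, speed_drift_sd_bpm = 0))
#' detect_extrema(s)
#' @export
detect_extrema <- function(series, min_peak_height_deg = 4) {
  stopifnot(inherits(series, "head_angle_series"))
  check_scalar(min_peak_height_deg, "min_peak_height_deg", nonneg = TRUE)
  if (length(series$angles) < 3L) {
    stop("detect_extrema: need at least 3 samples", call. = FALSE)
  }
  baseline <- mean(series$angles)
  y <- series$angles - baseline
  pk <- region_peaks(y, min_peak_height_deg)
  vl <- region_peaks(-y, min_peak_height_deg)
  df <- rbind(
    if (nrow(pk)) data.frame(time = series$times[pk$idx], height = pk$height,
                             prominence = pk$prominence, kind = "peak"),
    if (nrow(vl)) data.frame(time = series$times[vl$idx], height = -vl$height,
                             prominence = vl$prominence, kind = "valley")
  )
  if (is.null(df)) {
    df <- data.frame(time = numeric(0), height = numeric(0),
                     prominence = numeric(0), kind = character(0))
  }
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  df <- enforce_alternation(df)
  structure(df, class = c("extrema_list", "data.frame"),
            baseline = baseline, min_peak_height_deg = min_peak_height_deg)
}

# Resolve runs of consecutive same-kind extrema: keep the largest |height|
# within each run; ties keep the earliest.
enforce_alternation <- function(df) {
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

#' Convert an extrema interval to beats per minute
#'
#' One metronome beat is one sweep to an extreme, so a full oscillation
#' (peak to peak, or valley to valley) spans two beats: a same-kind
#' interval of `dt` seconds corresponds to `120 / dt` bpm, an adjacent
#' peak-to-valley interval to `60 / dt` bpm.
#'
#' @param dt_s time difference in seconds (> 0).
#' @param kind `"peak_to_peak"` (same-kind) or `"adjacent_extrema"`.
#' @return measured tempo in bpm.
#' @examples
#' interval_bpm(1.0)               # 120
#' interval_bpm(0.375, "adjacent_extrema")  # 160
#' @export
interval_bpm <- function(dt_s, kind = c("peak_to_peak", "adjacent_extrema")) {
  kind <- match.arg(kind)
  if (!is.numeric(dt_s) || any(!is.finite(dt_s)) || any(dt_s <= 0)) {
    stop("dt_s: must be > 0 and finite", call. = FALSE)
  }
  if (kind == "peak_to_peak") 120 / dt_s else 60 / dt_s
}

#' Classify head-turn intervals against a prescription
#'
#' Consecutive same-kind extrema (peak-to-peak and valley-to-valley) give
#' intervals with `measured_bpm = 120 / dt`. An interval is `correct` when
#' `|measured - goal| <= delta`, `slow` below the window, `fast` above.
#' `percent_correct` is interval-count weighted.
#'
#' @param extrema an `extrema_list` from [detect_extrema()].
#' @param rx a [prescription()].
#' @return a `compliance_report`: list with `intervals` (data.frame of
#'   `start_time`, `end_time`, `measured_bpm`, `label`), `percent_correct`
#'   (`NA` and `flagged = TRUE` when no interval exists), `mean_bpm`,
#'   `n_peaks`, `n_valleys`, `goal_bpm`, `compliance_delta_bpm`.
#' @examples
#' s <- simulate_head_motion(sim_config(goal_bpm = 120, duration_s = 30,
#'   frame_jitter_sd_s = 0, angle_noise_sd_deg = 0, speed_drift_sd_bpm = 0))
#' classify_intervals(detect_extrema(smooth_series(s)),
#'                    prescription("horizontal", 120))
#' @export
classify_intervals <- function(extrema, rx) {
  stopifnot(inherits(extrema, "extrema_list"), inherits(rx, "prescription"))
  ivals <- lapply(c("peak", "valley"), function(k) {
    tt <- extrema$time[extrema$kind == k]
    if (length(tt) < 2L) return(NULL)
    data.frame(start_time = tt[-length(tt)], end_time = tt[-1L],
               measured_bpm = interval_bpm(diff(tt)))
  })
  ivals <- do.call(rbind, ivals)
  if (is.null(ivals)) {
    ivals <- data.frame(start_time = numeric(0), end_time = numeric(0),
                        measured_bpm = numeric(0))
  }
  ivals <- ivals[order(ivals$start_time), , drop = FALSE]
  rownames(ivals) <- NULL
  g <- rx$goal_bpm
  d <- rx$compliance_delta_bpm
  ivals$label <- ifelse(abs(ivals$measured_bpm - g) <= d, "correct",
                        ifelse(ivals$measured_bpm < g - d, "slow", "fast"))
  n <- nrow(ivals)
  structure(list(
    intervals = ivals,
    percent_correct = if (n > 0) 100 * sum(ivals$label == "correct") / n else NA_real_,
    flagged = n == 0,
    mean_bpm = if (n > 0) mean(ivals$measured_bpm) else NA_real_,
    n_peaks = sum(extrema$kind == "peak"),
    n_valleys = sum(extrema$kind == "valley"),
    goal_bpm = g, compliance_delta_bpm = d
  ), class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> goal %g bpm (±%g)\n",
              x$goal_bpm, x$compliance_delta_bpm))
  cat(sprintf("  %d peaks, %d valleys, %d intervals\n",
              x$n_peaks, x$n_valleys, nrow(x$intervals)))
  if (!x$flagged) {
    cat(sprintf("  percent correct %.2f%%, mean %.1f bpm\n",
                x$percent_correct, x$mean_bpm))
  } else {
    cat("  no intervals (insufficient extrema)\n")
  }
  invisible(x)
}

#' Gaze label sequence
#'
#' @param times frame times in seconds, non-decreasing.
#' @param on_target logical vector of on/off-target labels, same length.
#' @return a list of class `gaze_series`.
#' @export
gaze_series <- function(times, on_target) {
  times <- as.numeric(times)
  on_target <- as.logical(on_target)
  if (length(times) != length(on_target)) {
    stop("times and on_target must have equal length", call. = FALSE)
  }
  if (length(times) < 1L) stop("gaze series must be non-empty", call. = FALSE)
  if (any(is.na(on_target))) stop("on_target labels must be TRUE/FALSE", call. = FALSE)
  if (any(diff(times) < 0)) stop("gaze times must be non-decreasing", call. = FALSE)
  structure(list(times = times, on_target = on_target), class = "gaze_series")
}

#' Percent of frames with gaze on target
#'
#' @param gaze a [gaze_series()].
#' @return percentage in `[0, 100]`.
#' @examples
#' gaze_compliance(simulate_gaze_sequence(200, 0.25, seed = 1))  # 25
#' @export
gaze_compliance <- function(gaze) {
  stopifnot(inherits(gaze, "gaze_series"))
  100 * mean(gaze$on_target)
}

#' Reward coins for one exercise session
#'
#' Five coins for completing the exercise, plus zero to five coins for
#' head-speed compliance and zero to five for gaze compliance, each scaled
#' linearly from the percentage and rounded half away from zero.
#'
#' @param completed logical: was the exercise completed?
#' @param head_percent head-speed percent-correct in `[0, 100]`.
#' @param gaze_percent gaze percent-on-target in `[0, 100]`.
#' @return integer coin count in `[0, 15]`.
#' @examples
#' compute_rewards(TRUE, 100, 100)  # 15
#' compute_rewards(TRUE, 0, 0)      # 5
#' @export
compute_rewards <- function(completed, head_percent, gaze_percent) {
  if (!is.logical(completed) || length(completed) != 1L || is.na(completed)) {
    stop("completed: must be TRUE or FALSE", call. = FALSE)
  }
  for (p in list(c(head_percent), c(gaze_percent))) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 100) {
      stop("percent arguments must lie in [0, 100]", call. = FALSE)
    }
  }
  as.integer((if (completed) 5L else 0L) +
               round_half_away(5 * head_percent / 100) +
               round_half_away(5 * gaze_percent / 100))
}
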