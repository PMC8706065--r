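# Head-angle time series container and time-aware smoothing.

#' Head-angle time series
#'
#' A timestamped head-angle signal in a single rotation plane, the common
#' currency of the package: the simulator produces it, the compliance
#' pipeline consumes it, and the validation harness compares two of them.
#'
#' @param times numeric vector of timestamps in seconds, strictly increasing.
#' @param angles numeric vector of head angles in degrees, same length.
#' @param plane rotation plane, one of `"yaw"`, `"pitch"`, `"roll"`.
#' @param source provenance label, one of `"camera"`, `"imu"`, `"synthetic"`.
#' @param meta optional list of free-form metadata (e.g. generator config),
#'   carried through file round-trips.
#'
#' @return an object of class `head_angle_series`: a list with elements
#'   `times`, `angles`, `plane`, `source`, `meta`.
#' @examples
#' s <- head_angle_series(seq(0, 1, 0.1), sin(seq(0, 1, 0.1)), "yaw", "synthetic")
#' length(s$times)
#' @export
head_angle_series <- function(times, angles,
                              plane = c("yaw", "pitch", "roll"),
                              source = c("synthetic", "camera", "imu"),
                              meta = NULL) {
  plane <- match.arg(plane)
  source <- match.arg(source)
  times <- as.numeric(times)
  angles <- as.numeric(angles)
  if (length(times) != length(angles)) {
    stop("times and angles must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a head-angle series needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(times)) || !all(is.finite(angles))) {
    stop("times and angles must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing (violated at sample %d)", i),
         call. = FALSE)
  }
  structure(list(times = times, angles = angles, plane = plane,
                 source = source, meta = meta),
            class = "head_angle_series")
}

#' @export
print.head_angle_series <- function(x, ...) {
  cat(sprintf("<head_angle_series> %d samples, %.2f s, plane=%s, source=%s\n",
              length(x$times), diff(range(x$times)), x$plane, x$source))
  cat(sprintf("  angle range [%.2f, %.2f] deg\n",
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' @export
as.data.frame.head_angle_series <- function(x, ...) {
  data.frame(time_s = x$times, angle_deg = x$angles)
}

#' Time-aware moving-average smoothing
#'
#' Centred moving average over all samples within `window_s / 2` of each
#' timestamp. Because the window is defined in time, not in samples, the
#' filter is robust to the non-uniform frame intervals of camera-derived
#' signals. Endpoints use truncated (one-sided) windows; `window_s = 0`
#' returns the input unchanged.
#'
#' @param series a [head_angle_series()].
#' @param window_s window width in seconds (full width), `>= 0`.
#' @return a smoothed [head_angle_series()] on the same timestamps.
#' @examples
#' s <- simulate_head_motion(sim_config(goal_bpm = 120, duration_s = 5, seed = 1))
#' sm <- smooth_series(s, 0.15)
#' @export
smooth_series <- function(series, window_s = 0.15) {
  stopifnot(inherits(series, "head_angle_series"))
  check_scalar(window_s, "window_s", nonneg = TRUE)
  if (window_s == 0) return(series)
  t <- series$times
  y <- series$angles
  h <- window_s / 2
  # prefix sums + binary search: O(n log n), exact truncated-window means
  cs <- c(0, cumsum(y))
  lo <- findInterval(t - h, t, left.open = TRUE) + 1L   # first index >= t-h
  hi <- findInterval(t + h, t)                          # last index  <= t+h
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  head_angle_series(t, sm, plane = series$plane, source = series$source,
                    meta = series$meta)
}
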