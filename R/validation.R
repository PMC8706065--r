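# Camera-vs-reference (IMU) validation harness.
#
# The reference series (IMU-derived head angle) carries no DC component
# and may lead or lag the camera signal; the harness aligns the two by
# normalized cross-correlation on mean-removed, uniformly resampled
# copies, restores the camera DC to the reference, and then compares
# per-timestamp angles, matched peak timings, per-interval head-turn
# frequency, and compliance percentages.

#' Align a reference series to a camera series
#'
#' Both series are linearly interpolated onto a uniform grid at the median
#' camera frame interval over the overlapping span. The reference is
#' shifted by the lag (positive = camera delayed relative to the
#' reference) maximizing the normalized cross-correlation of the
#' mean-removed signals within `+/- max_lag_s`, the camera-minus-reference
#' mean difference is added as the DC compensation, and the result is
#' resampled onto the camera timestamps.
#'
#' @param camera,reference [head_angle_series()] objects with at least 5 s
#'   of overlapping time span.
#' @param max_lag_s lag search half-width in seconds (default 2).
#' @return list of class `alignment_result`: `lag_s`, `dc_applied_deg`,
#'   `aligned` (a [head_angle_series()] on the camera timestamps),
#'   `grid_dt_s` (the resample interval), `peak_correlation`.
#' @examples
#' p <- simulate_paired_trial(paired_trial_config(sim_config(seed = 2), lag_s = 0.2))
#' align_series(p$camera, p$imu)$lag_s
#' @export
align_series <- function(camera, reference, max_lag_s = 2) {
  stopifnot(inherits(camera, "head_angle_series"),
            inherits(reference, "head_angle_series"))
  check_scalar(max_lag_s, "max_lag_s", positive = TRUE)
  t0 <- max(min(camera$times), min(reference$times))
  t1 <- min(max(camera$times), max(reference$times))
  if (t1 - t0 < 5) {
    stop(sprintf("align_series: overlapping span %.2f s < 5 s", t1 - t0),
         call. = FALSE)
  }
  dt <- stats::median(diff(camera$times))
  grid <- seq(t0, t1, by = dt)
  xc <- stats::approx(camera$times, camera$angles, xout = grid)$y
  xr <- stats::approx(reference$times, reference$angles, xout = grid)$y
  xc0 <- xc - mean(xc)
  xr0 <- xr - mean(xr)
  kmax <- min(length(grid) - 2L, round(max_lag_s / dt))
  # lag k > 0: camera delayed; compare camera[t] with reference[t - k*dt]
  best <- c(k = 0L, r = -Inf)
  for (k in (-kmax):kmax) {
    if (k >= 0) {
      a <- xc0[(k + 1L):length(xc0)]
      b <- xr0[1L:(length(xr0) - k)]
    } else {
      a <- xc0[1L:(length(xc0) + k)]
      b <- xr0[(1L - k):length(xr0)]
    }
    r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    if (is.finite(r) && r > best[["r"]]) best <- c(k = k, r = r)
  }
  lag <- best[["k"]] * dt
  dc <- mean(xc) - mean(xr)
  # reference seen through the camera clock: ref(t - lag) + dc
  aligned <- stats::approx(reference$times + lag, reference$angles + dc,
                           xout = camera$times, rule = 2)$y
  structure(list(
    lag_s = lag, dc_applied_deg = dc,
    aligned = head_angle_series(camera$times, aligned,
                                plane = reference$plane,
                                source = reference$source),
    grid_dt_s = dt, peak_correlation = best[["r"]]
  ), class = "alignment_result")
}

#' Match same-kind extrema between two lists
#'
#' Greedy nearest-in-time one-to-one matching between peaks of `a` and
#' peaks of `b` (and likewise valleys) within `tol_s`. Extrema without a
#' partner — e.g. a head turn one system missed — are counted as dropped
#' and excluded from interpeak statistics.
#'
#' @param a,b `extrema_list` objects (see [detect_extrema()]).
#' @param tol_s matching tolerance in seconds (>= 0).
#' @return list of class `peak_matching`: `pairs` (data.frame `time_a`,
#'   `time_b`, `kind`, sorted by `time_a`), `n_dropped_a`, `n_dropped_b`.
#' @export
match_peaks <- function(a, b, tol_s) {
  stopifnot(inherits(a, "extrema_list"), inherits(b, "extrema_list"))
  check_scalar(tol_s, "tol_s", nonneg = TRUE)
  out <- lapply(c("peak", "valley"), function(k) {
    ta <- a$time[a$kind == k]
    tb <- b$time[b$kind == k]
    if (!length(ta) || !length(tb)) {
      return(list(pairs = NULL, da = length(ta), db = length(tb)))
    }
    cand <- expand.grid(i = seq_along(ta), j = seq_along(tb))
    cand$d <- abs(ta[cand$i] - tb[cand$j])
    cand <- cand[cand$d <= tol_s, , drop = FALSE]
    cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
    used_i <- logical(length(ta)); used_j <- logical(length(tb))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_i[i] && !used_j[j]) {
        keep[r] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    list(pairs = if (nrow(cand)) data.frame(time_a = ta[cand$i],
                                            time_b = tb[cand$j], kind = k),
         da = sum(!used_i), db = sum(!used_j))
  })
  pairs <- do.call(rbind, lapply(out, `[[`, "pairs"))
  if (is.null(pairs)) {
    pairs <- data.frame(time_a = numeric(0), time_b = numeric(0),
                        kind = character(0))
  }
  pairs <- pairs[order(pairs$time_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 n_dropped_a = sum(vapply(out, `[[`, numeric(1), "da")),
                 n_dropped_b = sum(vapply(out, `[[`, numeric(1), "db"))),
            class = "peak_matching")
}

#' Interpeak time error between matched extrema
#'
#' For consecutive matched pairs of the same kind, compares the
#' peak-to-peak interval measured by each system; reports the mean
#' absolute difference and its RMSE.
#'
#' @param matched a `peak_matching` from [match_peaks()].
#' @return list with `mean_abs_error_s`, `rmse_s`, `n_intervals`,
#'   `flagged` (`TRUE` when fewer than 2 matched pairs exist, in which
#'   case the statistics are `NA`).
#' @export
interpeak_errors <- function(matched) {
  stopifnot(inherits(matched, "peak_matching"))
  p <- matched$pairs
  errs <- unlist(lapply(c("peak", "valley"), function(k) {
    pk <- p[p$kind == k, , drop = FALSE]
    if (nrow(pk) < 2L) return(NULL)
    diff(pk$time_a) - diff(pk$time_b)
  }))
  if (is.null(errs) || !length(errs)) {
    return(list(mean_abs_error_s = NA_real_, rmse_s = NA_real_,
                n_intervals = 0L, flagged = TRUE))
  }
  list(mean_abs_error_s = mean(abs(errs)),
       rmse_s = sqrt(mean(errs^2)),
       n_intervals = length(errs), flagged = FALSE)
}

#' Frequency error implied by a peak-to-peak interval error
#'
#' A measured head-turn frequency comes from a peak-to-peak interval whose
#' ideal value is `120 / goal` seconds. An interval error of
#' `err_interval` seconds maps to a bpm error of
#' `goal * (-err_interval / (120/goal + err_interval))`, identical to
#' `120 / (120/goal + err_interval) - goal`. The same interval error
#' produces a larger bpm error at higher goal tempo.
#'
#' @param goal prescribed tempo, bpm (> 0).
#' @param err_interval measured minus ideal peak-to-peak interval,
#'   seconds; must satisfy `120/goal + err_interval > 0`.
#' @return list of class `frequency_error_record`: `goal`, `err_interval`,
#'   `err_bpm`.
#' @examples
#' frequency_error(160, 0.05)$err_bpm  # -10
#' @export
frequency_error <- function(goal, err_interval) {
  check_scalar(goal, "goal", positive = TRUE)
  check_scalar(err_interval, "err_interval")
  ideal <- 120 / goal
  if (ideal + err_interval <= 0) {
    stop("err_interval: measured interval 120/goal + err_interval must be > 0",
         call. = FALSE)
  }
  structure(list(goal = goal, err_interval = err_interval,
                 err_bpm = goal * (-err_interval / (ideal + err_interval))),
            class = "frequency_error_record")
}

#' Full paired-trial validation report
#'
#' Runs the whole harness on one camera/reference pair: alignment (lag +
#' DC), per-timestamp absolute angle error, smoothed peak detection on
#' both signals, peak matching and interpeak statistics, per-interval
#' head-turn frequency error of the camera signal against the prescribed
#' goal, and the compliance percentages of both systems.
#'
#' @param camera,reference [head_angle_series()] objects.
#' @param rx a [prescription()].
#' @param smoothing_window_s smoothing window passed to [smooth_series()].
#' @param max_lag_s lag search bound for [align_series()].
#' @param match_tol_s peak-match tolerance; default half a beat,
#'   `30 / goal_bpm` seconds.
#' @return list of class `validation_report` with fields
#'   `mean_abs_head_angle_error_deg`, `head_angle_rmse_deg`,
#'   `n_peaks_reference`, `n_peaks_camera`,
#'   `mean_matched_interpeak_time_error_s`, `interpeak_time_rmse_s`,
#'   `mean_abs_head_turn_frequency_error_bpm`,
#'   `head_turn_frequency_rmse_bpm`, `percent_correct_reference`,
#'   `percent_correct_camera`, `percent_correct_difference`
#'   (camera minus reference), `lag_s`, `dc_applied_deg`, `n_dropped`.
#' @examples
#' p <- simulate_paired_trial(paired_trial_config(sim_config(seed = 4)))
#' trial_report(p$camera, p$imu, prescription("horizontal", 120))
#' @export
trial_report <- function(camera, reference, rx,
                         smoothing_window_s = 0.15, max_lag_s = 2,
                         match_tol_s = 30 / rx$goal_bpm) {
  stopifnot(inherits(rx, "prescription"))
  al <- align_series(camera, reference, max_lag_s = max_lag_s)
  err <- abs(camera$angles - al$aligned$angles)
  cam_s <- smooth_series(camera, smoothing_window_s)
  ref_s <- smooth_series(al$aligned, smoothing_window_s)
  ex_cam <- detect_extrema(cam_s, rx$min_peak_height_deg)
  ex_ref <- detect_extrema(ref_s, rx$min_peak_height_deg)
  mp <- match_peaks(ex_ref, ex_cam, tol_s = match_tol_s)
  ip <- interpeak_errors(mp)
  rep_cam <- classify_intervals(ex_cam, rx)
  rep_ref <- classify_intervals(ex_ref, rx)
  # camera head-turn frequency: per-trial 120/mean(interval), error vs goal;
  # RMSE over per-interval bpm values
  iv <- rep_cam$intervals$measured_bpm
  dts <- 120 / iv
  trial_freq <- if (length(dts)) 120 / mean(dts) else NA_real_
  structure(list(
    mean_abs_head_angle_error_deg = mean(err),
    head_angle_rmse_deg = sqrt(mean(err^2)),
    n_peaks_reference = rep_ref$n_peaks,
    n_peaks_camera = rep_cam$n_peaks,
    mean_matched_interpeak_time_error_s = ip$mean_abs_error_s,
    interpeak_time_rmse_s = ip$rmse_s,
    mean_abs_head_turn_frequency_error_bpm =
      if (is.na(trial_freq)) NA_real_ else abs(trial_freq - rx$goal_bpm),
    head_turn_frequency_rmse_bpm =
      if (length(iv)) sqrt(mean((iv - rx$goal_bpm)^2)) else NA_real_,
    percent_correct_reference = rep_ref$percent_correct,
    percent_correct_camera = rep_cam$percent_correct,
    percent_correct_difference =
      rep_cam$percent_correct - rep_ref$percent_correct,
    lag_s = al$lag_s, dc_applied_deg = al$dc_applied_deg,
    n_dropped = mp$n_dropped_a + mp$n_dropped_b,
    n_matched_intervals = ip$n_intervals
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  lag %.3f s, DC %.2f deg\n", x$lag_s, x$dc_applied_deg))
  cat(sprintf("  mean abs angle error %.2f deg (RMSE %.2f)\n",
              x$mean_abs_head_angle_error_deg, x$head_angle_rmse_deg))
  cat(sprintf("  peaks ref/cam %d/%d, interpeak err %.3f s (RMSE %.3f)\n",
              x$n_peaks_reference, x$n_peaks_camera,
              x$mean_matched_interpeak_time_error_s, x$interpeak_time_rmse_s))
  cat(sprintf("  percent correct ref %.2f cam %.2f (diff %.2f)\n",
              x$percent_correct_reference, x$percent_correct_camera,
              x$percent_correct_difference))
  invisible(x)
}

#' Confusion matrix for binary gaze classification
#'
#' Positive class = on-target.
#'
#' @param tn,fp,fn,tp non-negative counts, total > 0.
#' @return list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  for (nm in c("tn", "fp", "fn", "tp")) {
    check_scalar(get(nm), nm, nonneg = TRUE, integerish = TRUE)
  }
  if (tn + fp + fn + tp <= 0) {
    stop("confusion matrix total must be > 0", call. = FALSE)
  }
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1 for the on-target class. A zero
#' denominator yields `NA` with the metric named in `undefined` — never a
#' silent 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list of class `classification_metrics`: `accuracy`,
#'   `precision`, `recall`, `f1`, `undefined` (character vector of metric
#'   names with zero denominators).
#' @examples
#' m <- classification_metrics(confusion_matrix(tn = 2002, fp = 72,
#'                                              fn = 107, tp = 951))
#' round(m$accuracy, 4)  # 0.9428
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  undefined <- character(0)
  accuracy <- (cm$tp + cm$tn) / total
  if (cm$tp + cm$fp > 0) {
    precision <- cm$tp / (cm$tp + cm$fp)
  } else {
    precision <- NA_real_; undefined <- c(undefined, "precision")
  }
  if (cm$tp + cm$fn > 0) {
    recall <- cm$tp / (cm$tp + cm$fn)
  } else {
    recall <- NA_real_; undefined <- c(undefined, "recall")
  }
  if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    f1 <- 2 * precision * recall / (precision + recall)
  } else {
    f1 <- NA_real_; undefined <- c(undefined, "f1")
  }
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, undefined = undefined),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %s  recall %s  f1 %s\n",
              x$accuracy,
              ifelse(is.na(x$precision), "undefined", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$recall), "undefined", sprintf("%.4f", x$recall)),
              ifelse(is.na(x$f1), "undefined", sprintf("%.4f", x$f1))))
  invisible(x)
}
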