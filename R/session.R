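# Session records, symptom ratings and report rendering.
#
# Units are fixed package-wide: angles in degrees, times in seconds,
# tempi in beats per minute. Symptom ratings follow the vestibular/
# ocular-motor screening (VOMS) format: a continuous 0 (no symptom) to 10
# (as bad as it can get) scale; perceived difficulty is a discrete 0
# (extremely easy) to 10 (extremely hard) integer.

#' Pre- or post-exercise symptom record
#'
#' @param dizziness,headache,nausea,fogginess ratings on the continuous
#'   `[0, 10]` scale.
#' @param phase `"pre"` or `"post"`.
#' @return list of class `symptom_record`.
#' @export
symptom_record <- function(dizziness, headache, nausea, fogginess,
                           phase = c("pre", "post")) {
  phase <- match.arg(phase)
  vals <- list(dizziness = dizziness, headache = headache,
               nausea = nausea, fogginess = fogginess)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 10) {
      stop(sprintf("%s: rating must lie in [0, 10]", nm), call. = FALSE)
    }
  }
  structure(c(vals, list(phase = phase)), class = "symptom_record")
}

#' Perceived-difficulty rating
#'
#' @param value integer in `[0, 10]` (0 extremely easy, 10 extremely hard).
#' @return list of class `difficulty_rating`.
#' @export
difficulty_rating <- function(value) {
  check_scalar(value, "difficulty", nonneg = TRUE, integerish = TRUE)
  if (value > 10) stop("difficulty: must lie in [0, 10]", call. = FALSE)
  structure(list(value = as.integer(value)), class = "difficulty_rating")
}

#' Per-symptom change from pre to post
#'
#' @param pre,post [symptom_record()]s with phases `"pre"` and `"post"`.
#' @return named numeric vector of post-minus-pre changes; positive means
#'   worsening.
#' @examples
#' symptom_delta(symptom_record(2, 0, 0, 1, "pre"),
#'               symptom_record(5, 0, 1, 1, "post"))
#' @export
symptom_delta <- function(pre, post) {
  stopifnot(inherits(pre, "symptom_record"), inherits(post, "symptom_record"))
  if (pre$phase != "pre" || post$phase != "post") {
    stop("symptom_delta: expected a 'pre' and a 'post' record (in that order)",
         call. = FALSE)
  }
  nm <- c("dizziness", "headache", "nausea", "fogginess")
  vapply(nm, function(k) post[[k]] - pre[[k]], numeric(1))
}

#' Assemble a session record
#'
#' @param rx a [prescription()].
#' @param compliance a `compliance_report` from [classify_intervals()].
#' @param gaze_percent gaze percent-on-target in `[0, 100]`.
#' @param pre a pre-exercise [symptom_record()].
#' @param post a post-exercise [symptom_record()], or `NULL` when the
#'   exercise was not completed (a post record implies completion).
#' @param difficulty a [difficulty_rating()] or `NULL`.
#' @param completed logical; must be `TRUE` whenever `post` is given.
#' @param timestamp session timestamp string (default: current UTC time).
#' @return list of class `session_record`; coins are computed here via
#'   [compute_rewards()].
#' @export
session_record <- function(rx, compliance, gaze_percent, pre, post = NULL,
                           difficulty = NULL, completed = !is.null(post),
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                              tz = "UTC")) {
  stopifnot(inherits(rx, "prescription"),
            inherits(compliance, "compliance_report"),
            inherits(pre, "symptom_record"))
  if (!is.null(post) && !inherits(post, "symptom_record")) {
    stop("post must be a symptom_record or NULL", call. = FALSE)
  }
  if (!is.null(post) && !completed) {
    stop("a post-exercise record is only valid for a completed exercise",
         call. = FALSE)
  }
  head_pct <- if (compliance$flagged) 0 else compliance$percent_correct
  structure(list(
    prescription = rx, compliance = compliance,
    gaze_percent = gaze_percent, pre = pre, post = post,
    difficulty = difficulty, completed = completed,
    coins = compute_rewards(completed, head_pct, gaze_percent),
    timestamp = timestamp
  ), class = "session_record")
}

#' Render a session report
#'
#' Deterministic human-readable text plus a JSON summary (numbers to two
#' decimals) mirroring the schema shipped at
#' `system.file("schema", "session-report-schema.json", package = "vorx")`.
#' An incomplete session (no post-symptom record) is flagged as partial.
#'
#' @param session a [session_record()].
#' @return list with elements `text` (character vector of lines) and
#'   `json` (single JSON string).
#' @export
render_report <- function(session) {
  stopifnot(inherits(session, "session_record"))
  rx <- session$prescription
  comp <- session$compliance
  head_pct <- if (comp$flagged) NA_real_ else comp$percent_correct
  deltas <- if (!is.null(session$post)) {
    as.list(round(symptom_delta(session$pre, session$post), 2))
  } else NULL
  obj <- list(
    timestamp = session$timestamp,
    complete = session$completed,
    prescription = list(direction = rx$direction, goal_bpm = rx$goal_bpm,
                        duration_s = rx$duration_s,
                        compliance_delta_bpm = rx$compliance_delta_bpm),
    head_speed = list(
      percent_correct = round2_or_null(head_pct),
      mean_bpm = round2_or_null(comp$mean_bpm),
      n_peaks = comp$n_peaks, n_valleys = comp$n_valleys,
      n_intervals = nrow(comp$intervals)),
    gaze = list(percent_on_target = round2_or_null(session$gaze_percent)),
    coins = session$coins,
    symptoms = list(
      pre = symptoms_as_list(session$pre),
      post = if (!is.null(session$post)) symptoms_as_list(session$post),
      delta = deltas),
    difficulty = if (!is.null(session$difficulty)) session$difficulty$value
  )
  obj <- drop_nulls(obj)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    sprintf("VORx1 session report  [%s]%s", session$timestamp,
            if (session$completed) "" else "  (INCOMPLETE)"),
    sprintf("  prescription: %s, %g bpm (+/- %g) for %g s",
            rx$direction, rx$goal_bpm, rx$compliance_delta_bpm, rx$duration_s),
    sprintf("  head speed:   %s%% correct (%d peaks / %d valleys)",
            fmt2(head_pct), comp$n_peaks, comp$n_valleys),
    sprintf("  gaze:         %s%% on target", fmt2(session$gaze_percent)),
    sprintf("  coins:        %d", session$coins),
    if (!is.null(deltas)) {
      sprintf("  symptom change (post - pre): %s",
              paste(sprintf("%s %+0.2f", names(deltas), unlist(deltas)),
                    collapse = ", "))
    } else "  symptom change: unavailable (exercise incomplete)"
  )
  list(text = txt, json = as.character(json))
}

fmt2 <- function(x) if (is.null(x) || is.na(x)) "NA" else sprintf("%.2f", x)
round2_or_null <- function(x) if (is.null(x) || is.na(x)) NULL else round(x, 2)
symptoms_as_list <- function(s) {
  lapply(s[c("dizziness", "headache", "nausea", "fogginess")],
         function(v) round(v, 2))
}
drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_nulls)
  x[!vapply(x, is.null, logical(1))]
}

#' Write a head-angle series to CSV (with JSON sidecar)
#'
#' CSV with header `time_s,angle_deg` at full precision; plane/source and
#' any generator metadata go to `<path>.json`.
#'
#' @param series a [head_angle_series()].
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sidecar = TRUE) {
  stopifnot(inherits(series, "head_angle_series"))
  df <- data.frame(time_s = format(series$times, digits = 17, trim = TRUE,
                                   scientific = FALSE),
                   angle_deg = format(series$angles, digits = 17, trim = TRUE,
                                      scientific = FALSE))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  if (sidecar) {
    meta <- list(plane = series$plane, source = series$source,
                 units = list(time = "s", angle = "deg"),
                 meta = series$meta)
    jsonlite::write_json(drop_nulls(meta), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a head-angle series from CSV
#'
#' Expects the exact header `time_s,angle_deg`. Malformed rows and
#' non-monotone timestamps are rejected with the offending file line
#' named. If `<path>.json` exists, plane/source/meta are restored from it.
#'
#' @param path CSV path.
#' @return a [head_angle_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1L]) != "time_s,angle_deg") {
    stop(sprintf("%s: missing or wrong header (expected 'time_s,angle_deg')",
                 path), call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) {
    stop(sprintf("%s: malformed row at line %d", path, bad[1L] + 1L),
         call. = FALSE)
  }
  t <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(t) | is.na(y))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value at line %d", path, bad[1L] + 1L),
         call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1L] + 1L
    stop(sprintf("%s: times not strictly increasing at line %d", path, i + 1L),
         call. = FALSE)
  }
  plane <- "yaw"; source <- "camera"; meta <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    info <- jsonlite::read_json(sc, simplifyVector = TRUE)
    plane <- info$plane %||% plane
    source <- info$source %||% source
    meta <- info$meta
  }
  head_angle_series(t, y, plane = plane, source = source, meta = meta)
}
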