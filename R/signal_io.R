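# File formats and typed session containers.
#
# All files are plain comma-separated text with a mandatory header row, dot
# decimal separator, UTF-8. Parsing is header-driven: column order never
# matters. Times are seconds from trial start; angular velocity is in deg/s.

#' Construct a tri-axial gyroscope recording
#'
#' A uniformly sampled tri-axial angular-velocity time series for one walking
#' trial. Samples are implicitly spaced at `1/sample_rate` starting at
#' `start_time`.
#'
#' @param gyro Numeric matrix with one row per sample and three columns
#'   (angular velocity about x, y, z in deg/s).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param participant_id Participant identifier string.
#' @param condition One of [GAIT_CONDITIONS].
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `gyro_recording`.
#' @export
gyro_recording <- function(gyro, sample_rate, participant_id = "unknown",
                           condition = "PRE_NP", start_time = 0) {
  gyro <- as.matrix(gyro)
  if (ncol(gyro) != 3L) stopf("gyro must have 3 columns, got %d", ncol(gyro))
  if (nrow(gyro) < 1L) stopf("gyro recording must contain at least one sample")
  if (!all(is.finite(gyro))) stopf("gyro recording contains non-finite values")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stopf("sample_rate must be a single positive number")
  }
  condition <- match.arg(condition, GAIT_CONDITIONS)
  colnames(gyro) <- c("x", "y", "z")
  structure(
    list(participant_id = as.character(participant_id), condition = condition,
         sample_rate = sample_rate, gyro = gyro, start_time = start_time),
    class = "gyro_recording"
  )
}

#' @export
print.gyro_recording <- function(x, ...) {
  cat(sprintf("<gyro_recording> %s / %s: %d samples @ %g Hz (%.2f s)\n",
              x$participant_id, x$condition, nrow(x$gyro), x$sample_rate,
              nrow(x$gyro) / x$sample_rate))
  invisible(x)
}

# time span covered by the recording's samples, half-open [start, end)
recording_span <- function(rec) {
  c(rec$start_time, rec$start_time + nrow(rec$gyro) / rec$sample_rate)
}

#' Construct a validated gait-event table
#'
#' @param events Data frame with columns `time_s` (seconds), `side`
#'   (`"pro"`/`"nonpro"`), `event` (`"foot_strike"`/`"foot_off"`).
#'   Within each side, times must be strictly increasing and foot-strike /
#'   foot-off must strictly alternate. An empty table is valid.
#' @return An object of class `gait_events` (also a data frame).
#' @export
gait_events <- function(events) {
  events <- as.data.frame(events)
  need <- c("time_s", "side", "event")
  miss <- setdiff(need, names(events))
  if (length(miss)) stopf("event table missing column(s): %s", paste(miss, collapse = ", "))
  events <- events[need]
  if (nrow(events)) {
    events$time_s <- as.numeric(events$time_s)
    events$side <- as.character(events$side)
    events$event <- as.character(events$event)
    if (!all(is.finite(events$time_s))) stopf("event times must be finite")
    bad_side <- which(!events$side %in% GAIT_SIDES)
    if (length(bad_side)) stopf("row %d: unknown side '%s'", bad_side[1], events$side[bad_side[1]])
    bad_ev <- which(!events$event %in% c("foot_strike", "foot_off"))
    if (length(bad_ev)) stopf("row %d: unknown event '%s'", bad_ev[1], events$event[bad_ev[1]])
    for (s in unique(events$side)) {
      rows <- which(events$side == s)
      tt <- events$time_s[rows]
      if (any(diff(tt) <= 0)) {
        i <- rows[which(diff(tt) <= 0)[1] + 1L]
        stopf("row %d: times for side '%s' are not strictly increasing", i, s)
      }
      ee <- events$event[rows]
      alt <- which(ee[-1] == ee[-length(ee)])
      if (length(alt)) {
        i <- rows[alt[1] + 1L]
        stopf("row %d: consecutive '%s' events for side '%s' (foot_strike/foot_off must alternate)",
              i, ee[alt[1] + 1L], s)
      }
    }
  }
  class(events) <- c("gait_events", "data.frame")
  events
}

#' Construct a joint-angle trace
#'
#' @param values Numeric vector of joint angles in degrees, uniformly sampled.
#' @param sample_rate Sampling rate in Hz.
#' @param joint One of [GAIT_JOINTS].
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `angle_trace`.
#' @export
angle_trace <- function(values, sample_rate, joint, start_time = 0) {
  values <- as.numeric(values)
  if (!length(values) || !all(is.finite(values))) stopf("angle trace must be non-empty and finite")
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  joint <- match.arg(joint, GAIT_JOINTS)
  structure(list(joint = joint, plane = "FLEX_EXT", sample_rate = sample_rate,
                 values = values, start_time = start_time),
            class = "angle_trace")
}

#' Construct a foot forward-position trace
#'
#' @param positions Numeric vector of forward-axis displacement in meters.
#' @param sample_rate Sampling rate in Hz.
#' @param side `"pro"` or `"nonpro"`.
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `foot_position_trace`.
#' @export
foot_position_trace <- function(positions, sample_rate, side, start_time = 0) {
  positions <- as.numeric(positions)
  if (!length(positions) || !all(is.finite(positions))) stopf("position trace must be non-empty and finite")
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  side <- match.arg(side, GAIT_SIDES)
  structure(list(side = side, sample_rate = sample_rate, positions = positions,
                 start_time = start_time),
            class = "foot_position_trace")
}

trace_time <- function(trace) {
  n <- length(trace$values %||% trace$positions)
  trace$start_time + (seq_len(n) - 1) / trace$sample_rate
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------- readers ----

read_checked_csv <- function(path, need) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  df[need]
}

#' Read a tri-axial gyroscope CSV
#'
#' Expects columns `time_s,gyro_x,gyro_y,gyro_z` (any order; header-driven).
#' The declared sampling rate is checked against the median inter-sample
#' interval; a mismatch beyond 1% is an error, never silently resampled.
#'
#' @param path Path to the CSV file.
#' @param participant_id Participant identifier.
#' @param condition One of [GAIT_CONDITIONS].
#' @param sample_rate Declared sampling rate in Hz.
#' @return A [gyro_recording].
#' @export
read_gyro_csv <- function(path, participant_id = "unknown",
                          condition = "PRE_NP", sample_rate = 100) {
  df <- read_checked_csv(path, c("time_s", "gyro_x", "gyro_y", "gyro_z"))
  for (nm in names(df)) df[[nm]] <- as.numeric(df[[nm]])
  if (!all(vapply(df, function(v) all(is.finite(v)), logical(1)))) {
    stopf("%s: non-numeric or non-finite values", path)
  }
  if (nrow(df) < 1L) stopf("%s: no samples", path)
  if (nrow(df) > 1L) {
    if (any(diff(df$time_s) <= 0)) stopf("%s: time column is not strictly increasing", path)
    dt <- stats::median(diff(df$time_s))
    if (abs(dt * sample_rate - 1) > 0.01) {
      stopf("%s: median interval %.6g s is inconsistent with declared %g Hz (>1%% off)",
            path, dt, sample_rate)
    }
  }
  gyro_recording(cbind(df$gyro_x, df$gyro_y, df$gyro_z), sample_rate,
                 participant_id = participant_id, condition = condition,
                 start_time = df$time_s[1])
}

#' Write a gyroscope recording to CSV
#'
#' @param recording A [gyro_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(recording, path) {
  n <- nrow(recording$gyro)
  tt <- recording$start_time + (seq_len(n) - 1) / recording$sample_rate
  lines <- paste(fmt_num(tt), fmt_num(recording$gyro[, 1]),
                 fmt_num(recording$gyro[, 2]), fmt_num(recording$gyro[, 3]),
                 sep = ",")
  writeLines(c("time_s,gyro_x,gyro_y,gyro_z", lines), path)
  invisible(path)
}

#' Read a gait-event CSV
#'
#' Expects columns `time_s,side,event` with `side` in `pro`/`nonpro` and
#' `event` in `foot_strike`/`foot_off`. An empty body yields a valid empty
#' table. Alternation violations are reported with the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A [gait_events] table.
#' @export
read_events_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "side", "event"))
  gait_events(df)
}

#' Write a gait-event table to CSV
#'
#' @param events A [gait_events] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  lines <- if (nrow(events)) {
    paste(fmt_num(events$time_s), events$side, events$event, sep = ",")
  } else character()
  writeLines(c("time_s,side,event", lines), path)
  invisible(path)
}

#' Read joint-angle traces from a long-format CSV
#'
#' Expects columns `time_s,joint,angle_deg`; one uniformly sampled trace per
#' joint. The sampling rate of each trace is inferred from its median
#' inter-sample interval.
#'
#' @param path Path to the CSV file.
#' @return Named list of [angle_trace] objects, one per joint present.
#' @export
read_angles_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "joint", "angle_deg"))
  df$time_s <- as.numeric(df$time_s)
  df$angle_deg <- as.numeric(df$angle_deg)
  out <- list()
  for (j in unique(df$joint)) {
    sub <- df[df$joint == j, ]
    sub <- sub[order(sub$time_s), ]
    if (nrow(sub) < 2L) stopf("%s: joint %s has fewer than 2 samples", path, j)
    dt <- stats::median(diff(sub$time_s))
    out[[j]] <- angle_trace(sub$angle_deg, 1 / dt, joint = j, start_time = sub$time_s[1])
  }
  out
}

#' Write joint-angle traces to a long-format CSV
#'
#' @param traces Named list of [angle_trace] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(traces, path) {
  blocks <- lapply(traces, function(tr) {
    paste(fmt_num(trace_time(tr)), tr$joint, fmt_num(tr$values), sep = ",")
  })
  writeLines(c("time_s,joint,angle_deg", unlist(blocks, use.names = FALSE)), path)
  invisible(path)
}

#' Read foot-position traces from a long-format CSV
#'
#' Expects columns `time_s,side,pos_m`; one uniformly sampled trace per side.
#'
#' @param path Path to the CSV file.
#' @return Named list (`pro`, `nonpro`) of [foot_position_trace] objects.
#' @export
read_positions_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "side", "pos_m"))
  df$time_s <- as.numeric(df$time_s)
  df$pos_m <- as.numeric(df$pos_m)
  out <- list()
  for (s in unique(df$side)) {
    sub <- df[df$side == s, ]
    sub <- sub[order(sub$time_s), ]
    if (nrow(sub) < 2L) stopf("%s: side %s has fewer than 2 samples", path, s)
    dt <- stats::median(diff(sub$time_s))
    out[[s]] <- foot_position_trace(sub$pos_m, 1 / dt, side = s, start_time = sub$time_s[1])
  }
  out
}

#' Write foot-position traces to a long-format CSV
#'
#' @param traces Named list (`pro`, `nonpro`) of [foot_position_trace] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions_csv <- function(traces, path) {
  blocks <- lapply(traces, function(tr) {
    paste(fmt_num(trace_time(tr)), tr$side, fmt_num(tr$positions), sep = ",")
  })
  writeLines(c("time_s,side,pos_m", unlist(blocks, use.names = FALSE)), path)
  invisible(path)
}

# ------------------------------------------------------------ result JSON ----

#' Write a classification result to JSON
#'
#' Serializes a [classification_result] (per-fold accuracies, mean and SD
#' accuracy per class, F1, and per-condition classified fractions) so that it
#' round-trips losslessly through [read_result_json()].
#'
#' @param result A [classification_result].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "classification_result"))
  payload <- unclass(result)
  payload$fold_accuracy <- as.data.frame(result$fold_accuracy)
  # named numeric vectors must become named lists or jsonlite drops the names
  payload$accuracy_mean <- as.list(result$accuracy_mean)
  payload$accuracy_sd <- as.list(result$accuracy_sd)
  payload$fractions <- lapply(result$fractions, as.list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a classification result from JSON
#'
#' Companion reader to [write_result_json()].
#'
#' @param path Path to the JSON file.
#' @return A [classification_result].
#' @export
read_result_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fold_accuracy <- as.data.frame(x$fold_accuracy)
  x$accuracy_mean <- unlist(x$accuracy_mean)
  x$accuracy_sd <- unlist(x$accuracy_sd)
  x$fractions <- lapply(x$fractions, function(f) {
    vapply(f, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  })
  class(x) <- "classification_result"
  x
}
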