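#' @keywords internal
"_PACKAGE"

# Physical limits of the sensor hardware the data model targets:
# accelerometer full range +/-6 g, gyroscope full range +/-500 deg/s.
ACCEL_RANGE_G <- 6
GYRO_RANGE_DPS <- 500

ACCEL_COLS <- c("ax", "ay", "az")
GYRO_COLS <- c("gx", "gy", "gz")
CHANNEL_COLS <- c(ACCEL_COLS, GYRO_COLS)

KNOWN_SENSORS <- as.vector(outer(
  c("wrist", "elbow1", "elbow2", "shoulder"),
  c("left", "right"), paste, sep = "_"))

#' Construct a single-sensor inertial stream
#'
#' A sensor stream is the time-ordered recording of one body-worn inertial
#' unit: tri-axial linear acceleration in g-units and tri-axial angular
#' rate in degrees per second, sampled at a nominal rate (50 Hz for the
#' target hardware).
#'
#' @param sensor_id placement label, e.g. `"wrist_right"`.
#' @param samples data frame with columns `t_s, ax, ay, az, gx, gy, gz`;
#'   `t_s` is seconds from session start, strictly increasing.
#' @param sample_rate_hz nominal sampling rate in Hz.
#' @param validate check invariants (monotone time, sensor ranges, gap
#'   regularity). Disable only for streams already validated upstream.
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(sensor_id, samples, sample_rate_hz = 50,
                          validate = TRUE) {
  stopifnot(is.character(sensor_id), length(sensor_id) == 1L,
            is.data.frame(samples), sample_rate_hz > 0)
  need <- c("t_s", CHANNEL_COLS)
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L) {
    stop("sensor_stream: missing column(s): ", paste(miss, collapse = ", "))
  }
  samples <- as.data.frame(samples)[need]
  rownames(samples) <- NULL
  x <- structure(
    list(sensor_id = sensor_id,
         sample_rate_hz = as.numeric(sample_rate_hz),
         samples = samples),
    class = "sensor_stream")
  if (validate) validate_sensor_stream(x)
  x
}

validate_sensor_stream <- function(x) {
  s <- x$samples
  if (nrow(s) == 0L) return(invisible(x))
  if (anyNA(s) || !all(vapply(s, is.numeric, logical(1)))) {
    stop("sensor_stream [", x$sensor_id, "]: non-numeric or missing values")
  }
  if (any(s$t_s < 0)) stop("sensor_stream [", x$sensor_id, "]: negative timestamps")
  dt <- diff(s$t_s)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stop("sensor_stream [", x$sensor_id, "]: timestamps not strictly ",
         "increasing at row ", i + 1L, " (t = ", s$t_s[i + 1L], ")")
  }
  nominal <- 1 / x$sample_rate_hz
  if (length(dt) > 0L && any(abs(dt - nominal) > 0.5 * nominal)) {
    i <- which(abs(dt - nominal) > 0.5 * nominal)[1L]
    stop("sensor_stream [", x$sensor_id, "]: inter-sample gap ",
         signif(dt[i], 4), " s at row ", i + 1L,
         " deviates more than 50% from nominal ", signif(nominal, 4), " s")
  }
  acc <- as.matrix(s[ACCEL_COLS])
  if (any(!is.finite(acc)) || any(abs(acc) > ACCEL_RANGE_G)) {
    stop("sensor_stream [", x$sensor_id, "]: acceleration outside +/-",
         ACCEL_RANGE_G, " g")
  }
  gyr <- as.matrix(s[GYRO_COLS])
  if (any(!is.finite(gyr)) || any(abs(gyr) > GYRO_RANGE_DPS)) {
    stop("sensor_stream [", x$sensor_id, "]: angular rate outside +/-",
         GYRO_RANGE_DPS, " deg/s")
  }
  invisible(x)
}

#' Construct a multi-sensor session recording
#'
#' A session bundles one or more synchronized sensor streams sharing a
#' common time origin (t = 0 at session start).
#'
#' @param streams list of [sensor_stream()] objects.
#' @param participant_id participant label.
#' @param duration_s session length in seconds; defaults to the latest
#'   timestamp plus one sample period.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(streams, participant_id = "anonymous",
                              duration_s = NULL) {
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  stopifnot(length(streams) >= 1L,
            all(vapply(streams, inherits, logical(1), "sensor_stream")))
  names(streams) <- vapply(streams, `[[`, character(1), "sensor_id")
  if (anyDuplicated(names(streams))) {
    stop("session_recording: duplicated sensor_id among streams")
  }
  if (is.null(duration_s)) {
    ends <- vapply(streams, function(s) {
      if (nrow(s$samples) == 0L) 0 else max(s$samples$t_s) + 1 / s$sample_rate_hz
    }, numeric(1))
    duration_s <- max(ends)
  }
  structure(
    list(participant_id = participant_id,
         streams = streams,
         duration_s = as.numeric(duration_s)),
    class = "session_recording")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat("<sensor_stream> ", x$sensor_id, ": ", nrow(x$samples),
      " samples @ ", x$sample_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording> participant ", x$participant_id, ", ",
      length(x$streams), " sensor(s), ", round(x$duration_s, 2), " s\n",
      sep = "")
  for (s in x$streams) {
    cat("  ", s$sensor_id, ": ", nrow(s$samples), " samples @ ",
        s$sample_rate_hz, " Hz\n", sep = "")
  }
  invisible(x)
}

#' List the sensors present in a session
#' @param session a [session_recording()].
#' @return character vector of sensor placement labels.
#' @export
session_sensors <- function(session) {
  stopifnot(inherits(session, "session_recording"))
  names(session$streams)
}

#' Extract one sensor stream from a session
#' @param session a [session_recording()].
#' @param sensor_id placement label of the wanted stream.
#' @return a [sensor_stream()].
#' @export
get_stream <- function(session, sensor_id) {
  stopifnot(inherits(session, "session_recording"))
  if (!sensor_id %in% names(session$streams)) {
    stop("sensor '", sensor_id, "' not present; available: ",
         paste(names(session$streams), collapse = ", "))
  }
  session$streams[[sensor_id]]
}

#' Construct a table of detected puff-movement events
#'
#' An SPM (sequence of puff movements) is one hand-to-mouth-and-back arm
#' cycle: upward movement, inhalation hold, downward movement. Events are
#' half-open intervals `[start_s, end_s)`.
#'
#' @param start_s,end_s event boundaries in seconds.
#' @param source one of `"edge"`, `"svm"`, `"truth"` per event (recycled).
#' @param confidence non-negative detector confidence or `NA` (the edge
#'   detector emits none).
#' @return data frame of class `spm_events`, sorted by `start_s`.
#' @export
spm_events <- function(start_s = numeric(), end_s = numeric(),
                       source = character(), confidence = NA_real_) {
  n <- length(start_s)
  stopifnot(length(end_s) == n)
  if (n > 0L && any(end_s <= start_s)) {
    stop("spm_events: every event must have end_s > start_s")
  }
  out <- data.frame(
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    source = if (n == 0L) character() else rep_len(as.character(source), n),
    confidence = if (n == 0L) numeric() else rep_len(as.numeric(confidence), n)
  )
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spm_events", "data.frame")
  out
}

#' Construct a table of interval annotations
#'
#' The machine form of human-observed ground truth: labelled half-open
#' intervals of kind `puff`, `spm` or `cigarette`. Within a kind,
#' intervals must not overlap.
#'
#' @param kind annotation kind per row.
#' @param start_s,end_s interval bounds in seconds, `end_s > start_s >= 0`.
#' @param cigarette_index 1-based index of the cigarette a puff/spm
#'   belongs to, or `NA`.
#' @return data frame of class `annotations`, sorted by `start_s`.
#' @export
annotations <- function(kind = character(), start_s = numeric(),
                        end_s = numeric(), cigarette_index = NA_integer_) {
  n <- length(start_s)
  stopifnot(length(end_s) == n, length(kind) %in% c(1L, n) || n == 0L)
  out <- data.frame(
    kind = if (n == 0L) character() else rep_len(as.character(kind), n),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    cigarette_index = if (n == 0L) integer()
                      else rep_len(as.integer(cigarette_index), n)
  )
  validate_annotations(out)
  out <- out[order(out$start_s, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotations", "data.frame")
  out
}

validate_annotations <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  bad_kind <- setdiff(unique(df$kind), c("puff", "spm", "cigarette"))
  if (length(bad_kind) > 0L) {
    stop("annotations: unknown kind(s): ", paste(bad_kind, collapse = ", "))
  }
  if (any(df$start_s < 0) || any(df$end_s <= df$start_s)) {
    stop("annotations: intervals must satisfy end_s > start_s >= 0")
  }
  for (k in unique(df$kind)) {
    sub <- df[df$kind == k, , drop = FALSE]
    sub <- sub[order(sub$start_s), , drop = FALSE]
    if (nrow(sub) > 1L) {
      ov <- which(sub$start_s[-1L] < sub$end_s[-nrow(sub)])
      if (length(ov) > 0L) {
        i <- ov[1L]
        stop("annotations: overlapping '", k, "' intervals [",
             sub$start_s[i], ", ", sub$end_s[i], ") and [",
             sub$start_s[i + 1L], ", ", sub$end_s[i + 1L], ")")
      }
    }
  }
  invisible(df)
}

#' Convert detected events to the annotation representation
#' @param events an [spm_events()] table (or cigarette table).
#' @param kind annotation kind to stamp on every row.
#' @return an [annotations()] table.
#' @export
events_as_annotations <- function(events, kind = "spm") {
  annotations(kind = kind, start_s = events$start_s, end_s = events$end_s)
}
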