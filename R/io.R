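# Plain-text interchange formats.
#
# Session CSV: t_s,sensor_id,ax,ay,az,gx,gy,gz  (one row per timestamp and
# sensor; acceleration in g, angular rate in deg/s, "." decimal separator).
# Annotation CSV: kind,start_s,end_s,cigarette_index.

SESSION_COLS <- c("t_s", "sensor_id", CHANNEL_COLS)
ANNOTATION_COLS <- c("kind", "start_s", "end_s", "cigarette_index")

#' Read a multi-sensor session from CSV
#'
#' Rows are partitioned by `sensor_id` into time-sorted streams; units are
#' taken verbatim (acceleration in g, angular rate in deg/s).
#'
#' @param path CSV file with columns `t_s,sensor_id,ax,ay,az,gx,gy,gz`.
#' @param sample_rate_hz nominal rate of every stream, in Hz.
#' @param participant_id label stored on the recording.
#' @return a [session_recording()].
#' @export
read_session <- function(path, sample_rate_hz = 50,
                         participant_id = "anonymous") {
  if (!file.exists(path)) stop("session file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(SESSION_COLS, names(df))
  if (length(miss) > 0L) {
    stop("session file ", path, ": missing column(s): ",
         paste(miss, collapse = ", "))
  }
  streams <- lapply(split(df, df$sensor_id), function(sub) {
    sub <- sub[order(sub$t_s), , drop = FALSE]
    sensor_stream(sub$sensor_id[1L], sub[c("t_s", CHANNEL_COLS)],
                  sample_rate_hz = sample_rate_hz)
  })
  session_recording(unname(streams), participant_id = participant_id)
}

#' Write a session recording to CSV
#'
#' Inverse of [read_session()]: numeric values are written with enough
#' digits (15 significant) for a lossless round trip at double precision.
#'
#' @param session a [session_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_recording"))
  rows <- lapply(session$streams, function(s) {
    if (nrow(s$samples) == 0L) return(NULL)
    cbind(s$samples["t_s"], sensor_id = s$sensor_id,
          s$samples[CHANNEL_COLS])
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(t_s = numeric(), sensor_id = character())
    for (cn in CHANNEL_COLS) df[[cn]] <- numeric()
  }
  write_csv15(df[SESSION_COLS], path)
  invisible(path)
}

#' Read interval annotations from CSV
#'
#' @param path CSV file with columns `kind,start_s,end_s` (and optionally
#'   `cigarette_index`).
#' @return an [annotations()] table sorted by `start_s`; overlapping
#'   intervals within a kind are rejected.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("kind", "start_s", "end_s"), names(df))
  if (length(miss) > 0L) {
    stop("annotation file ", path, ": missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(df$cigarette_index)) df$cigarette_index <- NA_integer_
  annotations(df$kind, df$start_s, df$end_s, df$cigarette_index)
}

#' Write interval annotations to CSV
#' @param ann an [annotations()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  write_csv15(as.data.frame(ann)[ANNOTATION_COLS], path)
  invisible(path)
}

# CSV writer with 15 significant digits so numeric round trips are exact
# at the precision we declare.
write_csv15 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    v <- df[[cn]]
    df[[cn]] <- ifelse(is.na(v), "",
                       trimws(formatC(v, digits = 15, format = "g")))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}
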