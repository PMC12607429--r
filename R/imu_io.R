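# Reading, writing and validation of six-channel IMU recordings and
# annotation tracks in the Consensys-style CSV dialect.

#' Canonical IMU channel names
#'
#' Column names of the six inertial channels in the Consensys CSV export:
#' three axes of linear acceleration followed by three axes of angular
#' velocity.
#'
#' @export
imu_channels <- function() {
  c("Accel_LN_X", "Accel_LN_Y", "Accel_LN_Z", "Gyro_X", "Gyro_Y", "Gyro_Z")
}

accel_channels <- function() imu_channels()[1:3]
gyro_channels <- function() imu_channels()[4:6]

#' Construct an IMU recording
#'
#' A recording is one subject's continuous six-channel inertial stream at a
#' fixed sampling rate. Sample `i` (0-based) is timestamped
#' `t0 + i / sampling_rate`.
#'
#' @param data numeric matrix with one row per sample and the six columns
#'   named as in [imu_channels()]. Extra columns are dropped.
#' @param sampling_rate sampling frequency in Hz.
#' @param subject_id subject identifier.
#' @param t0 timestamp (seconds) of the first sample.
#' @param units list with `accel` and `gyro` unit declarations; units are
#'   carried as metadata and never converted implicitly.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(data, sampling_rate, subject_id = "subject",
                          t0 = 0,
                          units = list(accel = "m/s^2", gyro = "deg/s")) {
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  data <- as.matrix(data)
  missing <- setdiff(imu_channels(), colnames(data))
  if (length(missing) > 0) {
    stop("missing channel column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data <- data[, imu_channels(), drop = FALSE]
  if (nrow(data) < 1L) stop("recording must contain at least one sample", call. = FALSE)
  if (anyNA(data)) stop("recording contains missing values", call. = FALSE)
  storage.mode(data) <- "double"
  structure(
    list(subject_id = as.character(subject_id),
         sampling_rate = sampling_rate,
         t0 = t0,
         data = data,
         units = units),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject '%s': %d samples at %g Hz (%.2f s)\n",
              x$subject_id, nrow(x$data), x$sampling_rate,
              nrow(x$data) / x$sampling_rate))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `imu_recording`.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Duration of a recording in seconds
#' @param rec an `imu_recording`.
#' @export
recording_duration <- function(rec) n_samples(rec) / rec$sampling_rate

#' Sample timestamps of a recording
#' @param rec an `imu_recording`.
#' @return numeric vector of absolute timestamps, seconds.
#' @export
sample_times <- function(rec) {
  rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$sampling_rate
}

#' Construct an annotation track
#'
#' Ground-truth behaviour intervals over one recording, in seconds relative
#' to the recording start. Intervals are half-open `[start, end)`, must be
#' sorted and non-overlapping.
#'
#' @param subject_id subject identifier.
#' @param intervals data.frame with columns `start_s`, `end_s`, `label`
#'   (zero-row frames are allowed).
#' @return an object of class `annotation_track`.
#' @export
annotation_track <- function(subject_id, intervals = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    intervals <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            label = character(0))
  }
  intervals <- as.data.frame(intervals)[, c("start_s", "end_s", "label")]
  intervals$label <- as.character(intervals$label)
  if (any(intervals$start_s >= intervals$end_s)) {
    stop("every interval must satisfy start < end", call. = FALSE)
  }
  o <- order(intervals$start_s)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  if (nrow(intervals) > 1L &&
      any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)])) {
    stop("annotation intervals overlap", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), intervals = intervals),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> subject '%s': %d interval(s), %.2f s total\n",
              x$subject_id, nrow(x$intervals),
              sum(x$intervals$end_s - x$intervals$start_s)))
  invisible(x)
}

#' Write a recording as Consensys-style CSV
#'
#' One row per sample with a leading `Timestamp` column (seconds) followed by
#' the six channel columns.
#'
#' @param rec an `imu_recording`.
#' @param path output file path.
#' @export
write_imu_csv <- function(rec, path) {
  df <- data.frame(Timestamp = sample_times(rec))
  df <- cbind(df, as.data.frame(rec$data))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a Consensys-style CSV sensor export
#'
#' The header must contain the six channel names (see [imu_channels()]);
#' extra columns are ignored. Timestamps must be strictly increasing and
#' uniform within a +/-2% period jitter allowance; the nominal sampling rate
#' is taken from `sampling_rate` or inferred from the median timestamp step.
#'
#' @param path CSV file path.
#' @param sampling_rate nominal rate in Hz, or `NULL` to infer.
#' @param subject_id subject identifier (defaults to the file stem).
#' @param units unit declarations carried as metadata.
#' @param column_map optional named character vector mapping canonical channel
#'   names to the names used in the file, to absorb dialect differences.
#' @return an `imu_recording`.
#' @export
read_imu_csv <- function(path, sampling_rate = NULL, subject_id = NULL,
                         units = list(accel = "m/s^2", gyro = "deg/s"),
                         column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (column_map[[canon]] %in% names(df)) {
        names(df)[names(df) == column_map[[canon]]] <- canon
      }
    }
  }
  missing <- setdiff(imu_channels(), names(df))
  if (length(missing) > 0) {
    stop("missing channel column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"Timestamp" %in% names(df)) stop("missing 'Timestamp' column", call. = FALSE)
  ts <- df$Timestamp
  if (length(ts) > 1L) {
    dt <- diff(ts)
    if (any(dt <= 0)) stop("timestamps are not strictly increasing", call. = FALSE)
    period <- stats::median(dt)
    if (any(abs(dt - period) > 0.02 * period)) {
      stop("timestamps are not uniform within the 2% jitter tolerance",
           call. = FALSE)
    }
    inferred <- 1 / period
  } else {
    inferred <- sampling_rate
  }
  rate <- sampling_rate %||% inferred
  if (is.null(rate)) stop("sampling_rate must be given for single-row files", call. = FALSE)
  imu_recording(as.matrix(df[, imu_channels()]),
                sampling_rate = rate,
                subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                t0 = ts[1],
                units = units)
}

#' Write annotation tracks as CSV
#'
#' Columns: `subject_id, start_s, end_s, label`.
#'
#' @param tracks a single `annotation_track` or a list of them.
#' @param path output file path.
#' @export
write_annotation_csv <- function(tracks, path) {
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    if (nrow(tr$intervals) == 0L) {
      return(data.frame(subject_id = character(0), start_s = numeric(0),
                        end_s = numeric(0), label = character(0)))
    }
    cbind(subject_id = tr$subject_id, tr$intervals)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read annotation tracks from CSV
#'
#' @param path CSV with columns `subject_id, start_s, end_s, label`.
#' @return a named list of `annotation_track`, one per subject present.
#' @export
read_annotation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("subject_id", "start_s", "end_s", "label")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing annotation column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    annotation_track(d$subject_id[1], d[, c("start_s", "end_s", "label")])
  })
  out[unique(df$subject_id)]
}

#' Per-sample ground-truth mask for a recording
#'
#' Sample `i` is positive iff its timestamp (relative to recording start)
#' falls inside some half-open annotated interval `[start, end)`.
#'
#' @param rec an `imu_recording`.
#' @param ann an `annotation_track` for the same subject.
#' @return logical vector of length `n_samples(rec)`.
#' @export
annotations_to_mask <- function(rec, ann) {
  dur <- recording_duration(rec)
  iv <- ann$intervals
  if (nrow(iv) > 0L && (any(iv$start_s < 0) || any(iv$end_s > dur + 1e-9))) {
    stop("annotation interval lies outside the recording span", call. = FALSE)
  }
  t_rel <- (seq_len(n_samples(rec)) - 1) / rec$sampling_rate
  mask <- rep(FALSE, n_samples(rec))
  for (k in seq_len(nrow(iv))) {
    mask <- mask | (t_rel >= iv$start_s[k] & t_rel < iv$end_s[k])
  }
  mask
}
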