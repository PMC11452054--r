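#' Construct an IMU recording
#'
#' One foot's six-axis time series for a single measurement, on a uniform
#' time grid. Accelerations are in g, angular velocities in degrees per
#' second (see the package help page for the axis convention).
#'
#' @param acc numeric matrix, n x 3, accelerometer (ax, ay, az) in g.
#' @param gyr numeric matrix, n x 3, gyroscope (gx, gy, gz) in degrees/s.
#' @param fs sampling frequency in Hz.
#' @param foot `"left"` or `"right"`.
#' @param subject_id,group,session,measurement_id metadata strings;
#'   `group` is `"stroke"` or `"healthy"`.
#' @param uses_aid logical, walking-aid flag (metadata only).
#' @param time optional explicit time vector in seconds; defaults to a
#'   uniform grid starting at 0.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(acc, gyr, fs, foot = "right",
                          subject_id = NA_character_, group = NA_character_,
                          session = NA_character_, measurement_id = NA_character_,
                          uses_aid = FALSE, time = NULL) {
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  stopifnot(ncol(acc) == 3, ncol(gyr) == 3, nrow(acc) == nrow(gyr), fs > 0)
  if (!all(is.finite(acc)) || !all(is.finite(gyr))) {
    stop("imu_recording: non-finite samples")
  }
  n <- nrow(acc)
  if (is.null(time)) {
    time <- (seq_len(n) - 1) / fs
  } else {
    stopifnot(length(time) == n)
    if (n > 1 && max(abs(diff(time) - 1 / fs)) > 1e-6) {
      stop("imu_recording: time grid not uniform at fs")
    }
  }
  foot <- match.arg(foot, c("left", "right"))
  colnames(acc) <- IMU_CHANNELS[1:3]
  colnames(gyr) <- IMU_CHANNELS[4:6]
  structure(
    list(time = time, acc = acc, gyr = gyr, fs = fs, foot = foot,
         subject_id = subject_id, group = group, session = session,
         measurement_id = measurement_id, uses_aid = uses_aid),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s foot, %d samples @ %g Hz (%.1f s)\n",
              x$foot, nrow(x$acc), x$fs, nrow(x$acc) / x$fs))
  cat(sprintf("  subject=%s group=%s session=%s aid=%s\n",
              x$subject_id, x$group, x$session, x$uses_aid))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an [imu_recording()].
#' @export
n_samples <- function(rec) nrow(rec$acc)

#' Six-channel signal matrix of a recording
#'
#' @param rec an [imu_recording()].
#' @return n x 6 matrix with columns `ax_g ... gz_dps`.
#' @export
signal_matrix <- function(rec) {
  m <- cbind(rec$acc, rec$gyr)
  colnames(m) <- IMU_CHANNELS
  m
}

#' Write / read one recording as CSV with a JSON sidecar
#'
#' The CSV holds `time_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps`; the
#' sidecar (`<path>.json`) holds the metadata, the sampling frequency and
#' the gyroscope offset from the sensor's static calibration when one is
#' attached to the recording.
#'
#' @param rec an [imu_recording()].
#' @param path CSV file path.
#' @param gyro_offset_dps optional length-3 static-calibration offset to
#'   store in the sidecar.
#' @export
write_imu_csv <- function(rec, path, gyro_offset_dps = NULL) {
  df <- data.frame(time_s = rec$time, rec$acc, rec$gyr, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               session = rec$session, measurement_id = rec$measurement_id,
               foot = rec$foot, fs = rec$fs, uses_aid = rec$uses_aid)
  if (!is.null(gyro_offset_dps)) meta$gyro_offset_dps <- gyro_offset_dps
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_imu_csv
#' @return `read_imu_csv()` returns the reconstructed [imu_recording()];
#'   a stored gyroscope offset is attached as attribute
#'   `"gyro_offset_dps"`.
#' @export
read_imu_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("time_s", IMU_CHANNELS) %in% names(df)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rec <- imu_recording(
    acc = as.matrix(df[, IMU_CHANNELS[1:3]]),
    gyr = as.matrix(df[, IMU_CHANNELS[4:6]]),
    fs = meta$fs, foot = meta$foot,
    subject_id = meta$subject_id, group = meta$group,
    session = meta$session, measurement_id = meta$measurement_id,
    uses_aid = isTRUE(meta$uses_aid), time = df$time_s)
  if (!is.null(meta$gyro_offset_dps)) {
    attr(rec, "gyro_offset_dps") <- as.numeric(meta$gyro_offset_dps)
  }
  rec
}
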