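# Quaternion helpers (scalar-first convention, q = (w, x, y, z); R(q)
# rotates sensor-frame vectors into the global frame).

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_rotvec <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-12) return(c(1, v / 2))
  axis <- v / angle
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# Rotation matrix of q (sensor -> global).
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Quaternion rotating unit vector a onto unit vector b.
quat_between <- function(a, b) {
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    axis <- axis / sqrt(sum(axis^2))
    return(c(0, axis))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  q <- c(1 + d, axis)
  quat_normalize(q)
}

#' Estimate sensor orientation with a complementary filter
#'
#' Propagates the orientation quaternion by gyroscope integration and
#' corrects the tilt toward the accelerometer's gravity direction during
#' stance phases (gain per sample; no correction during swing, when the
#' accelerometer does not measure gravity alone). The gyroscope offset
#' must already be corrected.
#'
#' @param rec an [imu_recording()].
#' @param events a [gait_events()] for the recording; stance intervals
#'   gate the accelerometer correction. An events object without stance
#'   intervals disables the correction.
#' @param gain tilt-correction gain per sample during stance.
#' @return An `orientation_series`: list with `quat` (n x 4 matrix of
#'   unit quaternions, sensor-to-global, scalar first) and `fs`.
#' @export
estimate_orientation <- function(rec, events, gain = 0.02) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- n_samples(rec)
  dt <- 1 / rec$fs
  gyr_rad <- rec$gyr * pi / 180
  in_stance <- rep(FALSE, n)
  if (inherits(events, "gait_events") && nrow(events$stance_intervals)) {
    for (i in seq_len(nrow(events$stance_intervals))) {
      in_stance[events$stance_intervals[i, 1]:
                  (events$stance_intervals[i, 2] - 1L)] <- TRUE
    }
  }
  # initialize from the first accelerometer samples (gravity direction)
  a0 <- colMeans(rec$acc[seq_len(min(20, n)), , drop = FALSE])
  a0 <- a0 / sqrt(sum(a0^2))
  # want R(q)^T e_z = a0  <=>  R(q) a0 = e_z
  q <- quat_between(a0, c(0, 0, 1))
  quat <- matrix(0, n, 4)
  quat[1, ] <- q
  for (k in 2:n) {
    q <- quat_mult(q, quat_from_rotvec(gyr_rad[k - 1, ] * dt))
    if (in_stance[k]) {
      a <- rec$acc[k, ]
      an <- sqrt(sum(a^2))
      if (an > 0.5 && an < 1.5) {
        a <- a / an
        R <- quat_to_matrix(q)
        g_pred <- R[3, ]            # R^T e_z: gravity direction in sensor frame
        axis <- c(a[2] * g_pred[3] - a[3] * g_pred[2],
                  a[3] * g_pred[1] - a[1] * g_pred[3],
                  a[1] * g_pred[2] - a[2] * g_pred[1])
        q <- quat_mult(q, quat_from_rotvec(gain * axis))
      }
    }
    q <- quat_normalize(q)
    quat[k, ] <- q
  }
  structure(list(quat = quat, fs = rec$fs), class = "orientation_series")
}

#' Global-frame linear acceleration
#'
#' Rotates the accelerometer signal into the global frame, removes
#' gravity (1 g on the vertical axis) and converts to m/s^2 with
#' g = 9.81.
#'
#' @param rec an [imu_recording()].
#' @param orient an `orientation_series` from [estimate_orientation()].
#' @return n x 3 matrix (two horizontal components, then vertical), in
#'   m/s^2.
#' @export
global_linear_acceleration <- function(rec, orient) {
  stopifnot(inherits(rec, "imu_recording"),
            inherits(orient, "orientation_series"))
  # v' = v + 2 q_v x (q_v x v + w v), vectorized over samples
  a <- rec$acc
  qw <- orient$quat[, 1]
  qv <- orient$quat[, 2:4, drop = FALSE]
  cross_rows <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  t2 <- 2 * cross_rows(qv, a)
  out <- (a + qw * t2 + cross_rows(qv, t2)) * GRAVITY_MPS2
  out[, 3] <- out[, 3] - GRAVITY_MPS2
  colnames(out) <- c("h1", "h2", "vertical")
  out
}

# Central 40% window of a stance interval (the mid-stance samples used
# as zero-velocity anchors).
zupt_windows <- function(stance_intervals, frac = 0.4) {
  if (!nrow(stance_intervals)) return(matrix(integer(0), 0, 2))
  len <- stance_intervals[, 2] - stance_intervals[, 1]
  lo <- stance_intervals[, 1] + floor(len * (0.5 - frac / 2))
  hi <- stance_intervals[, 1] + ceiling(len * (0.5 + frac / 2))
  w <- cbind(pmax(lo, stance_intervals[, 1]),
             pmin(pmax(hi, lo + 1L), stance_intervals[, 2]))
  w[w[, 2] > w[, 1], , drop = FALSE]
}

cumtrapz_mat <- function(m, fs) {
  apply(m, 2, function(col) c(0, cumsum((col[-1] + col[-length(col)]) / 2)) / fs)
}

#' Integrate acceleration to velocity and distance with zero-velocity
#' updates
#'
#' Cumulative trapezoidal integration of the horizontal acceleration to
#' velocity; within the mid-stance window (central 40%) of every stance
#' interval the velocity is reset to zero, and the accumulated drift is
#' removed by linear de-trending across each inter-anchor span. Position
#' is the integral of the corrected velocity; the walked distance is the
#' sum of the magnitudes of the per-span displacements, so heading
#' reversals at turns do not cancel. Gait speed is distance divided by
#' the covered duration (first to last zero-velocity anchor).
#'
#' @param acc n x d matrix (d = 1 or 2) of horizontal global-frame
#'   acceleration in m/s^2, or a numeric vector.
#' @param events a [gait_events()] with at least 2 stance intervals.
#' @param fs sampling rate in Hz.
#' @return A `speed_result`: list with `velocity` (n x d, m/s),
#'   `position` (n x d, m), `total_distance` (m), `gait_speed` (m/s),
#'   `duration_s` (covered duration) and `zupt_intervals`.
#' @export
integrate_with_zupt <- function(acc, events, fs) {
  if (is.null(dim(acc))) acc <- matrix(acc, ncol = 1)
  stopifnot(inherits(events, "gait_events"))
  if (nrow(events$stance_intervals) < 2) stop("ZUPT impossible")
  n <- nrow(acc)
  w <- zupt_windows(events$stance_intervals)
  w <- w[w[, 2] <= n + 1L & w[, 1] >= 1L, , drop = FALSE]
  if (nrow(w) < 2) stop("ZUPT impossible")
  v_raw <- cumtrapz_mat(acc, fs)
  v <- v_raw
  # zero inside anchors, de-trend linearly across each inter-anchor span
  for (i in seq_len(nrow(w))) v[w[i, 1]:(w[i, 2] - 1L), ] <- 0
  spans <- cbind(w[-nrow(w), 2] - 1L, w[-1, 1])   # [t0, t1]: anchor to anchor
  for (i in seq_len(nrow(spans))) {
    t0 <- spans[i, 1]; t1 <- spans[i, 2]
    if (t1 <= t0 + 1L) next
    idx <- (t0 + 1L):(t1 - 1L)
    for (j in seq_len(ncol(v))) {
      drift0 <- v_raw[t0, j]
      drift1 <- v_raw[t1, j]
      v[idx, j] <- v_raw[idx, j] - drift0 -
        (idx - t0) / (t1 - t0) * (drift1 - drift0)
    }
  }
  # before the first / after the last anchor the velocity is unknown
  if (w[1, 1] > 1) v[seq_len(w[1, 1] - 1L), ] <- 0
  if (w[nrow(w), 2] <= n) v[w[nrow(w), 2]:n, ] <- 0
  pos <- cumtrapz_mat(v, fs)
  disp <- matrix(0, nrow(spans), ncol(v))
  for (i in seq_len(nrow(spans))) {
    disp[i, ] <- pos[spans[i, 2], ] - pos[spans[i, 1], ]
  }
  total <- sum(sqrt(rowSums(disp^2)))
  covered <- (w[nrow(w), 1] - w[1, 2] + 1L) / fs
  covered <- max(covered, 1 / fs)
  structure(list(velocity = v, position = pos, total_distance = total,
                 gait_speed = total / covered, duration_s = covered,
                 zupt_intervals = w),
            class = "speed_result")
}

#' Estimate gait speed from one foot-worn recording
#'
#' Full speed chain: resample to 100 Hz, correct the gyroscope offset,
#' detect gait events, estimate orientation, rotate to the global frame
#' and remove gravity, then integrate the horizontal acceleration with
#' zero-velocity updates. Works on either foot; by convention
#' measurement-level speed is reported from the right foot.
#'
#' @param rec an [imu_recording()].
#' @param gyro_offset length-3 static-calibration offset (defaults to
#'   the offset stored on the recording, else zero).
#' @param events optional precomputed [gait_events()] (on the 100 Hz
#'   grid); detected when `NULL`.
#' @param event_cfg an [event_config()].
#' @param gain complementary-filter gain.
#' @return A `speed_result` (see [integrate_with_zupt()]) with the
#'   detected `events` attached as an attribute.
#' @export
estimate_gait_speed <- function(rec, gyro_offset = NULL, events = NULL,
                                event_cfg = event_config(), gain = 0.02) {
  if (is.null(gyro_offset)) {
    gyro_offset <- attr(rec, "gyro_offset_dps") %||% c(0, 0, 0)
  }
  rec <- resample_to_100hz(rec)
  rec <- correct_gyro_offset(rec, gyro_offset)
  if (is.null(events)) events <- detect_gait_events(rec, event_cfg)
  orient <- estimate_orientation(rec, events, gain = gain)
  acc_g <- global_linear_acceleration(rec, orient)
  res <- integrate_with_zupt(acc_g[, 1:2], events, rec$fs)
  attr(res, "events") <- events
  res
}

#' Per-measurement gait speeds of a cohort
#'
#' Runs [estimate_gait_speed()] on one foot of every measurement.
#'
#' @param cohort a `gait_cohort`.
#' @param foot which foot's sensor to use (right by convention).
#' @return Data frame: measurement_id, foot, gait_speed_mps,
#'   total_distance_m.
#' @export
compute_speeds <- function(cohort, foot = c("right", "left")) {
  foot <- match.arg(foot)
  rows <- lapply(cohort$measurements, function(m) {
    res <- estimate_gait_speed(m[[foot]],
                               gyro_offset = m$meta$gyro_offset_dps)
    data.frame(measurement_id = m$meta$measurement_id, foot = foot,
               gait_speed_mps = res$gait_speed,
               total_distance_m = res$total_distance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
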