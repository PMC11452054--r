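#' Gait events container
#'
#' Foot contacts and stance/swing phases of one recording. Stance
#' intervals are half-open `[start, end)` sample ranges; every contact is
#' the start of a stance interval; swing intervals are the complementary
#' ranges between a stance end and the next contact.
#'
#' @param foot_contacts strictly increasing sample indices.
#' @param stance_intervals m x 2 matrix of half-open index ranges.
#' @param n_samples length of the source recording.
#' @param fs sampling frequency of the source recording.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(foot_contacts, stance_intervals, n_samples, fs) {
  foot_contacts <- as.integer(foot_contacts)
  if (is.null(stance_intervals) || length(stance_intervals) == 0) {
    stance_intervals <- matrix(integer(0), 0, 2)
  }
  stance_intervals <- matrix(as.integer(stance_intervals),
                             ncol = 2,
                             nrow = nrow(as.matrix(stance_intervals)))
  if (length(foot_contacts)) {
    stopifnot(all(diff(foot_contacts) > 0),
              all(foot_contacts >= 1), all(foot_contacts <= n_samples))
  }
  if (nrow(stance_intervals)) {
    stopifnot(all(stance_intervals[, 2] > stance_intervals[, 1]),
              all(stance_intervals[, 1] >= 1),
              all(stance_intervals[, 2] <= n_samples + 1L))
    o <- order(stance_intervals[, 1])
    stance_intervals <- stance_intervals[o, , drop = FALSE]
    if (nrow(stance_intervals) > 1) {
      stopifnot(all(stance_intervals[-1, 1] >=
                      stance_intervals[-nrow(stance_intervals), 2]))
    }
  }
  swing <- NULL
  if (nrow(stance_intervals) > 1) {
    swing <- cbind(stance_intervals[-nrow(stance_intervals), 2],
                   stance_intervals[-1, 1])
    swing <- swing[swing[, 2] > swing[, 1], , drop = FALSE]
  }
  if (is.null(swing)) swing <- matrix(integer(0), 0, 2)
  structure(list(foot_contacts = foot_contacts,
                 stance_intervals = stance_intervals,
                 swing_intervals = swing,
                 n_samples = as.integer(n_samples), fs = fs),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d contacts, %d stance intervals over %d samples\n",
              length(x$foot_contacts), nrow(x$stance_intervals), x$n_samples))
  invisible(x)
}

#' Detector configuration
#'
#' All thresholds of [detect_gait_events()]. The swing-peak threshold
#' and, by default, the contact/swing-onset thresholds are expressed as
#' fractions of the 95th percentile of the sagittal angular velocity, so
#' the detector is invariant to a common rescaling of the gyroscope
#' signal. At a typical stroke mid-swing peak (about 250 deg/s, 95th
#' percentile about 200 deg/s) the default fractions correspond to the
#' absolute values 20 deg/s (contact) and 40 deg/s (swing onset); set
#' `contact_thresh_dps` / `swing_onset_dps` to use absolute thresholds
#' instead.
#'
#' @param peak_frac mid-swing peaks must exceed `peak_frac` times the
#'   95th percentile of the sagittal angular velocity.
#' @param refractory_s minimum separation between mid-swing peaks (s).
#' @param contact_frac contact threshold as a fraction of the 95th
#'   percentile of gyroscope magnitude.
#' @param swing_onset_frac swing-onset threshold, same scale.
#' @param contact_hold_s minimum time below the contact threshold (s).
#' @param contact_thresh_dps,swing_onset_dps optional absolute
#'   thresholds in deg/s; when set they override the fractional ones.
#' @param min_activity_dps recordings whose sagittal 95th percentile is
#'   below this are treated as containing no gait (static guard).
#' @export
event_config <- function(peak_frac = 0.5, refractory_s = 0.5,
                         contact_frac = 0.10, swing_onset_frac = 0.20,
                         contact_hold_s = 0.05,
                         contact_thresh_dps = NULL, swing_onset_dps = NULL,
                         min_activity_dps = 30) {
  list(peak_frac = peak_frac, refractory_s = refractory_s,
       contact_frac = contact_frac, swing_onset_frac = swing_onset_frac,
       contact_hold_s = contact_hold_s,
       contact_thresh_dps = contact_thresh_dps,
       swing_onset_dps = swing_onset_dps,
       min_activity_dps = min_activity_dps)
}

#' Detect foot contacts and stance/swing phases
#'
#' Single-IMU gait-event detection from the sagittal angular velocity
#' (y gyroscope channel under the package axis convention): mid-swing =
#' peaks above an adaptive threshold (a fraction of the 95th percentile)
#' with a refractory period; foot contact = first sample after each
#' mid-swing where the gyroscope magnitude stays below the contact
#' threshold for at least `contact_hold_s`; stance runs from the contact
#' to the next swing onset (magnitude rising above the swing-onset
#' threshold).
#'
#' @param rec an [imu_recording()] (gyroscope offset already corrected).
#' @param config an [event_config()].
#' @return A [gait_events()] object; empty (with a warning) when no
#'   swing peaks are found.
#' @export
detect_gait_events <- function(rec, config = event_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- n_samples(rec)
  fs <- rec$fs
  if (n / fs < 4) stop("recording too short for gait-event detection (< 4 s)")
  gy <- rec$gyr[, 2]
  p95 <- quantile(abs(gy), 0.95, names = FALSE)
  if (p95 < config$min_activity_dps) {
    warning("no swing peaks found; returning empty events")
    return(gait_events(integer(0), NULL, n, fs))
  }
  peak_thresh <- config$peak_frac * quantile(gy, 0.95, names = FALSE)
  pk <- pracma::findpeaks(gy, minpeakheight = peak_thresh,
                          minpeakdistance = max(1L, round(config$refractory_s * fs)))
  if (is.null(pk)) {
    warning("no swing peaks found; returning empty events")
    return(gait_events(integer(0), NULL, n, fs))
  }
  peaks <- sort(pk[, 2])

  gmag <- sqrt(rowSums(rec$gyr^2))
  gmag_p95 <- quantile(gmag, 0.95, names = FALSE)
  contact_thr <- config$contact_thresh_dps %||% (config$contact_frac * gmag_p95)
  onset_thr <- config$swing_onset_dps %||% (config$swing_onset_frac * gmag_p95)
  hold <- max(1L, round(config$contact_hold_s * fs))
  below <- gmag < contact_thr
  runlen <- stats::filter(as.numeric(below), rep(1, hold), sides = 1)
  quiet_starts <- which(!is.na(runlen) & runlen == hold) - hold + 1L

  contacts <- integer(0)
  for (p in peaks) {
    j <- quiet_starts[quiet_starts > p]
    if (length(j)) contacts <- c(contacts, j[1])
  }
  contacts <- sort(unique(contacts))
  if (!length(contacts)) {
    warning("no foot contacts found; returning empty events")
    return(gait_events(integer(0), NULL, n, fs))
  }

  above <- gmag > onset_thr
  stance <- matrix(integer(0), 0, 2)
  for (i in seq_along(contacts)) {
    cstart <- contacts[i]
    lim <- if (i < length(contacts)) contacts[i + 1] - 1L else n
    rise <- which(above[cstart:lim])
    cend <- if (length(rise)) cstart + rise[1] - 1L else lim + 1L
    if (cend > cstart) stance <- rbind(stance, c(cstart, cend))
  }
  keep <- stance[, 2] > stance[, 1]
  gait_events(contacts, stance[keep, , drop = FALSE], n, fs)
}

#' Number of contact-to-contact gait cycles
#'
#' @param events a [gait_events()].
#' @return `max(length(foot_contacts) - 1, 0)`.
#' @export
stride_count <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  max(length(events$foot_contacts) - 1L, 0L)
}

#' Write detected events as CSV
#'
#' Columns: measurement id, contact index, stance start, stance end.
#'
#' @param events a [gait_events()].
#' @param measurement_id id string for the output rows.
#' @param path CSV path.
#' @export
write_events_csv <- function(events, measurement_id, path) {
  m <- nrow(events$stance_intervals)
  df <- data.frame(
    measurement_id = rep(measurement_id, m),
    contact_index = events$stance_intervals[, 1],
    stance_start = events$stance_intervals[, 1],
    stance_end = events$stance_intervals[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
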