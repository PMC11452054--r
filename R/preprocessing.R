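#' Construct an epoch
#'
#' A fixed-length (512 x 6) segment of a recording, the unit of input to
#' the variational autoencoder. Columns are `ax_g, ay_g, az_g, gx_dps,
#' gy_dps, gz_dps`.
#'
#' @param data 512 x 6 numeric matrix.
#' @param start_index sample index of the first row in the source
#'   recording.
#' @param foot,measurement_id,subject_id,group,session,uses_aid
#'   provenance metadata.
#' @param normalized logical; when `TRUE` all values must lie in
#'   \[-1, 1\].
#' @export
gait_epoch <- function(data, start_index, foot = NA_character_,
                       measurement_id = NA_character_,
                       subject_id = NA_character_, group = NA_character_,
                       session = NA_character_, uses_aid = NA,
                       normalized = FALSE) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == EPOCH_LEN, ncol(data) == 6, all(is.finite(data)))
  if (normalized && (max(data) > 1 + 1e-9 || min(data) < -1 - 1e-9)) {
    stop("normalized epoch values outside [-1, 1]")
  }
  colnames(data) <- IMU_CHANNELS
  structure(list(data = data, start_index = as.integer(start_index),
                 foot = foot, measurement_id = measurement_id,
                 subject_id = subject_id, group = group, session = session,
                 uses_aid = uses_aid, normalized = normalized),
            class = "gait_epoch")
}

#' Resample a recording to 100 Hz
#'
#' Linear interpolation of all six channels onto a uniform 100 Hz grid,
#' preserving the recorded duration to within one sample.
#'
#' @param rec an [imu_recording()] with `fs >= 100`.
#' @param target_fs target rate (default 100 Hz).
#' @return The resampled [imu_recording()].
#' @export
resample_to_100hz <- function(rec, target_fs = TARGET_FS) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$fs < target_fs) stop("resample_to_100hz: recording fs below target")
  if (rec$fs == target_fs) return(rec)
  n <- n_samples(rec)
  t_old <- rec$time
  n_new <- floor((t_old[n] - t_old[1]) * target_fs) + 1
  t_new <- t_old[1] + (seq_len(n_new) - 1) / target_fs
  interp <- function(col) approx(t_old, col, xout = t_new)$y
  out <- imu_recording(
    acc = apply(rec$acc, 2, interp), gyr = apply(rec$gyr, 2, interp),
    fs = target_fs, foot = rec$foot, subject_id = rec$subject_id,
    group = rec$group, session = rec$session,
    measurement_id = rec$measurement_id, uses_aid = rec$uses_aid,
    time = t_new)
  attr(out, "gyro_offset_dps") <- attr(rec, "gyro_offset_dps")
  out
}

#' Estimate the gyroscope offset from a static recording
#'
#' Mean of each gyroscope axis over a static segment of at least 5 s.
#'
#' @param rec an [imu_recording()] of a sensor at rest.
#' @return Length-3 offset in deg/s.
#' @export
estimate_gyro_offset <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (n_samples(rec) / rec$fs < 5) {
    stop("estimate_gyro_offset: static segment shorter than 5 s")
  }
  colMeans(rec$gyr)
}

#' Correct the gyroscope offset
#'
#' Subtracts a constant per-axis offset (from the sensor's static
#' calibration) from the gyroscope channels.
#'
#' @param rec an [imu_recording()].
#' @param offset length-3 finite numeric, deg/s.
#' @return The corrected [imu_recording()].
#' @export
correct_gyro_offset <- function(rec, offset) {
  stopifnot(inherits(rec, "imu_recording"),
            length(offset) == 3, all(is.finite(offset)))
  out <- rec
  out$gyr <- sweep(rec$gyr, 2, as.numeric(offset))
  colnames(out$gyr) <- IMU_CHANNELS[4:6]
  out
}

# First-order Butterworth band-pass (0.01-10 Hz), applied per column.
# Forward-only (causal) by default; `zero_phase = TRUE` switches to
# forward-backward filtering.
bandpass_matrix <- function(m, fs, low = 0.01, high = 10, order = 1,
                            zero_phase = FALSE) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  apply(m, 2, function(col) {
    if (zero_phase) signal::filtfilt(bf, col)
    else as.numeric(signal::filter(bf, col))
  })
}

#' Band-pass filter a recording or epoch
#'
#' First-order Butterworth band-pass with edges 0.01 and 10 Hz applied
#' to each of the six channels. Forward-only (causal) by default, as on
#' a wearable processing chain; set `zero_phase = TRUE` for
#' forward-backward filtering.
#'
#' @param x an [imu_recording()] at 100 Hz, or a [gait_epoch()].
#' @param low,high band edges in Hz.
#' @param zero_phase logical.
#' @param fs sampling rate; taken from the object when available.
#' @return Object of the same class, filtered.
#' @export
bandpass <- function(x, low = 0.01, high = 10, zero_phase = FALSE,
                     fs = TARGET_FS) {
  if (inherits(x, "imu_recording")) {
    m <- bandpass_matrix(signal_matrix(x), x$fs, low, high,
                         zero_phase = zero_phase)
    out <- x
    out$acc <- m[, 1:3]; out$gyr <- m[, 4:6]
    colnames(out$acc) <- IMU_CHANNELS[1:3]
    colnames(out$gyr) <- IMU_CHANNELS[4:6]
    return(out)
  }
  if (inherits(x, "gait_epoch")) {
    out <- x
    out$data <- bandpass_matrix(x$data, fs, low, high, zero_phase = zero_phase)
    colnames(out$data) <- IMU_CHANNELS
    return(out)
  }
  stop("bandpass: unsupported input")
}

# Nominal epoch starts under the 50%-overlap rule, before any
# stride-bound trimming: 0-based starts 0, step, 2*step, ...
nominal_epoch_starts <- function(n, width = EPOCH_LEN, step = EPOCH_STEP) {
  if (n < width) return(integer(0))
  seq(1L, n - width + 1L, by = step)
}

#' Segment a recording into 512-sample epochs
#'
#' Epochs span from the second to the second-to-last stride, start
#' inside a stance phase, and overlap by approximately 50%: candidate
#' starts advance by a nominal 256 samples and snap to the nearest
#' eligible stance. With the default `snap = "contact"`, starts snap to
#' the nearest stance-interval start (the foot contact), phase-locking
#' every epoch to the gait cycle; `snap = "stance"` snaps to the
#' nearest sample anywhere inside a stance interval, which leaves the
#' within-stance phase of each epoch arbitrary.
#'
#' @param rec an [imu_recording()] (typically at 100 Hz).
#' @param events a [gait_events()] for the same recording.
#' @param width,step epoch length and nominal advance, in samples.
#' @param snap `"contact"` (default) or `"stance"`.
#' @return A list of [gait_epoch()]s; empty (with a warning) when fewer
#'   than four strides are available.
#' @export
segment_epochs <- function(rec, events, width = EPOCH_LEN, step = EPOCH_STEP,
                           snap = c("contact", "stance")) {
  snap <- match.arg(snap)
  stopifnot(inherits(rec, "imu_recording"), inherits(events, "gait_events"))
  n <- n_samples(rec)
  if (stride_count(events) < 4) {
    warning("fewer than 4 strides; no epochs segmented")
    return(list())
  }
  contacts <- events$foot_contacts
  m <- length(contacts)
  st <- events$stance_intervals
  # stance intervals belonging to strides 2 .. m-1
  eligible <- st[st[, 1] >= contacts[2] & st[, 1] <= contacts[m - 1], ,
                 drop = FALSE]
  if (!nrow(eligible)) {
    warning("no eligible stance intervals; no epochs segmented")
    return(list())
  }
  stance_samples <- if (snap == "contact") {
    sort(unique(eligible[, 1]))
  } else {
    sort(unique(unlist(
      lapply(seq_len(nrow(eligible)),
             function(i) seq.int(eligible[i, 1], eligible[i, 2] - 1L)))))
  }
  # epochs may not extend past the end of the second-to-last stride
  limit <- min(n, contacts[m] - 1L)
  stance_samples <- stance_samples[stance_samples + width - 1L <= limit]
  if (!length(stance_samples)) {
    warning("recording too short for one epoch; no epochs segmented")
    return(list())
  }
  sig <- signal_matrix(rec)
  starts <- integer(0)
  s <- stance_samples[1]
  repeat {
    starts <- c(starts, s)
    nominal <- s + step
    # advance at least half a step so snapping never stalls or
    # produces near-duplicate epochs around stance gaps
    cand <- stance_samples[stance_samples >= s + step %/% 2]
    if (!length(cand)) break
    s2 <- cand[which.min(abs(cand - nominal))]
    if (s2 + width - 1L > n) break
    s <- s2
  }
  lapply(starts, function(s0) {
    gait_epoch(sig[s0:(s0 + width - 1L), , drop = FALSE], start_index = s0,
               foot = rec$foot, measurement_id = rec$measurement_id,
               subject_id = rec$subject_id, group = rec$group,
               session = rec$session, uses_aid = rec$uses_aid)
  })
}

#' Zero the start of an epoch
#'
#' Subtracts the first value of each of the six channels, so the first
#' row becomes all zeros. Idempotent.
#'
#' @param epoch a [gait_epoch()].
#' @export
zero_start <- function(epoch) {
  stopifnot(inherits(epoch, "gait_epoch"))
  out <- epoch
  out$data <- sweep(epoch$data, 2, epoch$data[1, ])
  colnames(out$data) <- IMU_CHANNELS
  out
}

#' Flag and remove outlier epochs
#'
#' For every epoch, the per-channel mean and standard deviation are
#' z-scored against the distribution of those statistics over the whole
#' epoch set; an epoch is removed when any |z| exceeds `z_thresh`
#' (two-sided). A statistic with zero spread across the set contributes
#' z = 0, so identical epochs are never removed.
#'
#' @param epochs list of [gait_epoch()]s (at least 2).
#' @param z_thresh removal threshold on |z| (default 5).
#' @return A list with `kept`, `removed` (lists of epochs) and `stats`
#'   (data frame of per-epoch means, SDs, max |z| and the outlier flag).
#' @export
flag_outliers <- function(epochs, z_thresh = 5) {
  stopifnot(length(epochs) >= 2)
  means <- t(vapply(epochs, function(e) colMeans(e$data), numeric(6)))
  sds <- t(vapply(epochs, function(e) apply(e$data, 2, sd), numeric(6)))
  zscore <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    z <- sweep(sweep(m, 2, mu), 2, ifelse(s > 0, s, Inf), "/")
    z
  }
  z_all <- cbind(zscore(means), zscore(sds))
  max_abs_z <- apply(abs(z_all), 1, max)
  outlier <- max_abs_z > z_thresh
  stats <- data.frame(
    epoch = seq_along(epochs),
    measurement_id = vapply(epochs, `[[`, character(1), "measurement_id"),
    max_abs_z = max_abs_z, outlier = outlier)
  list(kept = epochs[!outlier], removed = epochs[outlier], stats = stats)
}

#' Normalize / denormalize an epoch to the sensor ranges
#'
#' Symmetric min-max normalization per channel type: accelerometer
#' channels are divided by 8 (the +/-8 g range), gyroscope channels by
#' 500 (+/-500 deg/s), mapping the measurable range onto \[-1, 1\].
#' Values are clamped to \[-1, 1\] (filtering can produce negligible
#' overshoot past the hardware range).
#'
#' @param epoch a [gait_epoch()].
#' @export
normalize_epoch <- function(epoch) {
  stopifnot(inherits(epoch, "gait_epoch"), !isTRUE(epoch$normalized))
  out <- epoch
  d <- epoch$data
  d[, 1:3] <- d[, 1:3] / ACC_RANGE_G
  d[, 4:6] <- d[, 4:6] / GYR_RANGE_DPS
  out$data <- pmin(pmax(d, -1), 1)
  out$normalized <- TRUE
  out
}

#' @rdname normalize_epoch
#' @export
denormalize_epoch <- function(epoch) {
  stopifnot(inherits(epoch, "gait_epoch"), isTRUE(epoch$normalized))
  out <- epoch
  d <- epoch$data
  d[, 1:3] <- d[, 1:3] * ACC_RANGE_G
  d[, 4:6] <- d[, 4:6] * GYR_RANGE_DPS
  out$data <- d
  out$normalized <- FALSE
  out
}

#' Preprocess one recording into zero-started epochs
#'
#' Runs the fixed single-recording part of the preprocessing chain:
#' resample to 100 Hz, correct the gyroscope offset, detect gait events,
#' segment into 512-sample epochs, band-pass filter (per epoch by
#' default; `filter_scope = "recording"` filters the whole recording
#' before segmentation instead) and zero the epoch starts. Outlier
#' removal and range normalization are epoch-set-level operations, see
#' [prepare_epoch_set()].
#'
#' @param rec an [imu_recording()].
#' @param gyro_offset length-3 static-calibration offset in deg/s
#'   (defaults to the offset stored on the recording, else zero).
#' @param zero_phase passed to [bandpass()].
#' @param filter_scope `"epoch"` (default) or `"recording"`.
#' @param event_cfg an [event_config()].
#' @return List of unnormalized [gait_epoch()]s with attributes
#'   `"events"` (the detected [gait_events()]) and `"stages"` (the stage
#'   order executed).
#' @export
preprocess_measurement <- function(rec, gyro_offset = NULL,
                                   zero_phase = FALSE,
                                   filter_scope = c("epoch", "recording"),
                                   event_cfg = event_config()) {
  filter_scope <- match.arg(filter_scope)
  if (is.null(gyro_offset)) {
    gyro_offset <- attr(rec, "gyro_offset_dps") %||% c(0, 0, 0)
  }
  stages <- character(0)
  rec <- resample_to_100hz(rec);            stages <- c(stages, "resample")
  rec <- correct_gyro_offset(rec, gyro_offset); stages <- c(stages, "offset")
  events <- detect_gait_events(rec, event_cfg); stages <- c(stages, "events")
  if (filter_scope == "recording") {
    rec <- bandpass(rec, zero_phase = zero_phase)
    stages <- c(stages, "filter")
  }
  epochs <- segment_epochs(rec, events);    stages <- c(stages, "segment")
  if (filter_scope == "epoch") {
    epochs <- lapply(epochs, bandpass, zero_phase = zero_phase, fs = rec$fs)
    stages <- c(stages, "filter")
  }
  epochs <- lapply(epochs, zero_start);     stages <- c(stages, "zero")
  attr(epochs, "events") <- events
  attr(epochs, "stages") <- stages
  epochs
}

#' Outlier-screen and normalize an epoch set
#'
#' Dataset-level tail of the preprocessing chain: z-score based outlier
#' removal across the full epoch set, then range normalization of the
#' kept epochs.
#'
#' @param epochs list of unnormalized [gait_epoch()]s from
#'   [preprocess_measurement()] (all measurements pooled).
#' @param z_thresh outlier threshold, see [flag_outliers()].
#' @return List with `epochs` (kept, normalized), `removed`, `stats`,
#'   and `manifest` (one row per kept epoch).
#' @export
prepare_epoch_set <- function(epochs, z_thresh = 5) {
  fl <- flag_outliers(epochs, z_thresh = z_thresh)
  kept <- lapply(fl$kept, normalize_epoch)
  manifest <- data.frame(
    epoch_id = seq_along(kept),
    measurement_id = vapply(kept, `[[`, character(1), "measurement_id"),
    subject_id = vapply(kept, `[[`, character(1), "subject_id"),
    group = vapply(kept, `[[`, character(1), "group"),
    session = vapply(kept, `[[`, character(1), "session"),
    foot = vapply(kept, `[[`, character(1), "foot"),
    uses_aid = vapply(kept, function(e) isTRUE(e$uses_aid), logical(1)),
    start_index = vapply(kept, `[[`, integer(1), "start_index"),
    stringsAsFactors = FALSE)
  list(epochs = kept, removed = fl$removed, stats = fl$stats,
       manifest = manifest)
}

#' Epoch bookkeeping summary
#'
#' Derived accounting quantities of an epoch-screening run: the average
#' number of segmented epochs per measurement and the percentage of kept
#' epochs contributed by each group.
#'
#' @param n_epochs_total epochs segmented before outlier removal.
#' @param n_measurements number of measurements.
#' @param n_kept_total epochs kept after outlier removal.
#' @param n_kept_by_group named vector of kept-epoch counts per group.
#' @return List with `epochs_per_measurement`, `pct_removed` and
#'   `pct_by_group` (percentages of the kept total).
#' @export
epoch_bookkeeping <- function(n_epochs_total, n_measurements,
                              n_kept_total, n_kept_by_group) {
  stopifnot(n_measurements > 0, n_kept_total <= n_epochs_total)
  list(epochs_per_measurement = n_epochs_total / n_measurements,
       pct_removed = 100 * (n_epochs_total - n_kept_total) / n_epochs_total,
       pct_by_group = 100 * n_kept_by_group / n_kept_total)
}
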