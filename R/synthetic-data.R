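#' Subject-level gait parameters for the synthetic generator
#'
#' Bundles the generative factors of one subject's gait. Defaults
#' correspond to a mid-range stroke survivor walking with moderate
#' asymmetry; [draw_subject_params()] samples group-typical values.
#'
#' @param subject_id string identifier.
#' @param group `"stroke"` or `"healthy"`.
#' @param mean_speed preferred walking speed in m/s (> 0).
#' @param stride_time mean stride duration in s.
#' @param stride_time_cv coefficient of variation of stride times.
#' @param swing_fraction fraction of the stride spent in swing, in (0,1).
#' @param asymmetry left/right offset of swing parameters, in \[0,1):
#'   the left foot gets `(1 + asymmetry/2)`, the right `(1 - asymmetry/2)`
#'   times the swing fraction and swing gyroscope peak.
#' @param swing_peak_gyro peak sagittal angular velocity at mid-swing,
#'   degrees/s.
#' @param noise_acc_sd,noise_gyro_sd white sensor-noise SDs (g, deg/s).
#' @param gyro_offset length-3 constant gyroscope bias per axis, deg/s
#'   (|offset| <= 5).
#' @param uses_aid walking-aid flag (metadata only).
#' @param template waveform template variant, `"stroke"` (stance shuffle
#'   ripple, sharper impact transient) or `"healthy"` (smoother);
#'   defaults to the group.
#' @return A validated list of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S001", group = c("stroke", "healthy"),
                           mean_speed = 0.7, stride_time = 1.25,
                           stride_time_cv = 0.05, swing_fraction = 0.36,
                           asymmetry = 0.12, swing_peak_gyro = 260,
                           noise_acc_sd = 0.02, noise_gyro_sd = 1,
                           gyro_offset = c(0.5, -0.3, 0.8), uses_aid = FALSE,
                           template = NULL) {
  group <- match.arg(group)
  if (is.null(template)) template <- group
  template <- match.arg(template, c("stroke", "healthy"))
  stopifnot(mean_speed > 0, stride_time > 0,
            stride_time_cv >= 0, swing_fraction > 0, swing_fraction < 1,
            asymmetry >= 0, asymmetry < 1, swing_peak_gyro > 0,
            noise_acc_sd >= 0, noise_gyro_sd >= 0,
            length(gyro_offset) == 3, all(abs(gyro_offset) <= 5))
  structure(
    list(subject_id = subject_id, group = group, mean_speed = mean_speed,
         stride_time = stride_time, stride_time_cv = stride_time_cv,
         swing_fraction = swing_fraction, asymmetry = asymmetry,
         swing_peak_gyro = swing_peak_gyro, noise_acc_sd = noise_acc_sd,
         noise_gyro_sd = noise_gyro_sd, gyro_offset = as.numeric(gyro_offset),
         uses_aid = uses_aid, template = template),
    class = "subject_params")
}

#' Group-typical parameter distributions
#'
#' Per-group sampling distributions for every [subject_params()] field:
#' numeric entries are `c(mean, sd, lower, upper)` truncated normals.
#' Means mirror the cohort the generator emulates (stroke mean speed
#' 0.71 +/- 0.29 m/s, healthy 1.21 +/- 0.13 m/s); spreads and
#' gait-cycle values are realistic choices for clinical stroke vs
#' healthy adult gait. Override entries to design cohorts where chosen
#' factors dominate (set an `sd` of 0 to hold a parameter fixed).
#'
#' @return Named list with elements `stroke` and `healthy`.
#' @export
default_group_distributions <- function() {
  list(
    stroke = list(
      mean_speed = c(0.71, 0.29, 0.15, 1.35),  # mean, sd, lower, upper
      stride_time = c(1.25, 0.12, 0.90, 1.70),
      stride_time_cv = c(0.05, 0.015, 0.01, 0.10),
      swing_fraction = c(0.36, 0.03, 0.25, 0.45),
      asymmetry = c(0.12, 0.05, 0.00, 0.30),
      swing_peak_gyro = c(260, 40, 150, 420),
      noise_acc_sd = 0.02, noise_gyro_sd = 1,
      gyro_offset_max = 1.5, p_aid = 0.5),
    healthy = list(
      mean_speed = c(1.21, 0.13, 0.90, 1.50),
      stride_time = c(1.05, 0.06, 0.90, 1.25),
      stride_time_cv = c(0.02, 0.005, 0.005, 0.05),
      swing_fraction = c(0.42, 0.02, 0.35, 0.48),
      asymmetry = c(0.01, 0.01, 0.00, 0.05),
      swing_peak_gyro = c(360, 30, 250, 480),
      noise_acc_sd = 0.02, noise_gyro_sd = 1,
      gyro_offset_max = 1.5, p_aid = 0)
  )
}

rnorm_trunc <- function(n, spec) {
  x <- rnorm(n, spec[1], spec[2])
  pmin(pmax(x, spec[3]), spec[4])
}

#' Draw group-typical subject parameters
#'
#' Samples one subject's generative gait factors from the per-group
#' distributions (uses the current RNG stream).
#'
#' @param subject_id identifier.
#' @param group `"stroke"` or `"healthy"`.
#' @param distributions per-group distribution list, defaults to
#'   [default_group_distributions()]; entries may be overridden.
#' @return A [subject_params()] object.
#' @export
draw_subject_params <- function(subject_id, group = c("stroke", "healthy"),
                                distributions = default_group_distributions()) {
  group <- match.arg(group)
  d <- distributions[[group]]
  subject_params(
    subject_id = subject_id, group = group,
    mean_speed = rnorm_trunc(1, d$mean_speed),
    stride_time = rnorm_trunc(1, d$stride_time),
    stride_time_cv = rnorm_trunc(1, d$stride_time_cv),
    swing_fraction = rnorm_trunc(1, d$swing_fraction),
    asymmetry = rnorm_trunc(1, d$asymmetry),
    swing_peak_gyro = rnorm_trunc(1, d$swing_peak_gyro),
    noise_acc_sd = d$noise_acc_sd, noise_gyro_sd = d$noise_gyro_sd,
    gyro_offset = runif(3, -d$gyro_offset_max, d$gyro_offset_max),
    uses_aid = runif(1) < d$p_aid,
    template = group)
}

# --- walk kinematics -------------------------------------------------------

# Body-level forward simulation on a shuttle walking path: constant
# preferred speed, with a 180-degree turn every `path_length` metres of
# cumulative distance. A turn lasts `turn_duration` seconds, during which
# speed dips smoothly to half and heading rotates by pi (raised cosine).
# Turn geometry is a free modelling choice: the emulated protocol only
# fixes the 14-m path.
simulate_body_path <- function(n, fs, mean_speed, path_length = 14,
                               turn_duration = 1.5) {
  v <- numeric(n); psi <- numeric(n); psi_dot <- numeric(n); d <- numeric(n)
  dist <- 0; heading_base <- 0; turning <- FALSE; turn_k0 <- 0
  next_turn <- path_length
  turns <- NULL
  for (k in seq_len(n)) {
    if (!turning && dist >= next_turn) {
      turning <- TRUE
      turn_k0 <- k
      turns <- rbind(turns, c(k, min(n, k + round(turn_duration * fs))))
    }
    if (turning) {
      frac <- (k - turn_k0) / (turn_duration * fs)
      if (frac >= 1) {
        turning <- FALSE
        heading_base <- heading_base + pi
        next_turn <- next_turn + path_length
        psi[k] <- heading_base
        v[k] <- mean_speed
      } else {
        psi[k] <- heading_base + pi * (1 - cos(pi * frac)) / 2
        psi_dot[k] <- pi * (pi / turn_duration) * sin(pi * frac) / 2
        v[k] <- mean_speed * (1 - 0.5 * sin(pi * frac)^2)
      }
    } else {
      psi[k] <- heading_base
      v[k] <- mean_speed
    }
    dist <- dist + v[k] / fs
    d[k] <- dist
  }
  list(v = v, psi = psi, psi_dot = psi_dot, d = d, turns = turns)
}

# Per-foot stride schedule: contact times from i.i.d. truncated-normal
# stride durations, starting at `t0` (the right foot is offset by half a
# stride so the feet alternate).
draw_stride_schedule <- function(t0, t_end, stride_time, cv) {
  times <- t0
  repeat {
    tau <- rnorm(1, stride_time, cv * stride_time)
    tau <- max(tau, 0.5 * stride_time)
    times <- c(times, times[length(times)] + tau)
    if (times[length(times)] > t_end) break
  }
  times
}

# Build one foot's noise-free kinematics on the common clock.
# Returns per-sample forward speed u (m/s), pitch angle (deg), pitch rate
# (deg/s incl. template texture), vertical velocity (m/s), vertical
# impact acceleration (m/s^2), and the foot's own heading (rad) with its
# rate. A planted foot does not rotate with the body: heading is held
# during stance and caught up to the body heading during swing.
foot_kinematics <- function(contacts, tgrid, fs, body, swing_fraction,
                            swing_peak_gyro, template) {
  n <- length(tgrid)
  u <- numeric(n); th <- numeric(n); thdot <- numeric(n)
  w <- numeric(n); a_imp <- numeric(n)
  psi_f <- numeric(n); psid_f <- numeric(n)
  h_max <- if (template == "healthy") 0.05 else 0.03
  impact_amp <- if (template == "healthy") 1.5 else 3.0
  ripple_amp <- if (template == "stroke") 8 else 0
  d_at <- approx(tgrid, body$d, xout = pmax(contacts, 0), rule = 2)$y
  psi_at <- approx(tgrid, body$psi, xout = pmax(contacts, 0), rule = 2)$y
  n_strides <- length(contacts) - 1
  held <- psi_at[1]
  psi_f[] <- held
  for (i in seq_len(n_strides)) {
    t_c <- contacts[i]
    tau <- contacts[i + 1] - contacts[i]
    t_sw0 <- t_c + (1 - swing_fraction) * tau
    T_sw <- swing_fraction * tau
    delta <- d_at[i + 1] - d_at[i]
    v_max <- 2 * delta / T_sw
    th_max <- swing_peak_gyro * T_sw / pi   # deg, so that peak rate matches
    target <- psi_at[i + 1]
    # stance samples: heading held
    k_st_all <- which(tgrid >= t_c & tgrid < t_sw0)
    if (length(k_st_all)) psi_f[k_st_all] <- held
    # swing samples
    k_sw <- which(tgrid >= t_sw0 & tgrid < t_sw0 + T_sw)
    if (length(k_sw)) {
      s <- (tgrid[k_sw] - t_sw0) / T_sw
      u[k_sw] <- v_max * (1 - cos(2 * pi * s)) / 2
      th[k_sw] <- th_max * (1 - cos(2 * pi * s)) / 2
      thdot[k_sw] <- th_max * (pi / T_sw) * sin(2 * pi * s)
      w[k_sw] <- h_max * (pi / T_sw) * sin(2 * pi * s)
      psi_f[k_sw] <- held + (target - held) * (1 - cos(pi * s)) / 2
      psid_f[k_sw] <- (target - held) * pi * sin(pi * s) / (2 * T_sw)
    }
    if (length(k_sw) || length(k_st_all)) {
      last_k <- max(c(k_sw, k_st_all))
      if (last_k < n) psi_f[(last_k + 1):n] <- target
    }
    held <- target
    # stance texture (stroke template: low-amplitude shuffle ripple)
    if (ripple_amp > 0) {
      k_st <- which(tgrid >= t_c & tgrid < t_sw0)
      if (length(k_st)) {
        s_st <- (tgrid[k_st] - t_c) / (t_sw0 - t_c)
        thdot[k_st] <- thdot[k_st] +
          ripple_amp * sin(2 * pi * 3.5 * (tgrid[k_st] - t_c)) * sin(pi * s_st)^2
      }
    }
    # vertical impact transient at foot contact (biphasic, zero net)
    k_im <- which(tgrid >= t_c & tgrid < t_c + 0.06)
    if (length(k_im)) {
      s_im <- (tgrid[k_im] - t_c) / 0.06
      a_imp[k_im] <- a_imp[k_im] + impact_amp * sin(2 * pi * s_im)
    }
  }
  list(u = u, th = th, thdot = thdot, w = w, a_imp = a_imp,
       psi = psi_f, psi_dot = psid_f)
}

# Rotate global-frame quantities into the sensor frame and assemble the
# measured signals. R = Rz(psi) Ry(theta) maps sensor to global.
sensor_signals <- function(kin, body, fs) {
  n <- length(kin$u)
  psi <- kin$psi; psi_dot_dps <- kin$psi_dot * 180 / pi
  th_rad <- kin$th * pi / 180
  # global linear velocity and acceleration (numerical gradient)
  vx <- kin$u * cos(psi); vy <- kin$u * sin(psi); vz <- kin$w
  grad <- function(x) {
    g <- numeric(length(x))
    g[2:(length(x) - 1)] <- (x[3:length(x)] - x[1:(length(x) - 2)]) * fs / 2
    g[1] <- (x[2] - x[1]) * fs
    g[length(x)] <- (x[length(x)] - x[length(x) - 1]) * fs
    g
  }
  agx <- grad(vx); agy <- grad(vy); agz <- grad(vz) + kin$a_imp
  agz_tot <- agz + GRAVITY_MPS2
  c1 <- cos(psi); s1 <- sin(psi); c2 <- cos(th_rad); s2 <- sin(th_rad)
  ax <- (c1 * c2 * agx + s1 * c2 * agy - s2 * agz_tot) / GRAVITY_MPS2
  ay <- (-s1 * agx + c1 * agy) / GRAVITY_MPS2
  az <- (c1 * s2 * agx + s1 * s2 * agy + c2 * agz_tot) / GRAVITY_MPS2
  # body rates: omega = theta' e_y + Ry(theta)^T psi' e_z
  gx <- -psi_dot_dps * s2
  gy <- kin$thdot
  gz <- psi_dot_dps * c2
  list(acc = cbind(ax, ay, az), gyr = cbind(gx, gy, gz))
}

crop_indices <- function(times, fs, offset, n_out) {
  idx <- floor(times * fs + 1e-9) + 1 - offset
  idx[idx >= 1 & idx <= n_out]
}

#' Simulate one two-minute walk for both feet
#'
#' Generates a stride-periodic two-foot IMU recording pair from smooth
#' raised-cosine stride templates, with turns every 14 m of cumulative
#' distance, i.i.d. stride-time variability, left/right asymmetry, white
#' sensor noise, a constant gyroscope offset, and saturation at the
#' sensor ranges (+/-8 g, +/-500 deg/s). Ground truth (foot contacts,
#' stance intervals, walked distance, generative factors) is recorded
#' before noise is added.
#'
#' @param params a [subject_params()] object.
#' @param duration walk duration in seconds (>= 10, and at least two
#'   strides).
#' @param fs sampling frequency in Hz.
#' @param seed optional integer; when given the walk is a deterministic
#'   function of `(params, duration, fs, seed)`.
#' @param session metadata string stored on the recordings.
#' @param start_jitter optional length-2 vector of left/right recording
#'   start offsets in seconds (the two sensors are not synchronized);
#'   `NULL` draws both uniformly from \[0, 0.5\].
#' @return A list with elements `left` and `right` ([imu_recording()]s)
#'   and `truth` (ground-truth list: per-foot `contacts` and
#'   `stance_intervals` in local sample indices, `true_distance` in m,
#'   `true_mean_speed` in m/s, `ap_speed` series, `turn_intervals`,
#'   `generative_factors`).
#' @export
simulate_walk <- function(params, duration = 120, fs = 104, seed = NULL,
                          session = NA_character_, start_jitter = NULL) {
  stopifnot(inherits(params, "subject_params"))
  if (duration < 10) stop("duration must be at least 10 s")
  if (duration < 2 * params$stride_time) stop("walk too short")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  n_out <- round(duration * fs)
  max_jit <- 0.5
  if (is.null(start_jitter)) start_jitter <- runif(2, 0, max_jit)
  off <- round(start_jitter * fs)
  n_total <- n_out + max(off) + 2
  tgrid <- (seq_len(n_total) - 1) / fs

  body <- simulate_body_path(n_total, fs, params$mean_speed)

  a <- params$asymmetry
  foot_cfg <- list(
    left = list(offset = off[1], phase = 0,
                swf = min(0.95, params$swing_fraction * (1 + a / 2)),
                peak = params$swing_peak_gyro * (1 + a / 2)),
    right = list(offset = off[2], phase = -params$stride_time / 2,
                 swf = max(0.05, params$swing_fraction * (1 - a / 2)),
                 peak = params$swing_peak_gyro * (1 - a / 2)))

  out <- list()
  truth <- list(per_foot = list())
  for (foot in c("left", "right")) {
    cfg <- foot_cfg[[foot]]
    contacts <- draw_stride_schedule(cfg$phase, duration + max_jit + 1,
                                     params$stride_time, params$stride_time_cv)
    kin <- foot_kinematics(contacts, tgrid, fs, body, cfg$swf, cfg$peak,
                           params$template)
    sig <- sensor_signals(kin, body, fs)
    keep <- cfg$offset + seq_len(n_out)
    acc <- sig$acc[keep, , drop = FALSE]
    gyr <- sig$gyr[keep, , drop = FALSE]
    # ground truth in local (cropped) indices, before noise
    c_idx <- crop_indices(contacts, fs, cfg$offset, n_out)
    stance_len <- round((1 - cfg$swf) * diff(
      floor(contacts * fs + 1e-9) + 1)[seq_len(length(contacts) - 1)])
    all_c <- floor(contacts * fs + 1e-9) + 1 - cfg$offset
    st <- cbind(all_c[seq_along(stance_len)],
                all_c[seq_along(stance_len)] + stance_len)
    st <- st[st[, 1] >= 1 & st[, 2] <= n_out, , drop = FALSE]
    truth$per_foot[[foot]] <- list(
      contacts = c_idx, stance_intervals = st,
      swing_fraction = cfg$swf, swing_peak_gyro = cfg$peak)
    # sensor noise, constant offset, hardware saturation
    acc <- acc + matrix(rnorm(length(acc), 0, params$noise_acc_sd),
                        nrow = nrow(acc))
    gyr <- gyr + matrix(rnorm(length(gyr), 0, params$noise_gyro_sd),
                        nrow = nrow(gyr)) +
      matrix(params$gyro_offset, nrow(gyr), 3, byrow = TRUE)
    acc <- pmin(pmax(acc, -ACC_RANGE_G), ACC_RANGE_G)
    gyr <- pmin(pmax(gyr, -GYR_RANGE_DPS), GYR_RANGE_DPS)
    out[[foot]] <- imu_recording(
      acc, gyr, fs, foot = foot,
      subject_id = params$subject_id, group = params$group,
      session = session, uses_aid = params$uses_aid)
  }

  # body-level truth in the right foot's frame
  keep_r <- foot_cfg$right$offset + seq_len(n_out)
  ap_speed <- body$v[keep_r]
  true_distance <- sum((ap_speed[-1] + ap_speed[-n_out]) / 2) / fs
  turns <- body$turns
  if (!is.null(turns)) {
    turns <- turns - foot_cfg$right$offset
    turns <- turns[turns[, 1] >= 1 & turns[, 1] <= n_out, , drop = FALSE]
    turns[, 2] <- pmin(turns[, 2], n_out)
  }
  truth$true_contacts <- lapply(truth$per_foot, `[[`, "contacts")
  truth$true_stance_intervals <- lapply(truth$per_foot, `[[`, "stance_intervals")
  truth$ap_speed <- ap_speed
  truth$true_distance <- true_distance
  truth$true_mean_speed <- true_distance / duration
  truth$turn_intervals <- turns
  truth$generative_factors <- params
  truth$fs <- fs
  list(left = out$left, right = out$right, truth = truth)
}

#' Simulate a static (sensor at rest) recording
#'
#' Emulates the static calibration measurement used to determine the
#' gyroscope offset: the sensor lies flat (z up), so the accelerometer
#' reads 1 g on z and the gyroscope reads only its offset plus noise.
#'
#' @inheritParams simulate_walk
#' @param duration length in seconds.
#' @return An [imu_recording()].
#' @export
simulate_static <- function(params, duration = 6, fs = 104, seed = NULL) {
  stopifnot(inherits(params, "subject_params"))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  n <- round(duration * fs)
  acc <- cbind(rnorm(n, 0, params$noise_acc_sd),
               rnorm(n, 0, params$noise_acc_sd),
               rnorm(n, 1, params$noise_acc_sd))
  gyr <- matrix(rnorm(3 * n, 0, params$noise_gyro_sd), n, 3) +
    matrix(params$gyro_offset, n, 3, byrow = TRUE)
  imu_recording(acc, gyr, fs, foot = "right",
                subject_id = params$subject_id, group = params$group,
                session = "static", uses_aid = params$uses_aid)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_stroke,n_healthy subject counts (>= 0).
#' @param sessions character subset of `test`, `retest`, `T0`, `Tend`.
#'   Longitudinal sessions (`T0`/`Tend`) are generated for the stroke
#'   group only, mirroring a rehabilitation study design.
#' @param duration walk length in seconds (default 120, a 2MWT).
#' @param fs sampling frequency in Hz (> 20).
#' @param seed integer seed; the whole cohort is a deterministic
#'   function of the spec.
#' @param distributions per-group parameter distributions, see
#'   [default_group_distributions()].
#' @param session_sd named list of SDs for the small session-level
#'   perturbation added to retest/Tend parameters (so test-retest
#'   agreement is high but below 1).
#' @param longitudinal_effect named list, additive change in
#'   `mean_speed` (m/s) and `asymmetry` between T0 and Tend.
#' @param start_jitter_max maximum start-time desynchronization of the
#'   two sensors, in seconds.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stroke = 30, n_healthy = 30,
                        sessions = c("test", "retest"),
                        duration = 120, fs = 104, seed = 1,
                        distributions = default_group_distributions(),
                        session_sd = list(mean_speed = 0.05,
                                          stride_time = 0.02,
                                          swing_fraction = 0.01,
                                          swing_peak_gyro = 10,
                                          asymmetry = 0.01),
                        longitudinal_effect = list(mean_speed = 0.09,
                                                   asymmetry = -0.02),
                        start_jitter_max = 0.5) {
  stopifnot(n_stroke >= 0, n_healthy >= 0, fs > 20, duration >= 10)
  sessions <- match.arg(sessions, c("test", "retest", "T0", "Tend"),
                        several.ok = TRUE)
  structure(list(n_stroke = n_stroke, n_healthy = n_healthy,
                 sessions = sessions, duration = duration, fs = fs,
                 seed = seed, distributions = distributions,
                 session_sd = session_sd,
                 longitudinal_effect = longitudinal_effect,
                 start_jitter_max = start_jitter_max),
            class = "cohort_spec")
}

perturb_params <- function(params, session_sd) {
  p <- unclass(params)
  for (nm in names(session_sd)) {
    if (session_sd[[nm]] > 0) p[[nm]] <- p[[nm]] + rnorm(1, 0, session_sd[[nm]])
  }
  p$mean_speed <- max(p$mean_speed, 0.05)
  p$asymmetry <- min(max(p$asymmetry, 0), 0.95)
  p$swing_fraction <- min(max(p$swing_fraction, 0.05), 0.95)
  p$swing_peak_gyro <- max(p$swing_peak_gyro, 50)
  p$stride_time <- max(p$stride_time, 0.4)
  do.call(subject_params, p[setdiff(names(p), NULL)])
}

apply_longitudinal <- function(params, effect) {
  p <- unclass(params)
  p$mean_speed <- max(p$mean_speed + (effect$mean_speed %||% 0), 0.05)
  p$asymmetry <- min(max(p$asymmetry + (effect$asymmetry %||% 0), 0), 0.95)
  do.call(subject_params, p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-foot IMU cohort
#'
#' Draws per-subject gait parameters from the group distributions, then
#' simulates every requested session. Retest and Tend sessions reuse the
#' subject's drawn parameters plus a small session-level perturbation;
#' Tend additionally applies the longitudinal effect. Everything is a
#' deterministic function of `spec` (including `spec$seed`).
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `gait_cohort` with `measurements` (named list;
#'   each element has `left`, `right`, `truth`, `meta`), `manifest` (one
#'   row per measurement) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  groups <- c(rep("stroke", spec$n_stroke), rep("healthy", spec$n_healthy))
  n_sub <- length(groups)
  ids <- sprintf("S%03d", seq_len(n_sub))
  base <- lapply(seq_len(n_sub), function(i)
    draw_subject_params(ids[i], groups[i], spec$distributions))

  measurements <- list()
  rows <- list()
  for (i in seq_len(n_sub)) {
    sess <- spec$sessions
    if (groups[i] == "healthy") sess <- intersect(sess, c("test", "retest"))
    for (s in sess) {
      p <- base[[i]]
      if (s %in% c("retest", "Tend")) p <- perturb_params(p, spec$session_sd)
      if (s == "Tend") p <- apply_longitudinal(p, spec$longitudinal_effect)
      mid <- paste0(ids[i], "_", s)
      walk_seed <- (spec$seed + 1009L * i + 101L * match(s, c("test", "retest", "T0", "Tend"))) %% .Machine$integer.max
      jit <- runif(2, 0, spec$start_jitter_max)
      w <- simulate_walk(p, spec$duration, spec$fs, seed = walk_seed,
                         session = s, start_jitter = jit)
      w$left$measurement_id <- mid
      w$right$measurement_id <- mid
      measurements[[mid]] <- list(
        left = w$left, right = w$right, truth = w$truth,
        meta = list(measurement_id = mid, subject_id = ids[i],
                    group = groups[i], session = s, uses_aid = p$uses_aid,
                    gyro_offset_dps = p$gyro_offset))
      rows[[mid]] <- data.frame(
        measurement_id = mid, subject_id = ids[i], group = groups[i],
        session = s, uses_aid = p$uses_aid,
        true_mean_speed = w$truth$true_mean_speed,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(measurements = measurements, manifest = manifest,
                 spec = spec),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d measurements, %d subjects (%d stroke, %d healthy)\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              x$spec$n_stroke, x$spec$n_healthy))
  invisible(x)
}

#' Write / read a cohort as CSV + JSON files
#'
#' One CSV per recording (with JSON sidecar carrying metadata and the
#' static-calibration gyroscope offset), one ground-truth JSON per
#' measurement, and a cohort `manifest.csv`.
#'
#' @param cohort a `gait_cohort`.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$measurements) {
    mid <- m$meta$measurement_id
    for (foot in c("left", "right")) {
      write_imu_csv(m[[foot]], file.path(dir, paste0(mid, "_", foot, ".csv")),
                    gyro_offset_dps = m$meta$gyro_offset_dps)
    }
    tr <- m$truth
    tr$generative_factors <- unclass(tr$generative_factors)
    tr$per_foot <- NULL
    jsonlite::write_json(tr, file.path(dir, paste0(mid, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort()` returns a `gait_cohort` (without the full
#'   generator spec; `spec` holds only what the manifest implies).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  measurements <- list()
  for (i in seq_len(nrow(manifest))) {
    mid <- manifest$measurement_id[i]
    left <- read_imu_csv(file.path(dir, paste0(mid, "_left.csv")))
    right <- read_imu_csv(file.path(dir, paste0(mid, "_right.csv")))
    truth_path <- file.path(dir, paste0(mid, "_truth.json"))
    truth <- if (file.exists(truth_path)) {
      jsonlite::read_json(truth_path, simplifyVector = TRUE)
    }
    measurements[[mid]] <- list(
      left = left, right = right, truth = truth,
      meta = list(measurement_id = mid, subject_id = manifest$subject_id[i],
                  group = manifest$group[i], session = manifest$session[i],
                  uses_aid = manifest$uses_aid[i],
                  gyro_offset_dps = attr(right, "gyro_offset_dps")))
  }
  structure(list(measurements = measurements, manifest = manifest,
                 spec = NULL),
            class = "gait_cohort")
}
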