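test_that("noise-free symmetric walk: feet identical up to a half-stride shift, truth speed matches", {
  p <- clean_params()
  w <- simulate_walk(p, duration = 60, fs = 104, seed = 1,
                     start_jitter = c(0, 0))
  shift <- round(104 * p$stride_time / 2)
  # compare the straight-walking segment before the first turn (the turn
  # schedule is anchored in absolute time, not stride phase), skipping
  # the ramp-in stride at the recording start
  idx <- seq(2 * 104, 12 * 104)
  expect_equal(w$left$gyr[idx, 2], w$right$gyr[idx + shift, 2],
               tolerance = 1e-8)
  expect_equal(w$left$acc[idx, 1], w$right$acc[idx + shift, 1],
               tolerance = 1e-8)
  # with the turn model, truth speed is what the generator integrates:
  # close to, and never above, the commanded speed
  expect_lt(w$truth$true_mean_speed, p$mean_speed + 1e-9)
  expect_gt(w$truth$true_mean_speed, 0.9 * p$mean_speed)
})

test_that("same seed reproduces the walk bit-identically; different seeds differ", {
  p <- subject_params()
  w1 <- simulate_walk(p, 20, 104, seed = 9)
  w2 <- simulate_walk(p, 20, 104, seed = 9)
  w3 <- simulate_walk(p, 20, 104, seed = 10)
  expect_identical(w1$left$acc, w2$left$acc)
  expect_identical(w1$right$gyr, w2$right$gyr)
  expect_false(identical(w1$left$acc, w3$left$acc))
  expect_false(identical(w1$truth$true_contacts$left,
                         w3$truth$true_contacts$left))
})

test_that("emitted samples respect the sensor ranges and truth is internally consistent", {
  w <- default_walk()$walk
  for (foot in c("left", "right")) {
    expect_true(all(abs(w[[foot]]$acc) <= 8))
    expect_true(all(abs(w[[foot]]$gyr) <= 500))
  }
  # contacts counted against duration / stride_time
  p <- default_walk()$params
  expected <- 120 / p$stride_time
  for (foot in c("left", "right")) {
    expect_lte(abs(length(w$truth$true_contacts[[foot]]) - expected), 3)
    expect_true(all(diff(w$truth$true_contacts[[foot]]) > 0))
  }
  # distance equals the time-integral of the true forward speed (< 0.1%)
  v <- w$truth$ap_speed
  d_int <- sum((v[-1] + v[-length(v)]) / 2) / w$truth$fs
  expect_lt(abs(d_int - w$truth$true_distance) / w$truth$true_distance, 1e-3)
  expect_equal(w$truth$true_mean_speed, w$truth$true_distance / 120)
})

test_that("walks shorter than two strides are rejected", {
  p <- subject_params(stride_time = 1.25)
  expect_error(simulate_walk(p, 5, 104), "10 s")
  expect_error(simulate_walk(subject_params(stride_time = 6), 11, 104),
               "walk too short")
})

test_that("cohort counting, session structure and determinism", {
  spec <- cohort_spec(n_stroke = 0, n_healthy = 1, sessions = "test",
                      duration = 12, seed = 3)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co$manifest), 1)
  expect_length(co$measurements, 1)
  m <- co$measurements[[1]]
  expect_s3_class(m$left, "imu_recording")
  expect_s3_class(m$right, "imu_recording")

  spec2 <- cohort_spec(n_stroke = 2, n_healthy = 1,
                       sessions = c("test", "retest", "T0", "Tend"),
                       duration = 12, seed = 3)
  co2 <- simulate_cohort(spec2)
  # healthy subjects get no longitudinal sessions
  by_group <- table(co2$manifest$group)
  expect_equal(unname(by_group[["stroke"]]), 2 * 4)
  expect_equal(unname(by_group[["healthy"]]), 2)
  co2b <- simulate_cohort(spec2)
  expect_identical(co2$measurements[[3]]$right$acc,
                   co2b$measurements[[3]]$right$acc)
})

test_that("retest reuses subject parameters up to the session perturbation", {
  spec <- cohort_spec(n_stroke = 1, n_healthy = 0,
                      sessions = c("test", "retest"), duration = 12, seed = 8)
  co <- simulate_cohort(spec)
  f_test <- co$measurements[["S001_test"]]$truth$generative_factors
  f_retest <- co$measurements[["S001_retest"]]$truth$generative_factors
  expect_equal(f_retest$mean_speed, f_test$mean_speed, tolerance = 0.5)
  expect_false(f_retest$mean_speed == f_test$mean_speed)
  # untouched fields identical
  expect_identical(f_retest$gyro_offset, f_test$gyro_offset)
  expect_identical(f_retest$noise_acc_sd, f_test$noise_acc_sd)
})

test_that("Tend applies the longitudinal effect on top of the base draw", {
  spec <- cohort_spec(n_stroke = 1, n_healthy = 0, sessions = c("T0", "Tend"),
                      duration = 12, seed = 8,
                      session_sd = list(mean_speed = 0, stride_time = 0,
                                        swing_fraction = 0,
                                        swing_peak_gyro = 0, asymmetry = 0),
                      longitudinal_effect = list(mean_speed = 0.2,
                                                 asymmetry = -0.02))
  co <- simulate_cohort(spec)
  f0 <- co$measurements[["S001_T0"]]$truth$generative_factors
  f1 <- co$measurements[["S001_Tend"]]$truth$generative_factors
  expect_equal(f1$mean_speed - f0$mean_speed, 0.2, tolerance = 1e-10)
  expect_equal(f1$asymmetry - f0$asymmetry, -0.02, tolerance = 1e-10)
})

test_that("cohort round-trips through the CSV/JSON writer", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_stroke = 1, n_healthy = 0, sessions = "test",
                      duration = 12, seed = 5)
  co <- simulate_cohort(spec)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  co2 <- read_cohort(dir)
  m1 <- co$measurements[[1]]; m2 <- co2$measurements[[1]]
  expect_equal(m2$right$acc, m1$right$acc, tolerance = 1e-12)
  expect_equal(m2$meta$gyro_offset_dps, m1$meta$gyro_offset_dps,
               tolerance = 1e-12)
  expect_equal(m2$truth$true_mean_speed, m1$truth$true_mean_speed,
               tolerance = 1e-9)
})

test_that("stroke and healthy default cohorts separate in estimated gait speed", {
  co <- fixture("speed_cohort_small", function() {
    simulate_cohort(cohort_spec(n_stroke = 8, n_healthy = 8,
                                sessions = "test", duration = 60, seed = 77))
  })
  speeds <- compute_speeds(co)
  merged <- merge(speeds, co$manifest, by = "measurement_id")
  tt <- independent_t(merged$gait_speed_mps[merged$group == "stroke"],
                      merged$gait_speed_mps[merged$group == "healthy"])
  expect_lt(tt$p, 0.01)
  expect_lt(mean(merged$gait_speed_mps[merged$group == "stroke"]),
            mean(merged$gait_speed_mps[merged$group == "healthy"]))
})
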