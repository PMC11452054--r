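make_rec <- function(acc, gyr, fs = 104) {
  imu_recording(acc, gyr, fs, foot = "right", measurement_id = "m")
}

test_that("resampling 104 -> 100 Hz preserves duration, constants and tones", {
  n <- 12480
  rec <- make_rec(matrix(1, n, 3), matrix(0.5, n, 3), fs = 104)
  out <- resample_to_100hz(rec)
  expect_equal(n_samples(out), 12000)
  expect_equal(out$fs, 100)
  expect_true(all(abs(out$acc - 1) < 1e-12))
  expect_true(all(abs(out$gyr - 0.5) < 1e-12))

  # a 2 Hz tone survives linear resampling with < 1% amplitude error
  t104 <- (0:(n - 1)) / 104
  tone <- sin(2 * pi * 2 * t104)
  rec2 <- make_rec(cbind(tone, tone, tone), matrix(0, n, 3))
  out2 <- resample_to_100hz(rec2)
  t100 <- out2$time
  ref <- sin(2 * pi * 2 * t100)
  expect_lt(max(abs(out2$acc[, 1] - ref)), 0.01)
  # refuse upsampling
  expect_error(resample_to_100hz(make_rec(matrix(0, 500, 3),
                                          matrix(0, 500, 3), fs = 50)),
               "below target")
})

test_that("gyroscope offset correction is exact and recoverable from a static segment", {
  p <- subject_params(gyro_offset = c(1.2, -0.7, 0.4), noise_gyro_sd = 0.5)
  st <- simulate_static(p, duration = 6, seed = 2)
  est <- estimate_gyro_offset(st)
  # standard error of the mean over >= 5 s at 104 Hz with sd 0.5 is ~0.02
  expect_true(all(abs(est - p$gyro_offset) < 0.05))
  corr <- correct_gyro_offset(st, est)
  expect_true(all(abs(colMeans(corr$gyr)) < 1e-9))
  # zero offset is the identity
  rec <- make_rec(matrix(0, 600, 3), matrix(2, 600, 3))
  expect_equal(correct_gyro_offset(rec, c(0, 0, 0))$gyr, rec$gyr)
  # too-short static segment refused
  expect_error(estimate_gyro_offset(simulate_static(p, duration = 3)),
               "5 s")
})

test_that("band-pass rejects DC, passes 1 Hz and attenuates 40 Hz", {
  fs <- 100; n <- 6000
  t <- (0:(n - 1)) / fs
  mk <- function(x) make_rec(cbind(x, x, x), cbind(x, x, x), fs = fs)
  steady <- 3001:6000   # after the filter transient
  # the 0.01 Hz edge gives a ~16 s decay constant: DC must decay
  # monotonically toward zero over a long horizon
  nl <- 30000
  dc <- bandpass(make_rec(matrix(1, nl, 3), matrix(1, nl, 3), fs = fs))
  expect_lt(max(abs(dc$acc[28001:30000, 1])), 0.01)
  expect_lt(max(abs(dc$acc[28001:30000, 1])),
            max(abs(dc$acc[1001:3000, 1])) / 10)
  g1 <- bandpass(mk(sin(2 * pi * 1 * t)))
  amp1 <- max(abs(g1$acc[steady, 1]))
  expect_gte(amp1, 0.9); expect_lte(amp1, 1.0)
  g40 <- bandpass(mk(sin(2 * pi * 40 * t)))
  expect_lt(max(abs(g40$acc[steady, 1])), 0.3)
})

test_that("nominal 50%-overlap arithmetic gives floor((n-512)/256)+1 epochs", {
  starts <- gaitlatent:::nominal_epoch_starts(12000)
  expect_length(starts, floor((12000 - 512) / 256) + 1)  # 45
  expect_equal(diff(starts), rep(256L, 44))
  expect_length(gaitlatent:::nominal_epoch_starts(400), 0)
})

test_that("segmentation snaps starts into stance, trims the stride bounds and handles short input", {
  w <- default_walk()$walk
  p <- default_walk()$params
  rec <- correct_gyro_offset(resample_to_100hz(w$right), p$gyro_offset)
  ev <- detect_gait_events(rec)
  eps <- segment_epochs(rec, ev)
  expect_gte(length(eps), 40)
  expect_lte(length(eps), 47)
  starts <- vapply(eps, `[[`, integer(1), "start_index")
  in_stance <- vapply(starts, function(s)
    any(s >= ev$stance_intervals[, 1] & s < ev$stance_intervals[, 2]),
    logical(1))
  expect_true(all(in_stance))
  # first epoch starts in the stance of stride 2, none extends past the
  # second-to-last stride
  m <- length(ev$foot_contacts)
  expect_gte(starts[1], ev$foot_contacts[2])
  expect_lt(starts[1], ev$foot_contacts[3])
  expect_true(all(starts + 512 - 1 < ev$foot_contacts[m]))
  expect_true(all(vapply(eps, function(e) nrow(e$data) == 512L, logical(1))))

  # approximately 50% overlap: at least a half-step advance always, and
  # most steps close to the nominal 256 (turn-region stance gaps allow
  # occasional larger snaps)
  expect_true(all(diff(starts) >= 128))
  expect_gte(mean(abs(diff(starts) - 256) <= 64), 0.8)

  # too few strides -> empty with warning
  short <- make_rec(matrix(0, 600, 3), matrix(0, 600, 3), fs = 100)
  ev0 <- gait_events(c(10L, 120L, 230L), cbind(c(10L, 120L, 230L),
                                               c(60L, 170L, 280L)), 600, 100)
  expect_warning(out <- segment_epochs(short, ev0), "4 strides")
  expect_length(out, 0)
})

test_that("degenerate stance-everywhere events reproduce the overlap arithmetic", {
  n <- 12000
  rec <- make_rec(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3), n, 3),
                  fs = 100)
  ev <- stance_everywhere_events(n)
  eps <- segment_epochs(rec, ev)
  starts <- vapply(eps, `[[`, integer(1), "start_index")
  expect_equal(diff(starts), rep(256L, length(starts) - 1))
  # one overlap step of the full 45 is lost to each stride bound
  expect_gte(length(eps), 42)
})

test_that("zero_start zeroes the first row per channel and is idempotent", {
  e <- make_epoch(mean = 2, sd = 0.5)
  z <- zero_start(e)
  expect_equal(unname(z$data[1, ]), rep(0, 6))
  expect_equal(zero_start(z)$data, z$data)
  # constant column maps to all-zero column
  e2 <- e; e2$data[, 3] <- 7
  expect_true(all(zero_start(e2)$data[, 3] == 0))
})

test_that("outlier screening removes only gross statistical outliers", {
  eps <- lapply(1:199, function(i) make_epoch(seed = i))
  # dataset SD of the per-epoch means is ~ sd/sqrt(512); shift one epoch
  # by 10 dataset-SDs on one channel
  means <- vapply(eps, function(e) mean(e$data[, 1]), numeric(1))
  bad <- make_epoch(seed = 500)
  bad$data[, 1] <- bad$data[, 1] + 10 * sd(means)
  fl <- flag_outliers(c(eps, list(bad)))
  expect_length(fl$removed, 1)
  expect_equal(fl$stats$outlier, c(rep(FALSE, 199), TRUE))

  # a stationary batch yields (almost) no removals: |z| > 5 is ~6-sigma
  fl2 <- flag_outliers(eps)
  expect_lte(length(fl2$removed), 1)

  # two identical epochs: zero-variance statistics remove nothing
  twin <- list(make_epoch(seed = 3), make_epoch(seed = 3))
  expect_length(flag_outliers(twin)$removed, 0)
})

test_that("range normalization maps the sensor limits onto [-1, 1] and round-trips", {
  e <- make_epoch(sd = 0.01)
  e$data[1, ] <- c(8, -4, 2, 500, 0, -250)
  n <- normalize_epoch(e)
  expect_equal(unname(n$data[1, ]), c(1, -0.5, 0.25, 1, 0, -0.5))
  expect_true(all(n$data >= -1 & n$data <= 1))
  back <- denormalize_epoch(n)
  expect_equal(back$data, e$data, tolerance = 1e-12)
})

test_that("the preprocessing pipeline executes its stages in the fixed order", {
  w <- fixture("short_walk", function() {
    p <- subject_params(mean_speed = 0.9)
    list(params = p, walk = simulate_walk(p, 30, 104, seed = 11))
  })
  eps <- preprocess_measurement(w$walk$right,
                                gyro_offset = w$params$gyro_offset)
  expect_identical(attr(eps, "stages"),
                   c("resample", "offset", "events", "segment", "filter",
                     "zero"))
  # whole-recording filtering variant runs the filter before segmentation
  eps2 <- preprocess_measurement(w$walk$right,
                                 gyro_offset = w$params$gyro_offset,
                                 filter_scope = "recording")
  expect_identical(attr(eps2, "stages"),
                   c("resample", "offset", "events", "filter", "segment",
                     "zero"))
  prep <- prepare_epoch_set(eps)
  expect_true(all(vapply(prep$epochs, `[[`, logical(1), "normalized")))
  # removed fraction on a nominal cohort stays below 2%
  expect_lt(length(prep$removed) / length(eps), 0.02)
})
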