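# Shared fixtures, built once per test run and cached in this
# environment (generation is deterministic, so caching only saves time).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A clean, noise-free, symmetric walk (analytic checks).
clean_params <- function(...) {
  # stride_time 1.25 s puts the half-stride shift on the 104 Hz sample
  # grid exactly (65 samples), so shift comparisons are exact
  subject_params(mean_speed = 1.0, stride_time = 1.25, stride_time_cv = 0,
                 swing_fraction = 0.4, asymmetry = 0, swing_peak_gyro = 300,
                 noise_acc_sd = 0, noise_gyro_sd = 0, gyro_offset = c(0, 0, 0),
                 ...)
}

# Default-noise stroke walk reused by several modules.
default_walk <- function() {
  fixture("default_walk", function() {
    p <- subject_params(mean_speed = 0.8)
    list(params = p, walk = simulate_walk(p, 120, 104, seed = 404))
  })
}

# Fraction of true contacts matched by detected contacts within a time
# tolerance (truth indices on the recording's native grid).
contact_recall <- function(true_idx, true_fs, det_idx, det_fs, tol_s = 0.05) {
  if (!length(true_idx)) return(NA_real_)
  t_true <- (true_idx - 1) / true_fs
  t_det <- (det_idx - 1) / det_fs
  mean(vapply(t_true, function(tt) min(abs(t_det - tt)) <= tol_s, logical(1)))
}

# Build a degenerate gait_events object for segmentation arithmetic:
# contacts every `step` samples, stance covering everything.
stance_everywhere_events <- function(n, fs = 100, stride = 256L) {
  contacts <- seq(1L, n, by = stride)
  stance <- cbind(contacts, c(contacts[-1], n + 1L))
  gait_events(contacts, stance, n, fs)
}

# Synthetic epoch list with controlled per-channel means/sds.
make_epoch <- function(mean = 0, sd = 0.1, seed = 1, measurement_id = "m1") {
  set.seed(seed)
  gait_epoch(matrix(rnorm(512 * 6, mean, sd), 512, 6), start_index = 1L,
             foot = "right", measurement_id = measurement_id,
             subject_id = "s1", group = "stroke", session = "test",
             uses_aid = FALSE)
}

# Brute-force two-way ANOVA mean squares via stats::aov (independent
# oracle for the ICC implementation).
icc_2_1_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  session = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + session, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Small analysis table for psychometrics round trips.
toy_analysis_tables <- function(n = 12, seed = 5, icc_noise = 0.2) {
  set.seed(seed)
  base <- data.frame(subject_id = sprintf("P%02d", seq_len(n)),
                     group = "stroke")
  lat <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("L0", "L1", "L2")))
  speed <- runif(n, 0.3, 1.2)
  t1 <- cbind(base, as.data.frame(lat), gait_speed_mps = speed)
  t2 <- cbind(base, as.data.frame(lat + matrix(rnorm(n * 3, 0, icc_noise), n, 3)),
              gait_speed_mps = speed + rnorm(n, 0, 0.05))
  list(test = t1, retest = t2)
}
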