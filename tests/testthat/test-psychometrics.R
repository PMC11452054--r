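test_that("ICC(2,1) equals the brute-force ANOVA oracle on random matrices", {
  set.seed(42)
  for (i in 1:100) {
    x <- rnorm(20, 10, 3)
    y <- 0.8 * x + rnorm(20, 0, 1.5) + runif(1, -1, 1)
    expect_equal(icc_2_1(x, y)$icc, icc_2_1_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("ICC limits: perfect agreement gives 1; constant offsets are penalized", {
  x <- c(1, 3, 5, 7, 9, 11)
  r1 <- icc_2_1(x, x)
  expect_equal(r1$icc, 1)
  # retest = test + large constant: absolute agreement collapses
  r2 <- icc_2_1(x, x + 50)
  expect_lt(r2$icc, 0.2)
  # consistency would be perfect, agreement is not
  expect_gt(stats::cor(x, x + 50), 0.999)
  # no variance anywhere -> undefined
  expect_error(icc_2_1(rep(2, 5), rep(2, 5)), "undefined")
})

test_that("the ICC confidence interval matches an independent reference implementation", {
  # frozen from an external two-way random-effects (absolute agreement)
  # reference computation on this exact 15 x 2 matrix
  x <- c(8.021757299304, 9.264426697064, 12.575850522578, 10.387948838265,
         11.84046179928, 11.154207582515, 8.727072707258, 11.083904440821,
         9.366809097668, 9.355221767682, 10.194334637341, 6.948139186962,
         12.384332208203, 8.657820649652, 12.000538839319)
  y <- c(8.430814198387, 10.790053160767, 12.347874991545, 10.438512953089,
         12.410677100527, 9.688230703955, 9.689409860505, 12.617208756573,
         10.56825453228, 10.259037483132, 10.377552322849, 8.27366096861,
         13.543556705781, 9.271917325314, 12.304630289582)
  r <- icc_2_1(x, y)
  expect_equal(r$icc, 0.835035, tolerance = 1e-6)
  expect_equal(r$ci_low, 0.42, tolerance = 0.005)
  expect_equal(r$ci_high, 0.95, tolerance = 0.005)
})

test_that("SEM and MDC follow their closed forms", {
  x <- c(2, 4, 6, 8); y <- c(2.1, 3.9, 6.2, 7.8)
  r <- icc_2_1(x, y)
  sm <- sem_mdc(x, y, r)
  expect_equal(sm$sem, sd(c(x, y)) * sqrt(1 - r$icc), tolerance = 1e-12)
  expect_equal(sm$mdc, 1.96 * sqrt(2) * sm$sem, tolerance = 1e-12)
  expect_equal(sm$mdc / sm$sem, 2.77186, tolerance = 1e-4)
  # perfect reliability means zero measurement error
  sm1 <- sem_mdc(x, x, icc_2_1(x, x))
  expect_equal(sm1$sem, 0)
  expect_equal(sm1$mdc, 0)
  # published example: SEM 0.478 corresponds to an MDC of ~1.325
  expect_equal(1.96 * sqrt(2) * 0.478, 1.325, tolerance = 1e-3)
  # the ANOVA-error variant is available and close for near-agreement data
  sm2 <- sem_mdc(x, y, r, method = "ms_error")
  expect_gt(sm2$sem, 0)
})

test_that("pooled t-test matches the textbook closed form and is symmetric", {
  r <- independent_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  r2 <- independent_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # identical groups: t = 0, p = 1
  r3 <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  # Welch variant exposed
  r4 <- independent_t(c(1, 2, 3), c(4, 5, 9), welch = TRUE)
  expect_lt(r4$df, 4)
})

test_that("Hedges' g reproduces the published effect sizes and is affine invariant", {
  # published group summaries: gait speed and latent feature L2
  expect_equal(round(abs(hedges_g(0.4, 0.3, 68, 1.1, 0.2, 42)), 1), 2.6)
  expect_equal(round(abs(hedges_g(0.0, 0.6, 68, -0.1, 0.8, 42)), 2), 0.15)
  # equal means give zero
  expect_equal(hedges_g(1, 0.5, 10, 1, 0.7, 12), 0)
  # invariance under a common affine rescaling
  set.seed(1)
  a <- rnorm(15, 2, 1); b <- rnorm(12, 3, 1.5)
  g1 <- hedges_g_samples(a, b)
  g2 <- hedges_g_samples(3 * a - 5, 3 * b - 5)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("reliability categories use the 0.5 / 0.75 / 0.9 cut points exhaustively", {
  expect_identical(icc_category(c(-0.2, 0.49, 0.5, 0.74, 0.75, 0.89, 0.9, 1)),
                   c("poor", "poor", "moderate", "moderate", "good", "good",
                     "excellent", "excellent"))
})

test_that("reliability_analysis assembles ICC, SEM, MDC and categories per feature", {
  tabs <- toy_analysis_tables(n = 15, icc_noise = 0.15)
  rel <- reliability_analysis(tabs$test, tabs$retest)
  expect_setequal(rel$feature, c("L0", "L1", "L2", "gait_speed_mps"))
  expect_true(all(rel$ci_low <= rel$icc & rel$icc <= rel$ci_high))
  expect_equal(rel$mdc, 1.96 * sqrt(2) * rel$sem, tolerance = 1e-12)
  expect_identical(rel$category, icc_category(rel$icc))
  expect_true(all(rel$n_pairs == 15))
})

test_that("responsiveness classifies individual change by the strict MDC rule", {
  rel <- data.frame(feature = c("L0", "L1", "gait_speed_mps"),
                    icc = c(0.95, 0.6, 0.96),
                    ci_low = 0, ci_high = 1,
                    sem = c(0.1, 0.3, 0.05),
                    mdc = c(0.2, 0.6, 0.1),
                    n_pairs = 10,
                    category = c("excellent", "moderate", "excellent"))
  t0 <- data.frame(subject_id = c("a", "b", "c"),
                   L0 = c(0, 0, 0), L1 = c(0, 0, 0),
                   gait_speed_mps = c(0.5, 0.5, 0.5))
  # subject a: unchanged; b: +exactly MDC (not significant, strict);
  # c: clearly changed in L0 and speed
  t1 <- data.frame(subject_id = c("a", "b", "c"),
                   L0 = c(0, 0.2, 0.5), L1 = c(0, 0, 0),
                   gait_speed_mps = c(0.5, 0.5, 0.8))
  resp <- responsiveness(t0, t1, rel, reliable_only = TRUE)
  # L1 is only moderately reliable and must be excluded
  expect_false("L1" %in% resp$per_subject$feature)
  ps <- resp$per_subject
  expect_equal(ps$change[ps$subject_id == "a" & ps$feature == "L0"], "none")
  expect_equal(ps$change[ps$subject_id == "b" & ps$feature == "L0"], "none")
  expect_equal(ps$change[ps$subject_id == "c" & ps$feature == "L0"],
               "increased")
  expect_equal(resp$summary$changed_any_latent, 1)
  expect_equal(resp$summary$changed_gait_speed, 1)
  expect_equal(resp$summary$changed_both, 1)
  # identical sessions: everything "none"
  resp0 <- responsiveness(t0, t0, rel)
  expect_true(all(resp0$per_subject$change == "none"))
  # subjects without a pair are dropped with a message
  t1b <- t1[-1, ]
  expect_message(responsiveness(t0, t1b, rel), "excluded")
})

test_that("injected longitudinal speed gains of 2 MDC are classified as increases", {
  set.seed(99)
  n <- 20
  mdc <- 0.12
  base <- runif(n, 0.4, 1.0)
  gain <- rep(c(2 * mdc, 0), each = n / 2)
  t0 <- data.frame(subject_id = sprintf("s%02d", 1:n), gait_speed_mps = base)
  t1 <- data.frame(subject_id = sprintf("s%02d", 1:n),
                   gait_speed_mps = base + gain + rnorm(n, 0, 0.01))
  rel <- data.frame(feature = "gait_speed_mps", icc = 0.95, ci_low = 0.9,
                    ci_high = 0.99, sem = mdc / 2.77186, mdc = mdc,
                    n_pairs = n, category = "excellent")
  resp <- responsiveness(t0, t1, rel)
  inc <- resp$per_feature$increased[resp$per_feature$feature == "gait_speed_mps"]
  expect_gte(inc, n / 2 - 2)
  expect_lte(inc, n / 2 + 2)
})
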