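#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation for test-retest data:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`,
#' mean squares from the two-way ANOVA of the n x 2 score matrix. The
#' 95% confidence interval uses the F-distribution method.
#'
#' @param test,retest paired numeric vectors (same subjects, n >= 3, no
#'   missing values).
#' @param conf confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `n`, and the mean
#'   squares (`msr`, `msc`, `mse`).
#' @export
icc_2_1 <- function(test, retest, conf = 0.95) {
  stopifnot(length(test) == length(retest), length(test) >= 3,
            !anyNA(test), !anyNA(retest))
  y <- cbind(test, retest)
  n <- nrow(y); k <- 2
  gm <- mean(y)
  rm_ <- rowMeans(y); cm <- colMeans(y)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr == 0 && mse == 0)) {
    stop("ICC undefined: no variance in the score matrix")
  }
  icc <- (msr - mse) / denom
  # F-method confidence interval
  alpha <- 1 - conf
  fj <- msc / mse
  df2 <- (n - 1) * (k - 1)
  vn <- df2 * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- df2 * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f2u <- qf(1 - alpha / 2, n - 1, v)
  f2l <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f2u * mse) /
    (f2u * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f2l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2l * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n,
       msr = msr, msc = msc, mse = mse)
}

#' Standard error of measurement and minimal detectable change
#'
#' `SEM = sd_pooled * sqrt(1 - ICC)` with `sd_pooled` the SD of all 2n
#' scores (default), or `SEM = sqrt(MSE)` of the two-way ANOVA
#' (`method = "ms_error"`). The minimal detectable change is
#' `MDC = 1.96 * sqrt(2) * SEM`, the smallest individual change
#' exceeding measurement error at 95% confidence.
#'
#' @param test,retest paired numeric vectors.
#' @param icc the ICC(2,1) of the pair (list from [icc_2_1()] or a
#'   number).
#' @param method `"pooled_sd"` (default) or `"ms_error"`.
#' @return List with `sem` and `mdc`.
#' @export
sem_mdc <- function(test, retest, icc, method = c("pooled_sd", "ms_error")) {
  method <- match.arg(method)
  if (is.list(icc)) icc <- icc$icc
  if (method == "pooled_sd") {
    sem <- sd(c(test, retest)) * sqrt(max(1 - icc, 0))
  } else {
    full <- icc_2_1(test, retest)
    sem <- sqrt(full$mse)
  }
  list(sem = sem, mdc = 1.96 * sqrt(2) * sem)
}

#' Reliability category of an ICC value
#'
#' Cut points 0.5 / 0.75 / 0.9: below 0.5 poor, 0.5-0.75 moderate,
#' 0.75-0.9 good, 0.9 and above excellent.
#'
#' @param icc numeric vector of ICC values.
#' @return Character vector of categories.
#' @export
icc_category <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Independent two-sample t-test
#'
#' Two-sided pooled-variance t-test (df = n_a + n_b - 2) by default;
#' `welch = TRUE` switches to the Welch unequal-variance form.
#'
#' @param a,b numeric vectors.
#' @param welch logical.
#' @return List with `t`, `df`, `p`.
#' @export
independent_t <- function(a, b, welch = FALSE) {
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Hedges' g standardized mean difference
#'
#' `g = J * (mean_b - mean_a) / s_p` with the pooled SD
#' `s_p^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2)` and the
#' small-sample correction `J = 1 - 3 / (4(n_a+n_b) - 9)`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summary statistics.
#' @param correction apply the small-sample factor J (default TRUE).
#' @return The signed effect size g.
#' @export
hedges_g <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                     correction = TRUE) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  j <- if (correction) 1 - 3 / (4 * (n_a + n_b) - 9) else 1
  j * (mean_b - mean_a) / sp
}

#' @rdname hedges_g
#' @param a,b raw samples (alternative interface).
#' @export
hedges_g_samples <- function(a, b, correction = TRUE) {
  hedges_g(mean(a), sd(a), length(a), mean(b), sd(b), length(b),
           correction = correction)
}

#' Test-retest reliability table
#'
#' Pairs the test and retest measurements by subject and computes, per
#' feature, the ICC(2,1) with its 95% CI, the SEM, the MDC and the
#' reliability category. Subjects missing either session are dropped.
#'
#' @param test_tbl,retest_tbl analysis tables (one row per measurement,
#'   see [build_analysis_table()]) for the two sessions.
#' @param features feature columns; defaults to all `L*` columns plus
#'   `gait_speed_mps`.
#' @param sem_method passed to [sem_mdc()].
#' @return Data frame of class `reliability_result`: one row per feature
#'   with `icc`, `ci_low`, `ci_high`, `sem`, `mdc`, `n_pairs`,
#'   `category`.
#' @export
reliability_analysis <- function(test_tbl, retest_tbl, features = NULL,
                                 sem_method = "pooled_sd") {
  if (is.null(features)) {
    features <- c(grep("^L[0-9]+$", names(test_tbl), value = TRUE),
                  intersect("gait_speed_mps", names(test_tbl)))
  }
  merged <- merge(test_tbl, retest_tbl, by = "subject_id",
                  suffixes = c("_t", "_r"))
  rows <- lapply(features, function(f) {
    x <- merged[[paste0(f, "_t")]]
    y <- merged[[paste0(f, "_r")]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    res <- icc_2_1(x, y)
    sm <- sem_mdc(x, y, res, method = sem_method)
    data.frame(feature = f, icc = res$icc, ci_low = res$ci_low,
               ci_high = res$ci_high, sem = sm$sem, mdc = sm$mdc,
               n_pairs = res$n, category = icc_category(res$icc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_result", class(out))
  out
}

#' Group comparison (stroke vs healthy)
#'
#' Per feature: group means, SDs, ranges and counts, the independent
#' t-test and Hedges' g (group B minus group A).
#'
#' @param tbl analysis table with a `group` column.
#' @param features feature columns; defaults as in
#'   [reliability_analysis()].
#' @param group_a,group_b the two group labels to compare.
#' @param welch use Welch's t-test.
#' @return Data frame, one row per feature.
#' @export
group_comparison <- function(tbl, features = NULL, group_a = "stroke",
                             group_b = "healthy", welch = FALSE) {
  if (is.null(features)) {
    features <- c(grep("^L[0-9]+$", names(tbl), value = TRUE),
                  intersect("gait_speed_mps", names(tbl)))
  }
  a_rows <- tbl$group == group_a
  b_rows <- tbl$group == group_b
  stopifnot(sum(a_rows) >= 2, sum(b_rows) >= 2)
  rows <- lapply(features, function(f) {
    a <- tbl[[f]][a_rows]; b <- tbl[[f]][b_rows]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    tt <- independent_t(a, b, welch = welch)
    data.frame(
      feature = f,
      mean_a = mean(a), sd_a = sd(a), min_a = min(a), max_a = max(a),
      n_a = length(a),
      mean_b = mean(b), sd_b = sd(b), min_b = min(b), max_b = max(b),
      n_b = length(b),
      t_stat = tt$t, p_value = tt$p,
      hedges_g = hedges_g_samples(a, b),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Individual responsiveness during rehabilitation
#'
#' Classifies every subject's admission-to-discharge change per feature
#' against that feature's minimal detectable change: `increased` when
#' `delta > MDC`, `decreased` when `delta < -MDC`, otherwise `none`
#' (strict inequalities; a change exactly equal to the MDC is not
#' significant). By default only features with good-to-excellent
#' reliability (plus gait speed) are evaluated.
#'
#' @param t0_tbl,tend_tbl analysis tables for the admission and
#'   discharge sessions.
#' @param reliability a `reliability_result` table providing the MDCs.
#' @param reliable_only restrict latent features to those with category
#'   good or excellent.
#' @param features optional explicit feature set (overrides
#'   `reliable_only`).
#' @return List with `per_subject` (long data frame: subject, feature,
#'   delta, change), `per_feature` (counts increased/decreased/none) and
#'   `summary` (subjects changed in any latent feature, in gait speed,
#'   and in both).
#' @export
responsiveness <- function(t0_tbl, tend_tbl, reliability,
                           reliable_only = TRUE, features = NULL) {
  if (is.null(features)) {
    features <- reliability$feature
    if (reliable_only) {
      keep <- reliability$category %in% c("good", "excellent") |
        reliability$feature == "gait_speed_mps"
      features <- reliability$feature[keep]
    }
  }
  merged <- merge(t0_tbl, tend_tbl, by = "subject_id",
                  suffixes = c("_0", "_1"))
  dropped <- setdiff(union(t0_tbl$subject_id, tend_tbl$subject_id),
                     merged$subject_id)
  if (length(dropped)) {
    message(sprintf("responsiveness: %d subject(s) without a complete T0/Tend pair excluded",
                    length(dropped)))
  }
  mdc_of <- setNames(reliability$mdc, reliability$feature)
  rows <- lapply(features, function(f) {
    delta <- merged[[paste0(f, "_1")]] - merged[[paste0(f, "_0")]]
    mdc <- mdc_of[[f]]
    change <- ifelse(delta > mdc, "increased",
                     ifelse(delta < -mdc, "decreased", "none"))
    data.frame(subject_id = merged$subject_id, feature = f, delta = delta,
               mdc = mdc, change = change, stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  per_feature <- do.call(rbind, lapply(split(per_subject, per_subject$feature),
    function(d) data.frame(
      feature = d$feature[1],
      increased = sum(d$change == "increased"),
      decreased = sum(d$change == "decreased"),
      none = sum(d$change == "none"))))
  rownames(per_feature) <- NULL
  latent_feats <- grep("^L[0-9]+$", features, value = TRUE)
  changed_latent <- unique(per_subject$subject_id[
    per_subject$feature %in% latent_feats & per_subject$change != "none"])
  changed_speed <- unique(per_subject$subject_id[
    per_subject$feature == "gait_speed_mps" & per_subject$change != "none"])
  summary <- list(
    n_subjects = nrow(merged),
    changed_any_latent = length(changed_latent),
    changed_gait_speed = length(changed_speed),
    changed_both = length(intersect(changed_latent, changed_speed)),
    changed_any = length(union(changed_latent, changed_speed)))
  list(per_subject = per_subject, per_feature = per_feature,
       summary = summary)
}
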