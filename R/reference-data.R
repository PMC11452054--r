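#' Published reference summary statistics
#'
#' Summary tables from a published clinical stroke-rehabilitation 2MWT
#' cohort (12 latent gait features plus gait speed), bundled as inputs
#' for closed-form checks and worked examples:
#'
#' * `"groups"` — per-feature test-retest reliability (ICC with 95% CI,
#'   SEM, MDC) and stroke vs healthy group summaries (mean, SD, n,
#'   t-statistic, printed effect size).
#' * `"counts"` — epoch bookkeeping counts (epochs segmented/kept, kept
#'   from the stroke group, number of measurements, epoch geometry).
#'
#' The raw recordings behind these numbers are not distributed; the
#' tables carry only the printed summary statistics.
#'
#' @param which `"groups"` or `"counts"`.
#' @return A data frame.
#' @export
load_reference_summary <- function(which = c("groups", "counts")) {
  which <- match.arg(which)
  f <- switch(which,
              groups = "reference_group_summary.csv",
              counts = "reference_epoch_counts.csv")
  read.csv(system.file("extdata", f, package = "gaitlatent",
                       mustWork = TRUE))
}
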