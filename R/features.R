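#' Aggregate epoch-level latent scores to measurement level
#'
#' One two-minute walk test yields many epochs per foot; the
#' measurement-level feature is the arithmetic mean of each latent
#' dimension over the (non-outlier) epochs, per measurement and foot.
#'
#' @param scores data frame with columns `measurement_id`, `foot`, the
#'   latent columns `L0 ... L<k-1>`, and optionally `subject_id`,
#'   `group`, `session`, `uses_aid` (carried through).
#' @return Data frame, one row per measurement x foot, with the averaged
#'   latent columns and `n_epochs_used`.
#' @export
aggregate_features <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("measurement_id", "foot") %in% names(scores)))
  lcols <- grep("^L[0-9]+$", names(scores), value = TRUE)
  stopifnot(length(lcols) >= 1)
  meta_cols <- intersect(c("subject_id", "group", "session", "uses_aid"),
                         names(scores))
  key <- interaction(scores$measurement_id, scores$foot, drop = TRUE)
  idx <- split(seq_len(nrow(scores)), key)
  rows <- lapply(idx, function(ii) {
    first <- scores[ii[1], c("measurement_id", "foot", meta_cols),
                    drop = FALSE]
    means <- colMeans(scores[ii, lcols, drop = FALSE])
    cbind(first, as.data.frame(as.list(means)),
          n_epochs_used = length(ii))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$measurement_id, out$foot), , drop = FALSE]
}

#' Join aggregated features with gait speed into the analysis table
#'
#' Selects one foot's averaged latent scores per measurement (the right
#' foot by convention) and joins the per-measurement gait speed.
#'
#' @param features output of [aggregate_features()].
#' @param speeds data frame from [compute_speeds()] (`measurement_id`,
#'   `gait_speed_mps`).
#' @param foot which foot's latent scores to use.
#' @return Data frame, one row per measurement: metadata, `L*` columns,
#'   `gait_speed_mps`.
#' @export
build_analysis_table <- function(features, speeds, foot = c("right", "left")) {
  foot <- match.arg(foot)
  tbl <- features[features$foot == foot, , drop = FALSE]
  out <- merge(tbl, speeds[, c("measurement_id", "gait_speed_mps")],
               by = "measurement_id", all.x = TRUE)
  out[order(out$measurement_id), , drop = FALSE]
}

#' Z-normalize feature columns against a reference group
#'
#' Centers and scales each feature by the mean and SD computed on the
#' reference group (used for distribution plots and cross-group
#' comparisons on a common scale). Scores of the non-reference group
#' need not be mean-zero afterwards.
#'
#' @param tbl analysis table with a `group` column.
#' @param reference `"stroke"` (normalize against the stroke group) or
#'   `"all"`.
#' @param features character vector of columns to normalize; defaults
#'   to all `L*` columns plus `gait_speed_mps` when present.
#' @return `tbl` with the selected columns z-normalized.
#' @export
znormalize_features <- function(tbl, reference = c("stroke", "all"),
                                features = NULL) {
  reference <- match.arg(reference)
  if (is.null(features)) {
    features <- c(grep("^L[0-9]+$", names(tbl), value = TRUE),
                  intersect("gait_speed_mps", names(tbl)))
  }
  ref_rows <- if (reference == "all") rep(TRUE, nrow(tbl))
              else tbl$group == reference
  stopifnot(any(ref_rows))
  for (f in features) {
    m <- mean(tbl[[f]][ref_rows])
    s <- sd(tbl[[f]][ref_rows])
    if (!is.finite(s) || s == 0) stop(sprintf("zero variance in '%s'", f))
    tbl[[f]] <- (tbl[[f]] - m) / s
  }
  tbl
}
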