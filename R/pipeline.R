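#' Default pipeline configuration
#'
#' Nested configuration for [run_stage()]. Every key shown here is the
#' complete schema: unknown keys anywhere in a supplied config are
#' rejected. A single global seed fans out to per-stage seeds by fixed
#' offsets, so stages are independently reproducible.
#'
#' @param outdir artifact directory.
#' @param seed global integer seed.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "gaitlatent-run", seed = 1) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    cohort = list(n_stroke = 10, n_healthy = 10,
                  sessions = c("test", "retest", "T0", "Tend"),
                  duration = 120, fs = 104),
    preprocessing = list(zero_phase = FALSE, filter_scope = "epoch",
                         z_thresh = 5),
    vae = list(filters = c(16, 32, 64), latent_dim = 12, kernel_size = 3,
               batch_size = 64, max_epochs = 30, early_stop_patience = 10,
               learning_rate = 0.001, train_frac = 0.85),
    stats = list(foot = "right", reliable_only = TRUE)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [pipeline_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(pipeline_config())
  merge_into <- function(base, new, where) {
    for (nm in names(new)) {
      if (!nm %in% names(base)) {
        stop(sprintf("unknown config key '%s' at %s", nm, where))
      }
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]],
                                 paste0(where, "$", nm))
      } else {
        base[[nm]] <- if (is.list(new[[nm]])) unlist(new[[nm]]) else new[[nm]]
      }
    }
    base
  }
  out <- merge_into(cfg, user, "config")
  class(out) <- "pipeline_config"
  validate_pipeline_config(out)
  out
}

#' Validate a pipeline configuration
#'
#' Checks the schema (unknown keys anywhere are rejected) and basic
#' value constraints. Called automatically by [run_stage()].
#'
#' @param config a `pipeline_config`.
#' @return The config, invisibly; errors on violation.
#' @export
validate_pipeline_config <- function(config) {
  tmpl <- unclass(pipeline_config())
  stopifnot(identical(sort(names(config)), sort(names(tmpl))))
  for (nm in c("cohort", "preprocessing", "vae", "stats")) {
    extra <- setdiff(names(config[[nm]]), names(tmpl[[nm]]))
    if (length(extra)) {
      stop(sprintf("unknown config key(s) in %s: %s", nm,
                   paste(extra, collapse = ", ")))
    }
  }
  stopifnot(config$cohort$fs > 20, config$cohort$duration >= 10,
            config$vae$latent_dim >= 1,
            config$stats$foot %in% c("right", "left"))
  invisible(config)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

write_stage_manifest <- function(stage, config, inputs, outputs) {
  man <- list(stage = stage, seed = config$seed,
              config_hash = config_hash(config),
              package_version = as.character(utils::packageVersion("gaitlatent")),
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(man,
                       file.path(config$outdir,
                                 sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE)
  invisible(man)
}

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact for stage '%s': %s",
                 stage, basename(path)), call. = FALSE)
  }
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to CSV/JSON), `preprocess`
#' (epoch segmentation, outlier screening, normalization), `speed`
#' (per-measurement ZUPT gait speed), `train` (VAE on the stroke
#' epochs, participant-level train/test split), `encode` (latent scores
#' per epoch), `aggregate` (measurement-level features), `stats`
#' (reliability, group comparison, responsiveness), or `all`. Each
#' stage reads its inputs from, and writes its outputs and a manifest
#' (input/output hashes, config hash, seed) to, `config$outdir`.
#'
#' @param stage stage name.
#' @param config a `pipeline_config`.
#' @param verbose print progress.
#' @return Invisibly, a list of the stage's main outputs.
#' @export
run_stage <- function(stage = c("all", "simulate", "preprocess", "speed",
                                "train", "encode", "aggregate", "stats"),
                      config = pipeline_config(), verbose = FALSE) {
  stage <- match.arg(stage)
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    for (s in c("simulate", "preprocess", "speed", "train", "encode",
                "aggregate", "stats")) {
      run_stage(s, config, verbose = verbose)
    }
    return(invisible(config$outdir))
  }
  say <- function(...) if (verbose) message(sprintf(...))
  out <- switch(stage,
    simulate = {
      spec <- cohort_spec(
        n_stroke = config$cohort$n_stroke,
        n_healthy = config$cohort$n_healthy,
        sessions = config$cohort$sessions,
        duration = config$cohort$duration, fs = config$cohort$fs,
        seed = config$seed + 1L)
      cohort <- simulate_cohort(spec)
      cdir <- file.path(config$outdir, "cohort")
      write_cohort(cohort, cdir)
      say("simulate: %d measurements", nrow(cohort$manifest))
      write_stage_manifest("simulate", config, character(0),
                           file.path(cdir, "manifest.csv"))
      cdir
    },
    preprocess = {
      cdir <- need_artifact(file.path(config$outdir, "cohort", "manifest.csv"),
                            stage)
      cohort <- read_cohort(dirname(cdir))
      all_epochs <- list()
      for (m in cohort$measurements) {
        for (foot in c("left", "right")) {
          eps <- preprocess_measurement(
            m[[foot]], gyro_offset = m$meta$gyro_offset_dps,
            zero_phase = config$preprocessing$zero_phase,
            filter_scope = config$preprocessing$filter_scope)
          all_epochs <- c(all_epochs, eps)
        }
      }
      n_meas <- length(cohort$measurements)
      prep <- prepare_epoch_set(all_epochs,
                                z_thresh = config$preprocessing$z_thresh)
      kept_by_group <- table(prep$manifest$group)
      book <- epoch_bookkeeping(length(all_epochs), n_meas,
                                length(prep$epochs), c(kept_by_group))
      arr <- array(0, c(length(prep$epochs), EPOCH_LEN, 6))
      for (i in seq_along(prep$epochs)) arr[i, , ] <- prep$epochs[[i]]$data
      obj <- list(array = arr, manifest = prep$manifest,
                  bookkeeping = book)
      saveRDS(obj, file.path(config$outdir, "epochs.rds"))
      write.csv(prep$manifest, file.path(config$outdir, "epoch_manifest.csv"),
                row.names = FALSE)
      say("preprocess: %d epochs kept (%d removed), %.1f per measurement",
          length(prep$epochs), length(prep$removed),
          book$epochs_per_measurement / 2)
      write_stage_manifest("preprocess", config, cdir,
                           file.path(config$outdir,
                                     c("epochs.rds", "epoch_manifest.csv")))
      obj
    },
    speed = {
      cdir <- need_artifact(file.path(config$outdir, "cohort", "manifest.csv"),
                            stage)
      cohort <- read_cohort(dirname(cdir))
      speeds <- compute_speeds(cohort, foot = config$stats$foot)
      write.csv(speeds, file.path(config$outdir, "speeds.csv"),
                row.names = FALSE)
      say("speed: %d measurements", nrow(speeds))
      write_stage_manifest("speed", config, cdir,
                           file.path(config$outdir, "speeds.csv"))
      speeds
    },
    train = {
      ep_path <- need_artifact(file.path(config$outdir, "epochs.rds"), stage)
      obj <- readRDS(ep_path)
      stroke_idx <- which(obj$manifest$group == "stroke")
      if (!length(stroke_idx)) stop("no stroke epochs to train on")
      subj <- obj$manifest$subject_id[stroke_idx]
      subjects <- unique(subj)
      set.seed(config$seed + 4L)
      shuffled <- sample(subjects)
      n_train <- max(1, round(length(subjects) * config$vae$train_frac))
      train_sub <- shuffled[seq_len(n_train)]
      tr_idx <- stroke_idx[subj %in% train_sub]
      te_idx <- setdiff(stroke_idx, tr_idx)
      cfg <- vae_config(
        filters = config$vae$filters, latent_dim = config$vae$latent_dim,
        kernel_size = config$vae$kernel_size,
        batch_size = config$vae$batch_size,
        max_epochs = config$vae$max_epochs,
        early_stop_patience = config$vae$early_stop_patience,
        learning_rate = config$vae$learning_rate,
        seed = config$seed + 4L)
      model <- build_vae(cfg)
      model <- train_vae(model,
                         obj$array[tr_idx, , , drop = FALSE],
                         if (length(te_idx)) obj$array[te_idx, , , drop = FALSE],
                         verbose = verbose)
      save_vae(model, file.path(config$outdir, "vae_model.rds"))
      jsonlite::write_json(
        list(best_epoch = model$report$best_epoch,
             n_train_epochs = length(tr_idx), n_test_epochs = length(te_idx),
             history = model$report$history),
        file.path(config$outdir, "train_report.json"), dataframe = "columns",
        auto_unbox = TRUE, digits = NA)
      say("train: best epoch %d (%d train / %d test epochs)",
          model$report$best_epoch, length(tr_idx), length(te_idx))
      write_stage_manifest("train", config, ep_path,
                           file.path(config$outdir,
                                     c("vae_model.rds", "train_report.json")))
      model
    },
    encode = {
      ep_path <- need_artifact(file.path(config$outdir, "epochs.rds"), stage)
      mod_path <- need_artifact(file.path(config$outdir, "vae_model.rds"),
                                stage)
      obj <- readRDS(ep_path)
      model <- load_vae(mod_path)
      code <- vae_encode(model, obj$array)
      scores <- cbind(obj$manifest, as.data.frame(code$score))
      write.csv(scores, file.path(config$outdir, "scores.csv"),
                row.names = FALSE)
      say("encode: %d epochs scored", nrow(scores))
      write_stage_manifest("encode", config, c(ep_path, mod_path),
                           file.path(config$outdir, "scores.csv"))
      scores
    },
    aggregate = {
      sc_path <- need_artifact(file.path(config$outdir, "scores.csv"), stage)
      sp_path <- need_artifact(file.path(config$outdir, "speeds.csv"), stage)
      scores <- read.csv(sc_path)
      speeds <- read.csv(sp_path)
      feats <- aggregate_features(scores)
      feats <- merge(feats, speeds[, c("measurement_id", "gait_speed_mps")],
                     by = "measurement_id", all.x = TRUE)
      feats <- feats[order(feats$measurement_id, feats$foot), ]
      write.csv(feats, file.path(config$outdir, "features.csv"),
                row.names = FALSE)
      say("aggregate: %d measurement x foot rows", nrow(feats))
      write_stage_manifest("aggregate", config, c(sc_path, sp_path),
                           file.path(config$outdir, "features.csv"))
      feats
    },
    stats = {
      ft_path <- need_artifact(file.path(config$outdir, "features.csv"),
                               stage)
      feats <- read.csv(ft_path)
      tbl <- feats[feats$foot == config$stats$foot, , drop = FALSE]
      sessions <- unique(tbl$session)
      outputs <- character(0)
      rel <- NULL
      if (all(c("test", "retest") %in% sessions)) {
        rel <- reliability_analysis(tbl[tbl$session == "test", ],
                                    tbl[tbl$session == "retest", ])
        write.csv(rel, file.path(config$outdir, "reliability.csv"),
                  row.names = FALSE)
        outputs <- c(outputs, "reliability.csv")
      }
      if (length(unique(tbl$group)) == 2) {
        comp_sessions <- if ("test" %in% sessions) "test" else sessions[1]
        comp <- group_comparison(tbl[tbl$session %in% comp_sessions, ])
        write.csv(comp, file.path(config$outdir, "group_comparison.csv"),
                  row.names = FALSE)
        outputs <- c(outputs, "group_comparison.csv")
      }
      summary <- list()
      if (!is.null(rel) && all(c("T0", "Tend") %in% sessions)) {
        resp <- responsiveness(tbl[tbl$session == "T0", ],
                               tbl[tbl$session == "Tend", ], rel,
                               reliable_only = config$stats$reliable_only)
        write.csv(resp$per_feature,
                  file.path(config$outdir, "responsiveness.csv"),
                  row.names = FALSE)
        outputs <- c(outputs, "responsiveness.csv")
        summary <- resp$summary
      }
      jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      say("stats: wrote %s", paste(outputs, collapse = ", "))
      write_stage_manifest("stats", config, ft_path,
                           file.path(config$outdir, c(outputs, "summary.json")))
      outputs
    })
  invisible(out)
}

#' Run the full pipeline
#'
#' Equivalent to `run_stage("all", config)`.
#'
#' @inheritParams run_stage
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  run_stage("all", config, verbose = verbose)
}
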