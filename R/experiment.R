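## Experiment orchestration ----------------------------------------------------
##
## One config drives the whole pipeline: simulate -> preprocess -> split ->
## pretrain -> train -> evaluate -> cka. Each stage writes its artifacts under
## the output directory and can be rerun independently; a manifest records the
## config hash and the per-stage seeds (one global seed fans out by fixed
## offsets). All stage outputs are deterministic given the config.

#' Experiment configuration
#'
#' @param cohort a [cohort_spec()].
#' @param preprocess a [preprocess_config()].
#' @param split a [split_config()].
#' @param model a [model_config()].
#' @param mask a [mask_spec()].
#' @param pretrain a [pretrain_config()].
#' @param train a [train_config()].
#' @param noise a [noise_spec()] or `NULL`.
#' @param task one task id, or `"aggregate"` to pool segments across all
#'   tasks before splitting.
#' @param seed global seed; fans out to per-stage seeds by fixed offsets.
#' @param epochs_scale multiplier applied to every epoch count (desk-scale
#'   runs use values < 1).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              preprocess = preprocess_config(),
                              split = split_config(),
                              model = model_config(),
                              mask = mask_spec(),
                              pretrain = pretrain_config(),
                              train = train_config(),
                              noise = noise_spec(),
                              task = "aggregate", seed = 1L,
                              epochs_scale = 1) {
  if (!task %in% c(TASKS, "aggregate"))
    stopf("`task` must be one of %s or 'aggregate'",
          paste(TASKS, collapse = ", "))
  if (epochs_scale <= 0) stopf("`epochs_scale` must be positive")
  cohort$seed <- derive_seed(seed, "simulate")
  split$seed <- derive_seed(seed, "split")
  model$seed <- derive_seed(seed, "model")
  pretrain$seed <- derive_seed(seed, "pretrain")
  train$seed <- derive_seed(seed, "train")
  if (!is.null(noise)) noise$seed <- derive_seed(seed, "noise")
  pretrain$epochs <- max(1L, as.integer(round(pretrain$epochs * epochs_scale)))
  train$epochs_all <- max(1L, as.integer(round(train$epochs_all * epochs_scale)))
  train$epochs_head <- max(1L, as.integer(round(train$epochs_head * epochs_scale)))
  structure(list(cohort = cohort, preprocess = preprocess, split = split,
                 model = model, mask = mask, pretrain = pretrain,
                 train = train, noise = noise, task = task,
                 seed = as.integer(seed), epochs_scale = epochs_scale),
            class = "experiment_config")
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

log_stage <- function(out_dir, stage, msg) {
  line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = stage_file(out_dir, "experiment.log"),
      append = TRUE)
  message(line)
}

config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "noise")]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

require_artifact <- function(out_dir, file, needed_by, produced_by) {
  path <- stage_file(out_dir, file)
  if (!file.exists(path))
    stopf("stage '%s' needs %s: run stage '%s' first",
          needed_by, file, produced_by)
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages are idempotent: rerunning with the same config overwrites the same
#' artifacts with identical content. Downstream stages error with the name of
#' the stage to run first when an upstream artifact is missing.
#'
#' @param stage one of `"simulate"`, `"preprocess"`, `"split"`, `"pretrain"`,
#'   `"train"`, `"evaluate"`, `"cka"`, `"all"`.
#' @param config an [experiment_config()].
#' @param out_dir output directory for artifacts, logs and the manifest.
#' @return The stage's main artifact, invisibly.
#' @export
run_stage <- function(stage = c("all", "simulate", "preprocess", "split",
                                "pretrain", "train", "evaluate", "cka"),
                      config, out_dir) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   task = config$task,
                   stage_seeds = list(simulate = config$cohort$seed,
                                      split = config$split$seed,
                                      pretrain = config$pretrain$seed,
                                      train = config$train$seed))
  jsonlite::write_json(manifest, stage_file(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (stage == "all") {
    for (s in c("simulate", "preprocess", "split", "pretrain", "train",
                "evaluate", "cka"))
      run_stage(s, config, out_dir)
    return(invisible(out_dir))
  }
  switch(stage,
    simulate = {
      log_stage(out_dir, stage, "generating synthetic cohort")
      cohort <- generate_cohort(config$cohort)
      write_cohort_csv(cohort, stage_file(out_dir, "recordings"))
      saveRDS(cohort, stage_file(out_dir, "cohort.rds"))
      log_stage(out_dir, stage, sprintf("%d recordings written",
                                        nrow(cohort$manifest)))
      invisible(cohort)
    },
    preprocess = {
      path <- require_artifact(out_dir, "cohort.rds", stage, "simulate")
      cohort <- readRDS(path)
      tasks <- if (config$task == "aggregate") NULL else config$task
      segments <- preprocess_cohort(cohort, config$preprocess, tasks)
      saveRDS(segments, stage_file(out_dir, "segments.rds"))
      write_segment_index(segments, stage_file(out_dir, "segment_index.csv"))
      log_stage(out_dir, stage, sprintf("%d segments from %d groups",
                                        nrow(segments$meta),
                                        length(unique(segments$meta$group_id))))
      invisible(segments)
    },
    split = {
      path <- require_artifact(out_dir, "segments.rds", stage, "preprocess")
      segments <- readRDS(path)
      splits <- make_splits(segments, config$split)
      saveRDS(splits, stage_file(out_dir, "splits.rds"))
      g <- segment_groups(segments)
      for (i in seq_along(splits))
        write_split_manifest(splits[[i]], g,
                             stage_file(out_dir, sprintf("split_fold%d.csv", i)),
                             seed = config$split$seed)
      log_stage(out_dir, stage, sprintf("%d folds over %d groups",
                                        length(splits), nrow(g)))
      invisible(splits)
    },
    pretrain = {
      segments <- readRDS(require_artifact(out_dir, "segments.rds", stage,
                                           "preprocess"))
      splits <- readRDS(require_artifact(out_dir, "splits.rds", stage,
                                         "split"))
      weights <- pretrain_weight_sets(segments, splits, config$model,
                                      config$mask, config$pretrain)
      saveRDS(weights, stage_file(out_dir, "pretrained_weights.rds"))
      hist <- do.call(rbind, lapply(seq_along(weights), function(i)
        do.call(rbind, lapply(weights[[i]], function(w) {
          h <- w$history
          h$tag <- w$tag
          h
        }))))
      jsonlite::write_json(hist, stage_file(out_dir, "pretrain_report.json"),
                           dataframe = "rows", digits = NA)
      log_stage(out_dir, stage, sprintf("%d weight sets", 2L * length(weights)))
      invisible(weights)
    },
    train = {
      segments <- readRDS(require_artifact(out_dir, "segments.rds", stage,
                                           "preprocess"))
      splits <- readRDS(require_artifact(out_dir, "splits.rds", stage,
                                         "split"))
      weights <- readRDS(require_artifact(out_dir, "pretrained_weights.rds",
                                          stage, "pretrain"))
      fits <- lapply(seq_along(splits), function(i)
        train_fold_variants(i, splits[[i]], segments, weights[[i]],
                            config$model, config$train))
      saveRDS(fits, stage_file(out_dir, "fits.rds"))
      logs <- do.call(rbind, lapply(unlist(fits, recursive = FALSE),
                                    function(f) {
        lg <- f$log
        lg$variant_id <- f$variant$variant_id
        lg
      }))
      write.csv(logs, stage_file(out_dir, "training_log.csv"),
                row.names = FALSE)
      log_stage(out_dir, stage,
                sprintf("%d models trained", sum(lengths(fits))))
      invisible(fits)
    },
    evaluate = {
      segments <- readRDS(require_artifact(out_dir, "segments.rds", stage,
                                           "preprocess"))
      splits <- readRDS(require_artifact(out_dir, "splits.rds", stage,
                                         "split"))
      fits <- readRDS(require_artifact(out_dir, "fits.rds", stage, "train"))
      report <- evaluation_report(fits, segments, splits, config$noise)
      write.csv(report, stage_file(out_dir, "evaluation.csv"),
                row.names = FALSE)
      aggs <- rbind(aggregate_by_attribute(report, "train_set"),
                    aggregate_by_attribute(report, "init"))
      write.csv(aggs, stage_file(out_dir, "evaluation_by_attribute.csv"),
                row.names = FALSE)
      jsonlite::write_json(list(per_model = report, by_attribute = aggs),
                           stage_file(out_dir, "evaluation.json"),
                           dataframe = "rows", digits = NA)
      log_stage(out_dir, stage, sprintf("%d model evaluations", nrow(report)))
      invisible(report)
    },
    cka = {
      segments <- readRDS(require_artifact(out_dir, "segments.rds", stage,
                                           "preprocess"))
      splits <- readRDS(require_artifact(out_dir, "splits.rds", stage,
                                         "split"))
      fits <- readRDS(require_artifact(out_dir, "fits.rds", stage, "train"))
      tables <- cka_tables(fits, segments, splits)
      write.csv(tables, stage_file(out_dir, "cka.csv"), row.names = FALSE)
      log_stage(out_dir, stage, sprintf("%d CKA cells", nrow(tables)))
      invisible(tables)
    })
}

#' Run the full experiment
#'
#' Convenience wrapper for `run_stage("all", config, out_dir)`.
#'
#' @inheritParams run_stage
#' @return `out_dir`, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  run_stage("all", config, out_dir)
}
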