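#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: a working directory for
#' artifacts, one explicit seed per stochastic stage, and the parameter
#' blocks of each stage. The configuration round-trips through YAML
#' unchanged (`write_run_config()` / `read_run_config()`).
#'
#' @param workdir directory where stage artifacts are written.
#' @param seeds named list with integer `simulate`, `augment`, `train`.
#' @param study_config a `study_config` (default [default_study_config()]).
#' @param dynamics a [dynamics_params()].
#' @param n_samples,sd_shrink augmentation settings (see [build_dataset()]).
#' @param model a [model_config()]; the pipeline default reduces epochs to
#'   500 so the standard run completes quickly, the full-length schedule
#'   being one `model_config(epochs = 5000)` away.
#' @param crossval list with `n_repeats`, `n_holdout_groups`.
#' @param map_pairs list of 2-element character vectors: group-id pairs to
#'   difference in the interpret stage.
#' @param sweeps named list of [sweep_spec()]s for the sweep stage.
#' @return A `run_config` list.
#' @export
run_config <- function(workdir = "pulsim_run",
                       seeds = list(simulate = 11L, augment = 22L,
                                    train = 33L),
                       study_config = default_study_config(),
                       dynamics = dynamics_params(),
                       n_samples = 50L, sd_shrink = 5,
                       model = model_config(epochs = 500L),
                       crossval = list(n_repeats = 5L,
                                       n_holdout_groups = 2L),
                       map_pairs = list(c("group_03", "group_01"),
                                        c("group_04", "group_03")),
                       sweeps = NULL) {
  for (s in c("simulate", "augment", "train")) {
    stop_if_not_count(seeds[[s]], paste0("seeds$", s), min = 0L)
  }
  if (is.null(sweeps)) {
    sweeps <- list(
      case1 = sweep_spec(data.frame(step = c(3, 13), dose_gy = c(10, 10))),
      case2 = sweep_spec(data.frame(step = c(3, 13), dose_gy = c(20, 20))),
      case3 = sweep_spec(data.frame(step = 3, dose_gy = 40))
    )
  }
  structure(list(workdir = workdir, seeds = seeds,
                 study_config = study_config, dynamics = dynamics,
                 n_samples = n_samples, sd_shrink = sd_shrink,
                 model = model, crossval = crossval,
                 map_pairs = map_pairs, sweeps = sweeps),
            class = "run_config")
}

artifact_paths <- function(config) {
  wd <- config$workdir
  list(summaries = file.path(wd, "group_summaries.csv"),
       schedules = file.path(wd, "schedules.json"),
       dataset = file.path(wd, "dataset.rds"),
       checkpoint = file.path(wd, "checkpoint.rds"),
       metrics = file.path(wd, "training_metrics.csv"),
       crossval = file.path(wd, "crossval.csv"),
       regions = file.path(wd, "region_summaries.csv"),
       sweep = file.path(wd, "sweep.csv"),
       manifest = file.path(wd, "manifest.json"))
}

need_artifact <- function(path, producer_stage) {
  if (!file.exists(path)) {
    stop(sprintf(
      "missing upstream artifact '%s'; run stage '%s' first",
      path, producer_stage), call. = FALSE)
  }
  invisible(path)
}

#' Run the pipeline end-to-end (or stage by stage)
#'
#' Stages and their artifacts, all under `config$workdir`:
#' \describe{
#'   \item{simulate}{synthetic study -> `group_summaries.csv`,
#'     `schedules.json`}
#'   \item{augment}{encoded dataset -> `dataset.rds`}
#'   \item{train}{trained surrogate -> `checkpoint.rds`,
#'     `training_metrics.csv`}
#'   \item{crossval}{leave-groups-out folds -> `crossval.csv`}
#'   \item{interpret}{difference-map region statistics for the configured
#'     group pairs -> `region_summaries.csv`}
#'   \item{sweep}{AVC offset sweeps -> `sweep.csv`}
#' }
#' Later stages read earlier artifacts from disk, so a run is resumable;
#' a missing upstream artifact raises an error naming the stage to rerun.
#' Every stage appends a manifest entry (stage, seed, input/output files
#' with MD5 hashes) to `manifest.json`.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate", "augment", "train", "crossval", "interpret", "sweep")`.
#' @return the manifest (list of stage entries), invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "augment", "train",
                                    "crossval", "interpret", "sweep")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "augment", "train", "crossval", "interpret",
                  "sweep")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(config)

  manifest <- if (file.exists(paths$manifest)) {
    jsonlite::read_json(paths$manifest)
  } else list()
  note <- function(stage, seed, ins, outs) {
    entry <- list(
      stage = stage, seed = seed,
      inputs = as.list(tools::md5sum(ins)),
      outputs = as.list(tools::md5sum(outs)))
    manifest[[stage]] <<- entry
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  for (stage in stages) {
    message("pulsim: running stage '", stage, "'")
    switch(stage,
      simulate = {
        study <- generate_study(config$study_config, config$dynamics,
                                seed = config$seeds$simulate)
        write_study(study, config$workdir)
        note(stage, config$seeds$simulate, character(0),
             c(paths$summaries, paths$schedules))
      },
      augment = {
        need_artifact(paths$summaries, "simulate")
        need_artifact(paths$schedules, "simulate")
        study <- read_study(config$workdir)
        dataset <- build_dataset(study, n_samples = config$n_samples,
                                 sd_shrink = config$sd_shrink,
                                 seed = config$seeds$augment)
        saveRDS(dataset, paths$dataset)
        note(stage, config$seeds$augment,
             c(paths$summaries, paths$schedules), paths$dataset)
      },
      train = {
        need_artifact(paths$dataset, "augment")
        dataset <- readRDS(paths$dataset)
        cfg <- config$model
        cfg$seed <- config$seeds$train
        res <- train(dataset, cfg)
        saveRDS(res, paths$checkpoint)
        utils::write.csv(
          data.frame(epoch = seq_along(res$train_loss),
                     train_loss = num_chr(res$train_loss),
                     val_loss = num_chr(res$val_loss)),
          paths$metrics, row.names = FALSE, quote = FALSE)
        note(stage, config$seeds$train, paths$dataset,
             c(paths$checkpoint, paths$metrics))
      },
      crossval = {
        need_artifact(paths$dataset, "augment")
        dataset <- readRDS(paths$dataset)
        cfg <- config$model
        cfg$seed <- config$seeds$train
        folds <- crossvalidate(dataset,
                               n_repeats = config$crossval$n_repeats,
                               n_holdout_groups = config$crossval$n_holdout_groups,
                               config = cfg)
        utils::write.csv(
          data.frame(
            fold = seq_along(folds),
            holdout_groups = vapply(folds, function(f)
              paste(f$holdout_group_ids, collapse = "+"), character(1)),
            holdout_loss = num_chr(vapply(folds, `[[`, numeric(1),
                                          "holdout_loss"))),
          paths$crossval, row.names = FALSE, quote = FALSE)
        note(stage, config$seeds$train, paths$dataset, paths$crossval)
      },
      interpret = {
        need_artifact(paths$checkpoint, "train")
        need_artifact(paths$schedules, "simulate")
        model <- readRDS(paths$checkpoint)$model
        study <- read_study(config$workdir)
        sched_of <- function(id) {
          for (g in study$groups) if (g$group_id == id) return(g$schedule)
          stop(sprintf("group '%s' not found in study", id), call. = FALSE)
        }
        regions <- if (model$config$hidden_units >= 100)
          default_regions()
        else  # scale the conventional 100-unit regions to the actual width
          lapply(default_regions(), function(r) {
            f <- model$config$hidden_units / 100
            region_spec(r$name,
                        unique(pmax(1L, as.integer(round(r$rows * f)))))
          })
        rows <- lapply(config$map_pairs, function(pr) {
          ma <- extract_hidden_map(model, encode_inputs(
            sched_of(pr[1]), model$lq$alpha, model$lq$beta,
            model$lq$encoding))
          mb <- extract_hidden_map(model, encode_inputs(
            sched_of(pr[2]), model$lq$alpha, model$lq$beta,
            model$lq$encoding))
          rs <- region_summary(difference_map(ma, mb), regions)
          cbind(pair = paste(pr[1], "-", pr[2]), rs)
        })
        out <- do.call(rbind, rows)
        out$mean <- num_chr(out$mean)
        out$fraction_positive <- num_chr(out$fraction_positive)
        utils::write.csv(out, paths$regions, row.names = FALSE,
                         quote = FALSE)
        note(stage, NA, c(paths$checkpoint, paths$schedules),
             paths$regions)
      },
      sweep = {
        need_artifact(paths$checkpoint, "train")
        model <- readRDS(paths$checkpoint)$model
        rows <- lapply(names(config$sweeps), function(nm) {
          tab <- suppressWarnings(sweep_offsets(model, config$sweeps[[nm]]))
          cbind(case = nm, tab)
        })
        out <- do.call(rbind, rows)
        out$avc_mm3 <- num_chr(out$avc_mm3)
        utils::write.csv(out, paths$sweep, row.names = FALSE, quote = FALSE)
        note(stage, NA, paths$checkpoint, paths$sweep)
      })
  }
  invisible(manifest)
}

#' @rdname run_config
#' @param config a `run_config` to serialize.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path)
  invisible(path)
}

serialize_config <- function(config) {
  list(workdir = config$workdir, seeds = config$seeds,
       n_samples = config$n_samples, sd_shrink = config$sd_shrink,
       dynamics = unclass(config$dynamics),
       model = unclass(config$model),
       crossval = config$crossval)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(workdir = y$workdir, seeds = y$seeds,
             dynamics = do.call(dynamics_params, y$dynamics),
             n_samples = y$n_samples, sd_shrink = y$sd_shrink,
             model = do.call(model_config, y$model),
             crossval = y$crossval)
}
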