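#' Default pipeline configuration
#'
#' Returns the fully resolved configuration consumed by [run_pipeline()]:
#' phantom generation, preprocessing, patch extraction, section splitting,
#' training protocol and modality list. Values can be overridden via a YAML
#' file ([load_pipeline_config()]) or by modifying the returned list; it is
#' validated again before any stage runs. Seeds propagate hierarchically:
#' the global `seed` derives the per-section phantom seeds and the split and
#' training seeds.
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir = "dfirseg-run", seed = 0L) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    n_sections = 12L,
    phantom = list(image_height_px = 1024L, image_width_px = 1024L),
    preprocess = list(clip_max = 3, mask_method = "otsu", register = TRUE),
    patch = list(patch_size = 256L, min_tissue_frac = 0.5),
    split = list(train = 8L, val = 2L, test = 2L),
    train = list(backbone = "reduced", max_epochs = 10L, n_replicates = 3L,
                 batch_size = 8L),
    modalities = "COMBINED",
    log_level = "info"
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys override the defaults of
#' [default_pipeline_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @param out_dir,seed defaults if absent from the file.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path, out_dir = "dfirseg-run", seed = 0L) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_pipeline_config(out_dir = out_dir, seed = seed))
  for (k in names(user)) {
    if (!k %in% names(cfg))
      stop_param("unknown configuration key: %s", k)
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.list(cfg))
  required <- c("out_dir", "seed", "n_sections", "phantom", "preprocess",
                "patch", "split", "train", "modalities")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop_param("configuration is missing keys: %s", paste(missing, collapse = ", "))
  if (!is_count(cfg$n_sections) || cfg$n_sections < 3)
    stop_param("n_sections must be an integer >= 3")
  cfg$modalities <- toupper(cfg$modalities)
  if (!all(cfg$modalities %in% c("DF", "IR", "COMBINED")))
    stop_param("modalities must be a subset of DF, IR, COMBINED")
  bad <- setdiff(names(cfg$phantom), names(formals(phantom_params)))
  if (length(bad)) stop_param("unknown phantom parameters: %s", paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$train), names(formals(train_config)))
  if (length(bad)) stop_param("unknown training parameters: %s", paste(bad, collapse = ", "))
  with(cfg$split, stopifnot(train >= 1, val >= 0, test >= 1))
  cfg
}

pipeline_stages <- c("phantom", "preprocess", "patch", "train", "evaluate")

stage_dir <- function(cfg, stage) file.path(cfg$out_dir, stage)
stage_marker <- function(cfg, stage) file.path(stage_dir(cfg, stage), "stage.json")
stage_done <- function(cfg, stage) file.exists(stage_marker(cfg, stage))

finish_stage <- function(cfg, stage, files) {
  files <- files[file.exists(files)]
  info <- list(stage = stage,
               package_version = as.character(utils::packageVersion("dfirseg")),
               config = unclass(cfg),
               files = data.frame(path = files,
                                  md5 = unname(tools::md5sum(files)),
                                  stringsAsFactors = FALSE))
  write_json_file(info, stage_marker(cfg, stage))
  yaml::write_yaml(unclass(cfg), file.path(stage_dir(cfg, stage), "config.yaml"))
  invisible(info)
}

section_seed <- function(cfg, i) (cfg$seed * 131L + i) %% 2147483647L

section_ids <- function(cfg) {
  vapply(seq_len(cfg$n_sections),
         function(i) sprintf("phantom-%06d", section_seed(cfg, i)), "")
}

#' Run the pipeline
#'
#' Executes the requested stages in order (`phantom`, `preprocess`, `patch`,
#' `train`, `evaluate`), writing each stage's artifacts plus a manifest of
#' produced files with checksums, the resolved configuration and the package
#' version into `out_dir/<stage>/`. Completed stages are skipped on re-runs
#' unless `force = TRUE`; a stage whose upstream artifacts are missing raises
#' a dependency error naming the absent stage.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param stages subset of the five stage names.
#' @param force re-run stages whose artifacts already exist.
#' @return Invisibly, the per-stage marker info of the executed stages.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = pipeline_stages, force = FALSE) {
  cfg <- validate_pipeline_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  need <- function(stage) {
    if (!stage_done(cfg, stage))
      stop_param("dependency error: stage '%s' has not produced its artifacts yet",
                 stage)
  }
  log_msg <- function(...) {
    if (!identical(cfg$log_level, "quiet"))
      message(sprintf("[dfirseg] %s", sprintf(...)))
  }
  out <- list()
  for (stage in stages) {
    if (stage_done(cfg, stage) && !force) {
      log_msg("stage %s already complete; skipping", stage)
      next
    }
    upstream <- switch(stage, phantom = NULL, preprocess = "phantom",
                       patch = "preprocess", train = "patch",
                       evaluate = "train")
    if (!is.null(upstream)) need(upstream)
    dir.create(stage_dir(cfg, stage), recursive = TRUE, showWarnings = FALSE)
    log_msg("running stage %s", stage)
    out[[stage]] <- switch(stage,
      phantom = stage_phantom(cfg),
      preprocess = stage_preprocess(cfg),
      patch = stage_patch(cfg),
      train = stage_train(cfg),
      evaluate = stage_evaluate(cfg)
    )
  }
  invisible(out)
}

stage_phantom <- function(cfg) {
  d <- stage_dir(cfg, "phantom")
  files <- character()
  for (i in seq_len(cfg$n_sections)) {
    pars <- do.call(phantom_params, c(cfg$phantom,
                                      list(seed = section_seed(cfg, i))))
    sec <- generate_phantom(pars)
    files <- c(files, write_phantom(sec, d))
  }
  finish_stage(cfg, "phantom", files)
}

stage_preprocess <- function(cfg) {
  d <- stage_dir(cfg, "preprocess")
  files <- character()
  for (id in section_ids(cfg)) {
    sec <- read_phantom(stage_dir(cfg, "phantom"), id)
    st <- preprocess_section(sec, clip_max = cfg$preprocess$clip_max,
                             mask_method = cfg$preprocess$mask_method,
                             register = isTRUE(cfg$preprocess$register))
    files <- c(files, write_stack(st, d))
  }
  finish_stage(cfg, "preprocess", files)
}

stage_patch <- function(cfg) {
  d <- stage_dir(cfg, "patch")
  ids <- section_ids(cfg)
  stacks <- lapply(ids, function(id) read_stack(stage_dir(cfg, "preprocess"), id))
  splits <- split_sections(ids, counts = unlist(cfg$split), seed = cfg$seed)
  train_ids <- splits$section_id[splits$split == "train"]
  stats <- channel_stats(stacks[ids %in% train_ids])
  psets <- lapply(stacks, extract_patches,
                  patch_size = cfg$patch$patch_size,
                  min_tissue_frac = cfg$patch$min_tissue_frac)
  ds <- patch_dataset(psets, splits, stats)
  saveRDS(ds, file.path(d, "dataset.rds"))
  man <- dataset_manifest(ds)
  utils::write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
  counts <- lapply(unique(splits$split), function(s)
    as.list(class_pixel_summary(ds, s)))
  names(counts) <- unique(splits$split)
  write_json_file(counts, file.path(d, "class_pixel_counts.json"))
  finish_stage(cfg, "patch", file.path(d, c("dataset.rds", "manifest.csv",
                                            "class_pixel_counts.json")))
}

stage_train <- function(cfg) {
  d <- stage_dir(cfg, "train")
  ds <- readRDS(file.path(stage_dir(cfg, "patch"), "dataset.rds"))
  files <- character()
  for (m in cfg$modalities) {
    tc <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
    fit <- train_segmenter(ds, modality = m, config = tc)
    f <- file.path(d, sprintf("model_%s.rds", m))
    saveRDS(fit, f)
    files <- c(files, f)
    for (r in fit$replicates) {
      f <- file.path(d, sprintf("history_%s_rep%d.csv", m, r$replicate))
      utils::write.csv(r$history, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  finish_stage(cfg, "train", files)
}

stage_evaluate <- function(cfg) {
  d <- stage_dir(cfg, "evaluate")
  ds <- readRDS(file.path(stage_dir(cfg, "patch"), "dataset.rds"))
  files <- character()
  summary_rows <- list()
  for (m in cfg$modalities) {
    fit <- readRDS(file.path(stage_dir(cfg, "train"), sprintf("model_%s.rds", m)))
    rep <- evaluate_model(fit, ds, split = "test")
    f <- file.path(d, sprintf("report_%s.json", m))
    write_json_file(list(modality = m, aggregate = rep$aggregate,
                         per_replicate = lapply(rep$replicates, function(r)
                           list(accuracy = r$accuracy, macro_f1 = r$macro_f1,
                                per_class = r$per_class))), f)
    files <- c(files, f)
    for (r in rep$replicates) {
      f <- file.path(d, sprintf("confusion_%s_rep%d.csv", m, r$replicate))
      utils::write.csv(r$cm$percent, f)
      files <- c(files, f)
    }
    summary_rows[[m]] <- cbind(modality = m, rep$aggregate)
    # projection of the first test section
    test_id <- ds$splits$section_id[ds$splits$split == "test"][1]
    if (!is.na(test_id)) {
      st <- read_stack(stage_dir(cfg, "preprocess"), test_id)
      pred <- predict_section(fit, st,
                              tile = min(256L, st$grid_shape[1]), overlap = 32L)
      f <- file.path(d, sprintf("projection_%s_%s.png", m, test_id))
      render_projection(pred, st$labels, st$channels[, , 3], f)
      files <- c(files, f)
    }
  }
  utils::write.csv(do.call(rbind, summary_rows),
                   file.path(d, "comparison.csv"), row.names = FALSE)
  finish_stage(cfg, "evaluate", c(files, file.path(d, "comparison.csv")))
}
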