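#' Default end-to-end pipeline configuration
#'
#' A desk-scale configuration of the full simulate -> preprocess ->
#' features -> train -> evaluate pipeline: a three-subject sorted-cell
#' (isolation) dataset for training and a five-subject, fourteen-day
#' longitudinal study for composition analysis, both rendered on a reduced
#' 128 x 192 px scene so a complete run stays in the minutes range. All
#' entries can be overridden via `modifyList()`-style nesting in
#' [run_pipeline()].
#'
#' @param matrix `"blood"` or `"milk"`.
#' @return A nested configuration list.
#' @export
default_config <- function(matrix = "blood") {
  list(
    matrix = matrix,
    scene = list(frame_shape = c(128L, 192L), cells_per_frame_mean = 5,
                 noise_sd = 0.05, artifact_amplitude = 0.1),
    segmentation = list(phase_threshold = 0.8, min_area_px = 30L,
                        background_frames = 100L, connectivity = 8L,
                        patch_size = 96L, pixel_area_um2 = 11.9,
                        edge_policy = "zero_pad"),
    isolation = list(subjects = c("C1", "C2", "C3"), frames_per_class = 40L,
                     imbalance = c(5, 3, 1), subject_jitter_sd = 0.04),
    design = list(subjects = paste0("S", 1:5),
                  days = c(1, 3, 5, 8, 9, 10, 11, 12, 15, 17, 19, 22, 24, 26),
                  frames_per_sample = 60L, subject_jitter_sd = 0.04,
                  reference_noise_sd = 0.02),
    train = list(families = "rf", grid_search = FALSE, smote_k = 5L,
                 test_fraction = 0.3, folds = 5L))
}

config_scene <- function(config) {
  debris <- if (config$matrix == "milk") debris_phenotype() else NULL
  scene_config(frame_shape = config$scene$frame_shape,
               cells_per_frame_mean = config$scene$cells_per_frame_mean,
               noise_sd = config$scene$noise_sd,
               artifact_amplitude = config$scene$artifact_amplitude,
               debris = debris,
               debris_per_frame_mean = if (is.null(debris)) 0 else 1)
}

config_params <- function(config) {
  do.call(segmentation_params, config$segmentation)
}

config_phenotypes <- function(config) {
  if (config$matrix == "milk") milk_phenotypes() else blood_phenotypes()
}

# features of every recording of an isolation set, labeled by sorted class
isolation_feature_table <- function(iso, params) {
  purrr::map_dfr(iso$recordings, function(rec) {
    patches <- preprocess_recording(rec, params)
    cls <- sub("^.*_", "", rec$sample_id)
    build_feature_table(
      patches,
      metadata = list(subject_id = rec$subject_id, matrix = rec$matrix),
      labels = rep(cls, length(patches)), params = params)
  })
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full DCC pipeline
#'
#' Orchestrates simulate -> preprocess -> features -> train -> evaluate
#' from one configuration: synthesizes the isolation (sorted-cell) and
#' longitudinal datasets, extracts features, trains the configured
#' classifier families on the SMOTE-balanced training split, scores the
#' held-out test split, runs leave-one-subject-out validation, derives
#' per-sample compositions of the longitudinal study and compares them with
#' the reference series. All outputs are plain CSV/JSON under `out_dir`,
#' listed with content hashes in `run_manifest.json`. Stages are cached: an
#' unchanged (config, seed) skips recomputation when outputs are present.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the trained models, metric objects,
#'   composition tibbles and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = 1L,
                         verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  params <- config_params(config)
  scene <- config_scene(config)
  phen <- config_phenotypes(config)
  files <- character(0)
  log <- list(seed = seed)

  cache_ok <- function(stage, outputs) {
    marker <- file.path(out_dir, paste0(".", stage, ".hash"))
    h <- rlang::hash(list(config, seed, stage))
    if (file.exists(marker) && identical(readLines(marker, warn = FALSE), h) &&
        all(file.exists(file.path(out_dir, outputs)))) return(TRUE)
    unlink(marker)
    FALSE
  }
  cache_mark <- function(stage) {
    h <- rlang::hash(list(config, seed, stage))
    writeLines(h, file.path(out_dir, paste0(".", stage, ".hash")))
  }

  # -- stage 1: isolation dataset -> labeled features -------------------
  feat_file <- "isolation_features.csv"
  if (cache_ok("features", feat_file)) {
    say("* features: cached")
    features <- readr::read_csv(file.path(out_dir, feat_file),
                                show_col_types = FALSE)
    attr(features, "dhm_schema") <- list(features = feature_names(),
                                         fingerprint = feature_fingerprint())
  } else {
    say("* simulating isolation dataset and extracting features")
    iso <- synthesize_isolation_dataset(
      phen, subjects = config$isolation$subjects,
      frames_per_class = config$isolation$frames_per_class,
      imbalance = config$isolation$imbalance, scene = scene,
      subject_jitter_sd = config$isolation$subject_jitter_sd,
      seed = derive_seed(seed, "isolation"))
    features <- isolation_feature_table(iso, params)
    readr::write_csv(features, file.path(out_dir, feat_file))
    cache_mark("features")
  }
  files <- c(files, feat_file)
  log$n_training_cells <- nrow(features)

  if (nrow(features) == 0L) {
    warning("no cells detected; pipeline stops after feature extraction ",
            "(empty feature table, no model trained)")
    manifest <- build_manifest(config, seed, out_dir, files)
    return(invisible(list(features = features, models = NULL,
                          manifest = manifest)))
  }

  missing_cls <- setdiff(names(phen), unique(features$class))
  if (length(missing_cls))
    warning("no cells detected for class(es): ",
            paste(missing_cls, collapse = ", "),
            " - increase frames_per_class (short recordings contaminate ",
            "the median background)")

  # -- stage 2: train + evaluate + longitudinal DCC ---------------------
  outputs2 <- c("holdout_metrics.csv", "loso_per_subject.csv",
                "loso_summary.csv", "compositions.csv",
                "comparison_overall.csv", "comparison_per_class.csv",
                "comparison_per_subject.csv",
                paste0("confusion_", config$train$families, ".csv"))
  result <- NULL
  if (!cache_ok("analysis", outputs2)) {
    say("* training classifiers")
    split <- stratified_split(features,
                              test_fraction = config$train$test_fraction,
                              seed = derive_seed(seed, "split"))
    balanced <- smote_balance(split$train, k_neighbors = config$train$smote_k,
                              seed = derive_seed(seed, "smote"))
    models <- list(); metrics <- list(); confusions <- list()
    for (fam in config$train$families) {
      hyper <- list()
      cv <- NULL
      if (isTRUE(config$train$grid_search)) {
        gs <- grid_search_cv(split$train, fam, folds = config$train$folds,
                             smote_k = config$train$smote_k,
                             seed = derive_seed(seed, "grid", fam))
        hyper <- gs$best
        cv <- gs$summary
      }
      m <- fit_classifier(balanced, fam, hyper,
                          seed = derive_seed(seed, "fit", fam), cv = cv)
      pred <- predict(m, split$test)
      cm <- confusion_matrix(split$test$class, pred, m$classes)
      models[[fam]] <- m
      confusions[[fam]] <- cm
      metrics[[fam]] <- classification_metrics(cm)
      readr::write_csv(tidy(cm),
                       file.path(out_dir, paste0("confusion_", fam, ".csv")))
    }
    met_tbl <- purrr::imap_dfr(metrics, function(m, fam)
      dplyr::bind_cols(tibble::tibble(family = fam), glance(m)))
    readr::write_csv(met_tbl, file.path(out_dir, "holdout_metrics.csv"))

    say("* leave-one-subject-out validation")
    loso <- leave_one_subject_out(features, family = config$train$families[1],
                                  smote_k = config$train$smote_k,
                                  seed = derive_seed(seed, "loso"))
    readr::write_csv(loso$per_subject, file.path(out_dir, "loso_per_subject.csv"))
    readr::write_csv(loso$summary, file.path(out_dir, "loso_summary.csv"))

    say("* longitudinal study: simulate, classify, compare")
    design <- study_design(subjects = config$design$subjects,
                           days = config$design$days,
                           matrix = config$matrix,
                           reference_noise_sd = config$design$reference_noise_sd,
                           seed = derive_seed(seed, "design"))
    study <- synthesize_longitudinal_study(
      design, phen, scene = scene, matrix = config$matrix,
      frames_per_sample = config$design$frames_per_sample,
      subject_jitter_sd = config$design$subject_jitter_sd,
      seed = derive_seed(seed, "study"))
    model_main <- models[[config$train$families[1]]]
    pred_rows <- vector("list", nrow(study$samples))
    for (i in seq_len(nrow(study$samples))) {
      rec <- realize_sample(study, study$samples$subject_id[i],
                            study$samples$day[i])
      patches <- preprocess_recording(rec, params)
      if (length(patches) == 0L) next
      ft <- build_feature_table(patches, params = params)
      pred_rows[[i]] <- tibble::tibble(
        subject_id = rec$subject_id, matrix = rec$matrix, day = rec$day,
        class = predict(model_main, ft))
    }
    dhm_series <- composition_series(dplyr::bind_rows(pred_rows),
                                     classes = model_main$classes,
                                     source = paste0("DHM-",
                                                     config$train$families[1]))
    all_series <- dplyr::bind_rows(dhm_series, study$truth[names(dhm_series)],
                                   study$reference[names(dhm_series)])
    readr::write_csv(all_series, file.path(out_dir, "compositions.csv"))
    comp <- compare_series(dhm_series, study$reference)
    readr::write_csv(comp$overall, file.path(out_dir, "comparison_overall.csv"))
    readr::write_csv(comp$per_class,
                     file.path(out_dir, "comparison_per_class.csv"))
    readr::write_csv(comp$per_subject,
                     file.path(out_dir, "comparison_per_subject.csv"))
    cache_mark("analysis")
    result <- list(models = models, metrics = metrics,
                   confusions = confusions, loso = loso,
                   dhm_series = dhm_series, truth = study$truth,
                   reference = study$reference, comparison = comp)
  } else {
    say("* analysis: cached")
  }
  files <- c(files, outputs2)

  manifest <- build_manifest(config, seed, out_dir, files)
  say("* done: ", out_dir)
  invisible(c(list(features = features, manifest = manifest), result))
}

build_manifest <- function(config, seed, out_dir, files) {
  files <- unique(files[file.exists(file.path(out_dir, files))])
  manifest <- list(
    package = "holodcc",
    version = as.character(utils::packageVersion("holodcc")),
    seed = seed,
    config = config,
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  write_stage_json(manifest, file.path(out_dir, "run_manifest.json"))
  manifest
}
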