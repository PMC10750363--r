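# End-to-end experiment orchestration: synthetic cohort -> detection
# stage -> clip pipeline -> per-fold training -> metrics -> bundle.

#' Experiment configuration
#'
#' One object describing a full cross-validated experiment.  The four
#' ablation cells are reachable through \code{preprocessing}
#' ("detection" = tracked patient-centered crops; "short_side" = plain
#' short-side scale and center crop, no detection) and
#' \code{train$mode} ("scratch" / "transfer" with a checkpoint).
#'
#' @param n_patients,class_ratio,clips_per_patient,separation synthetic
#'   cohort parameters (see \code{\link{generate_cohort}}).
#' @param frame_width,frame_height,fps scene geometry.
#' @param preprocessing "detection" or "short_side".
#' @param spec a \code{\link{arch_spec}}.
#' @param train a \code{\link{train_config}}.
#' @param k folds (default 5).
#' @param seed master seed, fanned out deterministically to cohort
#'   generation, fold split, weight initialization and batch order.
#' @param crop_side detection-stage crop side (default 512).
#' @param model_side model input side (default 224).
#' @param checkpoint optional path to a pretrained checkpoint
#'   (required for transfer mode).
#' @return object of class \code{gait_experiment_config}.
#' @export
experiment_config <- function(n_patients = 12L, class_ratio = 0.5,
                              clips_per_patient = 3L, separation = 1,
                              frame_width = 640L, frame_height = 360L,
                              fps = 30L,
                              preprocessing = c("detection", "short_side"),
                              spec = arch_spec(c(1L, 1L, 1L, 1L),
                                               width_multiplier = 0.25),
                              train = train_config(),
                              k = 5L, seed = 1L,
                              crop_side = 512L, model_side = 224L,
                              checkpoint = NULL) {
  preprocessing <- match.arg(preprocessing)
  if (train$mode == "transfer" && is.null(checkpoint))
    stop_gaitscreen("transfer mode requires a checkpoint path",
                    "gaitscreen_config")
  structure(list(n_patients = as.integer(n_patients),
                 class_ratio = class_ratio,
                 clips_per_patient = as.integer(clips_per_patient),
                 separation = separation,
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 fps = as.integer(fps),
                 preprocessing = preprocessing, spec = spec,
                 train = train, k = as.integer(k), seed = as.integer(seed),
                 crop_side = as.integer(crop_side),
                 model_side = as.integer(model_side),
                 checkpoint = checkpoint),
            class = "gait_experiment_config")
}

#' Serialize / restore an experiment configuration
#'
#' JSON round trip; \code{config_from_json(config_to_json(cfg))}
#' reproduces the configuration exactly.
#'
#' @param config a \code{gait_experiment_config}.
#' @param json a JSON string from \code{config_to_json}.
#' @return JSON string / restored config.
#' @export
config_to_json <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' @rdname config_to_json
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  experiment_config(
    n_patients = x$n_patients, class_ratio = x$class_ratio,
    clips_per_patient = x$clips_per_patient, separation = x$separation,
    frame_width = x$frame_width, frame_height = x$frame_height,
    fps = x$fps, preprocessing = x$preprocessing,
    spec = arch_spec(x$spec$block_counts, x$spec$n_classes,
                     x$spec$t_frames, x$spec$width_multiplier),
    train = train_config(x$train$learning_rate, x$train$batch_size,
                         x$train$early_stop_patience,
                         x$train$lr_halve_patience, x$train$max_epochs,
                         x$train$seed, x$train$mode),
    k = x$k, seed = x$seed, crop_side = x$crop_side,
    model_side = x$model_side, checkpoint = x$checkpoint)
}

# Render and preprocess every clip of a cohort into model-ready
# tensors.  Scenes are processed one at a time and discarded, keeping
# only the small (3, T, side, side) arrays.
preprocess_cohort <- function(cohort, config) {
  clips <- list(); labels <- character(0); patients <- character(0)
  for (i in seq_len(nrow(cohort$patients))) {
    pid <- cohort$patients$patient_id[i]
    lab <- as.character(cohort$patients$label[i])
    for (cfg in cohort$scene_configs[[pid]]) {
      scene <- generate_scene(cfg)
      if (config$preprocessing == "detection") {
        ext <- extract_patient_clip(scene$frames, detect_scene(scene),
                                    out_side = config$crop_side)
        frames <- ext$frames
      } else {
        frames <- lapply(scene$frames, short_side_scale,
                         target = config$crop_side)
      }
      for (clip in slice_one_second_clips(frames, fps = config$fps,
                                          patient_id = pid, label = lab)) {
        s <- sample_frames(clip, t_frames = config$spec$t_frames)
        clips <- c(clips, list(resize_for_model(s, side = config$model_side)))
        labels <- c(labels, lab)
        patients <- c(patients, pid)
      }
    }
  }
  list(clips = clips, labels = labels, patient = patients)
}

subset_clipset <- function(cs, keep) {
  list(clips = cs$clips[keep], labels = cs$labels[keep],
       patient = cs$patient[keep])
}

#' Run a full cross-validated experiment
#'
#' Generates (or loads) the cohort, preprocesses every clip, splits
#' patients with \code{\link{stratified_group_kfold}}, trains one model
#' per fold and evaluates it on the held-out patients, then aggregates
#' the per-fold metrics.  Reproducible for a fixed config and seed
#' under single-threaded execution.
#'
#' @param config a \code{\link{experiment_config}}.
#' @param out_dir optional directory; when given, metrics, fold
#'   assignment and per-clip predictions are written as JSON/CSV.
#' @return object of class \code{gait_experiment}: \code{fold_metrics}
#'   data.frame, \code{mean_metrics}, \code{folds}, \code{histories},
#'   \code{predictions} data.frame, \code{config}.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "gait_experiment_config"))
  cohort <- generate_cohort(config$n_patients, config$class_ratio,
                            config$clips_per_patient,
                            seed = derive_seed(config$seed, 1L),
                            separation = config$separation,
                            frame_width = config$frame_width,
                            frame_height = config$frame_height,
                            fps = config$fps)
  data <- preprocess_cohort(cohort, config)
  labels <- cohort$patients$label
  names(labels) <- cohort$patients$patient_id
  folds <- stratified_group_kfold(labels, k = config$k,
                                  seed = derive_seed(config$seed, 2L))
  fold_rows <- list(); histories <- list(); preds <- list()
  for (f in seq_len(config$k)) {
    val_ids <- folds$folds[[f]]
    val <- subset_clipset(data, data$patient %in% val_ids)
    trn <- subset_clipset(data, !(data$patient %in% val_ids))
    model <- build_model(config$spec, seed = derive_seed(config$seed, 100L + f))
    if (config$train$mode == "transfer") {
      model <- load_checkpoint(model, config$checkpoint)
      model <- adapt_head(model, config$spec$n_classes,
                          seed = derive_seed(config$seed, 200L + f))
    }
    tc <- config$train
    tc$seed <- derive_seed(config$seed, 300L + f)
    fit <- train_fold(model, trn, val, tc)
    sc <- forward(fit$model, val$clips)
    pred <- GAIT_LEVELS[max.col(sc, ties.method = "first")]
    rep <- metrics_report(val$labels, pred, sc[, 1L], positive = "ASD")
    fold_rows[[f]] <- data.frame(fold = f, accuracy = rep$accuracy,
                                 f1 = rep$f1, auroc = rep$auroc,
                                 n_val_clips = length(val$clips))
    histories[[f]] <- fit$history
    preds[[f]] <- data.frame(fold = f, patient_id = val$patient,
                             label = val$labels, predicted = pred,
                             score_asd = sc[, 1L])
  }
  fold_metrics <- do.call(rbind, fold_rows)
  bundle <- structure(list(
    fold_metrics = fold_metrics,
    mean_metrics = c(accuracy = aggregate_cv(fold_metrics$accuracy),
                     f1 = aggregate_cv(fold_metrics$f1),
                     auroc = aggregate_cv(fold_metrics$auroc)),
    folds = folds, histories = histories,
    predictions = do.call(rbind, preds),
    config = config), class = "gait_experiment")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat(sprintf("Cross-validated gait experiment (%d folds, %d patients)\n",
              x$config$k, x$config$n_patients))
  print(round(x$fold_metrics[, c("fold", "accuracy", "f1", "auroc")], 4))
  m <- x$mean_metrics
  cat(sprintf("mean: accuracy %.4f | F1 %.4f | AUROC %.4f\n",
              m[["accuracy"]], m[["f1"]], m[["auroc"]]))
  invisible(x)
}

#' Write an experiment bundle to disk
#'
#' Metrics and fold assignment as JSON, per-clip predictions as CSV,
#' and the config snapshot as JSON.
#'
#' @param bundle a \code{gait_experiment}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(fold_metrics = bundle$fold_metrics,
         mean_metrics = as.list(bundle$mean_metrics)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(bundle$folds$folds, identity),
                       file.path(dir, "folds.json"))
  utils::write.csv(bundle$predictions,
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  writeLines(config_to_json(bundle$config), file.path(dir, "config.json"))
  invisible(dir)
}
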