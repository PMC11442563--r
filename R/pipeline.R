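#' Evaluate a detector on a manifest of pairs
#'
#' Scores every positive and negative image of the selected rows, builds
#' the FROC and case-level ROC curves, and reports the four headline
#' metrics: R-CPM, sensitivity at a fixed FP rate, AUROC, and sensitivity
#' at a fixed specificity.
#'
#' @param detector A `cad_detector` (or a bare parameter list, with
#'   `model_config` supplied).
#' @param manifest Pair manifest.
#' @param split Restrict to one split (`"train"`/`"val"`), or `NULL` for
#'   all rows.
#' @param iou_min IoU threshold for lesion matching.
#' @param fp_rate FROC operating point (FPs/case).
#' @param specificity ROC operating point.
#' @param model_config Only needed when `detector` is a raw parameter
#'   list.
#' @return List with `froc`, `roc`, and `metrics` (named numeric vector).
#' @export
evaluate_detector <- function(detector, manifest, split = NULL,
                              iou_min = 0.1, fp_rate = 0.2,
                              specificity = 0.8, model_config = NULL) {
  if (inherits(detector, "cad_detector")) {
    params <- detector$params
    model_config <- detector$model_config
  } else params <- detector
  pairs <- load_pairs(manifest, split)
  cases <- score_pairs(params, model_config, pairs)
  fr <- froc(cases, iou_min)
  rc <- case_roc(cases)
  neg <- vapply(cases, function(cs) !cs$is_positive_case, TRUE)
  fp_per_neg <- mean(vapply(cases[neg], function(cs) length(cs$candidates), 0))
  list(froc = fr, roc = rc,
       metrics = c(r_cpm = r_cpm(fr),
                   sensitivity_at_fp_rate = sensitivity_at_fp_rate(fr, fp_rate),
                   auroc = auroc(rc),
                   sensitivity_at_specificity =
                     sensitivity_at_specificity(rc, specificity),
                   fp_per_negative_image = fp_per_neg))
}

#' Mean number of candidates on negative images
#'
#' The raw false-positive burden of a detector on lesion-free images at
#' the natural operating point of the nonnegative-output detector (every
#' connected component of `f > 0` counts).
#'
#' @param detector A `cad_detector`.
#' @param manifest Pair manifest.
#' @param split Split to use (default `"val"`).
#' @return Mean candidate count per negative image.
#' @export
fp_rate_negatives <- function(detector, manifest, split = "val") {
  pairs <- load_pairs(manifest, split)
  mean(vapply(pairs, function(pr) {
    f <- net_forward(detector$params, detector$model_config, pr$negative)
    length(extract_candidates(f, pr$case_id))
  }, 0))
}

log_stage <- function(verbose, stage, ...) {
  if (verbose)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full synthesize-train-evaluate experiment
#'
#' Orchestrates the complete pipeline from one configuration: synthesizes
#' a paired training/validation dataset and a held-out test dataset,
#' trains the detector with the configured loss weights, selects the best
#' epoch by validation R-CPM, optionally applies Dice-only fine-tuning on
#' the test images (leave-one-out style single-image mode), evaluates on
#' the test set, and writes a JSON report stamped with the configuration
#' hash and seed. Reports contain no timestamps, so two runs with the same
#' configuration are byte-identical.
#'
#' @param config A `run_config` (see [load_config()] / [as_run_config()]).
#' @return The report list, invisibly; written to
#'   `<out_dir>/report.json`. The trained detector is saved to
#'   `<out_dir>/detector.rds` and the curves to delimited tables.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  verbose <- isTRUE(config$verbose)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- synth_config_from(config)
  mcfg <- model_config_from(config)
  tcfg <- train_config_from(config)

  n_total <- config$synth$n_train_pairs + config$synth$n_val_pairs
  val_frac <- config$synth$n_val_pairs / n_total
  log_stage(verbose, "synthesize", n_total, " training pairs")
  train_manifest <- withCallingHandlers(
    generate_dataset(n_total, scfg, stage_seed(config$seed, "synth"),
                     val_frac, file.path(config$out_dir, "data")),
    error = function(e) stop("[synthesize] ", conditionMessage(e)))
  log_stage(verbose, "synthesize", config$eval$n_test_pairs, " test pairs")
  test_manifest <- withCallingHandlers(
    generate_dataset(config$eval$n_test_pairs, scfg,
                     stage_seed(config$seed, "test"), 0,
                     file.path(config$out_dir, "test_data")),
    error = function(e) stop("[synthesize] ", conditionMessage(e)))

  log_stage(verbose, "train", tcfg$epochs, " epochs")
  detector <- withCallingHandlers(
    train_detector(train_manifest, mcfg, tcfg),
    error = function(e) stop("[train] ", conditionMessage(e)))

  if (config$finetune$epochs > 0) {
    log_stage(verbose, "finetune", config$finetune$epochs, " epochs")
    ft_manifest <- data.frame(case_id = test_manifest$case_id,
                              image_path = test_manifest$positive_path,
                              label_path = test_manifest$label_path)
    attr(ft_manifest, "dir") <- attr(test_manifest, "dir")
    detector$params <- withCallingHandlers(
      fine_tune_single(detector$params, mcfg, ft_manifest, tcfg,
                       epochs = config$finetune$epochs),
      error = function(e) stop("[finetune] ", conditionMessage(e)))
  }

  log_stage(verbose, "evaluate", config$eval$n_test_pairs, " test pairs")
  ev <- withCallingHandlers(
    evaluate_detector(detector, test_manifest, iou_min = config$eval$iou_min,
                      fp_rate = config$eval$fp_rate,
                      specificity = config$eval$specificity),
    error = function(e) stop("[evaluate] ", conditionMessage(e)))

  report <- list(config_hash = hash, seed = config$seed,
                 best_epoch = detector$best_epoch,
                 metrics = as.list(ev$metrics),
                 history = detector$history)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(ev$froc, file.path(config$out_dir, "froc_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$roc, file.path(config$out_dir, "roc_curve.csv"),
                   row.names = FALSE)
  detector$config_hash <- hash
  detector$seed <- config$seed
  save_detector(detector, file.path(config$out_dir, "detector.rds"))
  invisible(report)
}

#' Predict on image files and write the results
#'
#' Applies a trained detector to arbitrary single grayscale images — no
#' negative twin needed at inference time — writing one likelihood map per
#' image and a combined candidate table.
#'
#' @param detector A `cad_detector`.
#' @param image_paths Character vector of PNG/RDS image paths.
#' @param out_dir Output directory.
#' @return The candidate `data.frame`, invisibly; written to
#'   `out_dir/predictions.csv`, maps to `out_dir/maps/`.
#' @export
predict_to_dir <- function(detector, image_paths, out_dir) {
  dir.create(file.path(out_dir, "maps"), recursive = TRUE,
             showWarnings = FALSE)
  maps <- predict(detector, image_paths, type = "map")
  for (id in names(maps))
    saveRDS(maps[[id]], file.path(out_dir, "maps",
                                  paste0(sub("\\.[^.]+$", "", id), "_map.rds")))
  tab <- candidate_table(maps)
  utils::write.csv(tab, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(tab)
}

#' Save / load a detector with provenance metadata
#' @param detector A `cad_detector`.
#' @param path RDS path.
#' @export
save_detector <- function(detector, path) {
  saveRDS(detector, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) readRDS(path)
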