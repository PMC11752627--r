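# End-to-end orchestration: load (or synthesise) -> duration filter ->
# resample -> time-frequency transform -> render -> stratified split ->
# train -> evaluate, with per-stage logging and artifact output.

#' Pipeline configuration
#'
#' One seed fans out deterministically to the synthesis, split, model and
#' training sub-seeds. The rendered image size equals the model input size
#' by construction (both come from `image_size`). The preset trains the
#' bundled small CNN from random initialisation, hence the 1e-3 learning
#' rate; pass a `train` config to restore the transfer-learning defaults.
#'
#' @param input_dir directory of records (CinC 2017 layout), or `NULL` when
#'   `synth_counts` is given.
#' @param synth_counts named per-class counts for synthetic input.
#' @param labels_path optional labels csv for `input_dir`.
#' @param target_duration_s segment duration (s).
#' @param fs_analysis analysis sampling rate (Hz); the transform branch runs
#'   at this rate (set equal to the record rate to skip resampling).
#' @param transform `"cwt"` or `"stft"`.
#' @param morse a [morse_params()].
#' @param window_length,overlap STFT parameters.
#' @param image_size rendered image side length (pixels); also the model
#'   input size.
#' @param ratios train/validation/test fractions.
#' @param train a [train_config()]; `NULL` selects the small-CNN preset
#'   (rmsprop, lr 1e-3, batch 64, max 105 epochs, patience 10).
#' @param backbone `"small"` or a pretrained-backbone list (see
#'   [build_model()]).
#' @param out_dir optional artifact directory (images, metrics, history).
#' @param seed master seed.
#' @param verbose log stage progress.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synth_counts = NULL,
                            labels_path = NULL, target_duration_s = 30,
                            fs_analysis = 128,
                            transform = c("cwt", "stft"),
                            morse = morse_params(),
                            window_length = 256, overlap = 128,
                            image_size = 64,
                            ratios = c(0.64, 0.16, 0.20),
                            train = NULL, backbone = "small",
                            out_dir = NULL, seed = 1L, verbose = TRUE) {
  transform <- match.arg(transform)
  if (is.null(train)) {
    train <- train_config(learning_rate = 1e-3,
                          seed = derive_seed(seed, 3L))
  }
  structure(
    list(input_dir = input_dir, synth_counts = synth_counts,
         labels_path = labels_path, target_duration_s = target_duration_s,
         fs_analysis = fs_analysis, transform = transform, morse = morse,
         window_length = window_length, overlap = overlap,
         image_size = as.integer(image_size), ratios = ratios,
         train = train, backbone = backbone, out_dir = out_dir,
         seed = as.integer(seed), verbose = verbose),
    class = "pipeline_config"
  )
}

#' Run the full classification pipeline
#'
#' Stages: load (or synthesise) records, duration filter, resample,
#' time-frequency transform and image rendering, stratified split, training
#' with early stopping, evaluation on the held-out test subset. Stage errors
#' propagate with the stage name attached; counts are logged per stage.
#'
#' @param config a [pipeline_config()].
#' @param records optional pre-loaded list of [ecg_record()]s (overrides the
#'   config input source).
#' @return list with `report` (a [metrics_report()]), `history`, `summary`
#'   (the duration-filter summary), `split_sizes`, `images` (list of
#'   `scalogram_image`), and `model`.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    afw_log(stage, ..., sprintf(" [%.1fs]",
                                as.numeric(Sys.time() - t0, units = "secs")),
            verbose = v)
  }

  # load
  if (is.null(records)) {
    records <- tryCatch({
      if (!is.null(config$synth_counts)) {
        synth_dataset(config$synth_counts,
                      base_seed = derive_seed(config$seed, 1L))
      } else if (!is.null(config$input_dir)) {
        load_dataset(config$input_dir, config$labels_path)
      } else {
        stop("no input source configured")
      }
    }, error = function(e) stop_stage("load", conditionMessage(e)))
  }
  if (length(records) == 0L) stop_stage("load", "no records to process")
  log_stage("load", length(records), " records")

  # duration filter
  filt <- tryCatch(filter_dataset(records, config$target_duration_s),
                   error = function(e) stop_stage("filter", conditionMessage(e)))
  log_stage("filter", filt$summary$kept, " kept, ",
            filt$summary$excluded, " excluded")
  if (filt$summary$kept == 0L) stop_stage("filter", "no segments kept")

  # resample
  segments <- tryCatch(
    lapply(filt$segments, resample_segment, fs_target = config$fs_analysis),
    error = function(e) stop_stage("resample", conditionMessage(e)))
  log_stage("resample", "to ", config$fs_analysis, " Hz")

  # transform + render (shared filter bank across equal-length segments)
  images <- tryCatch({
    cfg <- list(mode = config$transform, params = config$morse,
                window_length = config$window_length,
                overlap = config$overlap,
                size = c(config$image_size, config$image_size))
    if (config$transform == "cwt") {
      cfg$bank <- design_filter_bank(2L * length(segments[[1L]]$samples),
                                     config$fs_analysis, config$morse)
    }
    lapply(segments, render_segment, cfg = cfg)
  }, error = function(e) stop_stage("render", conditionMessage(e)))
  log_stage("render", length(images), " images at ",
            config$image_size, "x", config$image_size)
  stopifnot(length(images) == filt$summary$kept)

  # split (stratified by label)
  labels <- vapply(segments, function(s) s$label, character(1))
  spec <- split_spec(config$ratios, seed = derive_seed(config$seed, 2L))
  split <- tryCatch(split_dataset(seq_along(images), spec, labels = labels),
                    error = function(e) stop_stage("split", conditionMessage(e)))
  sizes <- lengths(attr(split, "indices"))
  log_stage("split", paste(sizes, collapse = "/"))

  make_set <- function(idx) list(images = images[idx], labels = labels[idx])
  class_names <- sort(unique(labels))

  # train
  fitted <- tryCatch({
    model <- build_model(config$backbone, n_classes = length(class_names),
                         input_size = config$image_size,
                         class_names = class_names,
                         seed = derive_seed(config$seed, 4L))
    train(model, make_set(split$train), make_set(split$validation),
          config$train, verbose = FALSE)
  }, error = function(e) stop_stage("train", conditionMessage(e)))
  log_stage("train", nrow(fitted$history), " epochs (",
            attr(fitted$history, "stop_reason"), "), best val acc ",
            round(attr(fitted$history, "best_val_accuracy"), 4))

  # evaluate
  report <- tryCatch({
    test_set <- make_set(split$test)
    pred <- predict(fitted$model, test_set$images)
    metrics_report(test_set$labels, pred$decisions, pred$scores, class_names)
  }, error = function(e) stop_stage("evaluate", conditionMessage(e)))
  log_stage("evaluate", length(split$test), " test items, macro F1 ",
            round(report$macro$f1, 4))

  # artifacts
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    img_dir <- file.path(config$out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (im in images) {
      write_image_png(im, file.path(img_dir,
                                    paste0(im$label, "_", im$source_id, ".png")))
    }
    utils::write.csv(fitted$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      as.data.frame(report),
      file.path(config$out_dir, "metrics.json"),
      dataframe = "rows", digits = NA)
    log_stage("artifacts", "written to ", config$out_dir)
  }

  list(report = report, history = fitted$history, summary = filt$summary,
       split_sizes = as.integer(sizes), images = images,
       model = fitted$model)
}
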