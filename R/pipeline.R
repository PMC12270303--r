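#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Any
#' field can be overridden; everything else keeps its default. A
#' configuration can also be given as a YAML file path.
#'
#' @param output_dir Directory for all stage artifacts.
#' @param class_counts Named vector, class -> number of colonies.
#' @param n_timepoints Frames per colony.
#' @param n_cells Mean cells per colony.
#' @param differentiation_time Frame of full motif expression (NULL: mid
#'   series; 0: time-invariant motifs).
#' @param dims_used Homology dimensions for the landscape features.
#' @param sample_points Landscape grid.
#' @param n_functions Landscape functions per dimension (NULL: 40 single
#'   dimension, 20 combined).
#' @param threshold Rips threshold (NULL: twice the grid maximum).
#' @param timepoints Frames to train on (NULL: all).
#' @param repeats Models per timepoint.
#' @param randomize_labels Train against i.i.d. uniformly randomised
#'   colony labels (control experiment).
#' @param training Named list of [training_config()] overrides.
#' @param crosstime_offset Frame offset defining `S*` for the
#'   time-differential metric.
#' @param seed Master seed; all stage randomness derives from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            class_counts = c("WT" = 12, "BMP4" = 16,
                                             "CHIR" = 16, "DS" = 17,
                                             "DS+CHIR" = 17),
                            n_timepoints = 1,
                            n_cells = 200,
                            differentiation_time = NULL,
                            dims_used = c(0, 1),
                            sample_points = default_grid(),
                            n_functions = NULL,
                            threshold = NULL,
                            timepoints = NULL,
                            repeats = 10,
                            randomize_labels = FALSE,
                            training = list(),
                            crosstime_offset = 10,
                            seed = 1L) {
  if (missing(output_dir) || !nzchar(output_dir)) {
    abort("output_dir is required", class = "colonytda_invalid_config")
  }
  if (is.null(threshold)) threshold <- 2 * max(sample_points)
  cfg <- list(
    output_dir = output_dir,
    class_counts = unlist(class_counts),
    n_timepoints = as.integer(n_timepoints),
    n_cells = n_cells,
    differentiation_time = differentiation_time,
    dims_used = dims_used,
    sample_points = sample_points,
    n_functions = n_functions,
    threshold = threshold,
    timepoints = timepoints,
    repeats = as.integer(repeats),
    randomize_labels = isTRUE(randomize_labels),
    training = training,
    crosstime_offset = as.integer(crosstime_offset),
    seed = as.integer(seed)
  )
  # validate the training overrides eagerly, before any computation
  do.call(training_config, c(cfg$training, list(seed = cfg$seed)))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "colonytda_missing_input")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$class_counts)) raw$class_counts <- unlist(raw$class_counts)
  do.call(pipeline_config, raw)
}

stage_dir <- function(cfg, name) file.path(cfg$output_dir, name)

require_stage_dir <- function(cfg, name, needed_for) {
  d <- stage_dir(cfg, name)
  if (!dir.exists(d)) {
    abort(sprintf(
      "stage '%s' needs '%s', which does not exist; run the '%s' stage first",
      needed_for, d, name), class = "colonytda_missing_input")
  }
  d
}

pipeline_training_config <- function(cfg) {
  do.call(training_config, c(cfg$training, list(seed = cfg$seed)))
}

write_manifest <- function(cfg, stage, outputs) {
  manifest <- list(
    package = "colonytda",
    version = as.character(utils::packageVersion("colonytda")),
    stage = stage,
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = outputs
  )
  path <- file.path(cfg$output_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

pipe_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the colony classification pipeline
#'
#' Orchestrates the stages: `synthesize` (generate labelled point clouds
#' and write coordinate files), `persist` (Rips persistence barcodes),
#' `landscape` (landscape matrices), `train` (per-timepoint classifier
#' training with repeats), `evaluate` (accuracy, confusion, per-class
#' metrics), `crosstime` (cross-timepoint accuracy grid and
#' time-differential metric), or `all`. Each stage writes delimited-text
#' artifacts plus a JSON manifest under the configured output directory;
#' re-running with the same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param stage One of `synthesize`, `persist`, `landscape`, `train`,
#'   `evaluate`, `crosstime`, `all`.
#' @param verbose Log progress to stderr.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stage = "all", verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, c("synthesize", "persist", "landscape", "train",
                              "evaluate", "crosstime", "all"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("synthesize", "persist", "landscape", "train", "evaluate", "crosstime")
  } else stage
  out <- list()
  for (s in stages) {
    pipe_log(verbose, "stage %s ...", s)
    out[[s]] <- switch(s,
      synthesize = stage_synthesize(config),
      persist = stage_persist(config, verbose),
      landscape = stage_landscape(config),
      train = stage_train(config),
      evaluate = stage_evaluate(config),
      crosstime = stage_crosstime(config)
    )
    write_manifest(config, s, out[[s]])
  }
  invisible(out)
}

stage_synthesize <- function(cfg) {
  dataset <- generate_dataset(
    class_counts = cfg$class_counts, n_timepoints = cfg$n_timepoints,
    master_seed = cfg$seed, n_cells = cfg$n_cells,
    differentiation_time = cfg$differentiation_time)
  d <- stage_dir(cfg, "coordinates")
  write_dataset(dataset, d)
  list(coordinates = d)
}

stage_persist <- function(cfg, verbose = FALSE) {
  src <- require_stage_dir(cfg, "coordinates", "persist")
  dataset <- read_dataset(src)
  d <- stage_dir(cfg, "barcodes")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(dataset[c("colony_id", "timepoint", "points")],
    function(colony_id, timepoint, points) {
      dg <- compute_diagram(points, threshold = cfg$threshold)
      write_barcode(dg, file.path(d, sprintf("%s_t%03d.tsv",
                                             colony_id, timepoint)))
    })
  list(barcodes = d)
}

stage_landscape <- function(cfg) {
  src <- require_stage_dir(cfg, "barcodes", "landscape")
  d <- stage_dir(cfg, "landscapes")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(src, pattern = "\\.tsv$")) {
    dg <- read_barcode(file.path(src, f), threshold = cfg$threshold)
    lm <- landscape_matrix(dg, dims_used = cfg$dims_used,
                           sample_points = cfg$sample_points,
                           n_functions = cfg$n_functions)
    write_landscape(lm, file.path(d, f))
  }
  list(landscapes = d)
}

# Reassemble the feature table from landscape files + the label table.
load_features <- function(cfg, needed_for) {
  src <- require_stage_dir(cfg, "landscapes", needed_for)
  lab_path <- file.path(stage_dir(cfg, "coordinates"), "labels.csv")
  if (!file.exists(lab_path)) {
    abort(sprintf("'%s' needs the label table '%s'", needed_for, lab_path),
          class = "colonytda_missing_input")
  }
  lab <- utils::read.csv(lab_path, colClasses = "character")
  files <- list.files(src, pattern = "\\.tsv$")
  hits <- regmatches(files, regexec("^(.+)_t(\\d+)\\.tsv$", files))
  rows <- purrr::compact(purrr::map2(files, hits, function(f, h) {
    if (length(h) != 3) return(NULL)
    lm <- read_landscape(file.path(src, f))
    tibble::tibble(colony_id = h[2],
                   class = lab$class[match(h[2], lab$colony_id)],
                   timepoint = as.integer(h[3]),
                   features = list(as.vector(t(unclass(lm)))))
  }))
  dplyr::arrange(dplyr::bind_rows(rows), .data$colony_id, .data$timepoint)
}

stage_train <- function(cfg) {
  features <- load_features(cfg, "train")
  tcfg <- pipeline_training_config(cfg)
  labels <- NULL
  if (cfg$randomize_labels) {
    labels <- randomize_labels(
      dplyr::distinct(features, .data$colony_id, .data$class),
      classes = sort(unique(features$class)),
      seed = derive_seed(cfg$seed, 99L))
  }
  models <- train_timepoint_models(features, timepoints = cfg$timepoints,
                                   repeats = cfg$repeats, config = tcfg,
                                   labels = labels)
  d <- stage_dir(cfg, "models")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(models[c("timepoint", "repeat_id", "fit")],
    function(timepoint, repeat_id, fit) {
      write_model(fit, file.path(d, sprintf("model_t%03d_r%02d.json",
                                            timepoint, repeat_id)))
    })
  acc_path <- file.path(d, "val_accuracy.csv")
  utils::write.csv(models[c("timepoint", "repeat_id", "val_accuracy")],
                   acc_path, row.names = FALSE)
  if (!is.null(labels)) {
    utils::write.csv(labels, file.path(d, "randomized_labels.csv"),
                     row.names = FALSE)
  }
  list(models = d, val_accuracy = acc_path)
}

stage_evaluate <- function(cfg) {
  features <- load_features(cfg, "evaluate")
  mdir <- require_stage_dir(cfg, "models", "evaluate")
  files <- list.files(mdir, pattern = "^model_.*\\.json$")
  if (length(files) == 0) {
    abort(sprintf("no model files under '%s'; run the 'train' stage first",
                  mdir), class = "colonytda_missing_input")
  }
  hits <- regmatches(files, regexec("^model_t(\\d+)_r(\\d+)\\.json$", files))
  if (cfg$randomize_labels) {
    rl <- utils::read.csv(file.path(mdir, "randomized_labels.csv"),
                          colClasses = "character")
    features$class <- rl$class[match(features$colony_id, rl$colony_id)]
  }
  models <- dplyr::bind_rows(purrr::map2(files, hits, function(f, h) {
    fit <- read_model(file.path(mdir, f))
    tibble::tibble(timepoint = as.integer(h[2]),
                   repeat_id = as.integer(h[3]),
                   val_accuracy = fit$best_val_accuracy, fit = list(fit))
  }))
  report <- timepoint_report(models, features)
  d <- stage_dir(cfg, "reports")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(d, "class_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$accuracy, file.path(d, "accuracy.csv"),
                   row.names = FALSE)
  for (tp in names(report$confusion)) {
    utils::write.csv(as.data.frame(unclass(report$confusion[[tp]])),
                     file.path(d, sprintf("confusion_t%03d.csv",
                                          as.integer(tp))))
  }
  list(reports = d)
}

stage_crosstime <- function(cfg) {
  features <- load_features(cfg, "crosstime")
  tcfg <- do.call(crosstime_config, c(cfg$training, list(seed = cfg$seed)))
  grid <- cross_time_grid(features, config = tcfg,
                          repeats = max(1L, cfg$repeats %/% 2L))
  diff <- time_differential(grid, offset = cfg$crosstime_offset)
  d <- stage_dir(cfg, "crosstime")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(grid, file.path(d, "accuracy_grid.csv"), row.names = FALSE)
  utils::write.csv(diff, file.path(d, "time_differential.csv"),
                   row.names = FALSE)
  list(crosstime = d)
}

#' Serialize a trained model to a single JSON file
#'
#' The checkpoint stores the architecture, the best-epoch parameters, the
#' class order, the training configuration and seed, the split membership
#' and the epoch history; [read_model()] restores a fully functional
#' `tdanet_fit`.
#'
#' @param fit A `tdanet_fit`.
#' @param path Output path.
#' @export
write_model <- function(fit, path) {
  payload <- list(
    layer_sizes = fit$spec$layer_sizes,
    class_levels = fit$class_levels,
    params = lapply(fit$params, function(p)
      list(W = unclass(p$W), b = p$b)),
    best_epoch = fit$best_epoch,
    best_val_accuracy = fit$best_val_accuracy,
    split = fit$split,
    config = unclass(fit$config),
    history = fit$history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path),
          class = "colonytda_missing_input")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(seq_along(p$params$W), function(l) {
    W <- p$params$W[[l]]
    if (is.null(dim(W))) W <- matrix(W, nrow = 1)
    list(W = W, b = as.numeric(p$params$b[[l]]))
  })
  structure(
    list(
      spec = build_tdanet(p$layer_sizes[1],
                          p$layer_sizes[length(p$layer_sizes)],
                          hidden = p$layer_sizes[-c(1, length(p$layer_sizes))]),
      params = params,
      class_levels = p$class_levels,
      history = tibble::as_tibble(p$history),
      best_epoch = p$best_epoch,
      best_val_accuracy = p$best_val_accuracy,
      split = p$split,
      config = do.call(training_config, p$config[
        c("train_fraction", "max_epochs", "patience", "optimizer",
          "learning_rate", "batch_size", "stratify", "seed")])
    ),
    class = "tdanet_fit"
  )
}
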