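#' Landscape features for every colony frame
#'
#' Runs the topological stage end to end: for each row of a dataset
#' (colony x timepoint), computes the Rips persistence diagram and the
#' sampled landscape matrix, flattened to the classifier's input vector.
#'
#' @param dataset Dataset tibble from [generate_dataset()] (columns
#'   `colony_id`, `class`, `timepoint`, `points`).
#' @param dims_used Homology dimensions to featurise (default both).
#' @param sample_points Landscape grid (default `1:40`).
#' @param n_functions Landscape functions per dimension (default 20 when
#'   both dimensions are used, 40 for one).
#' @param threshold Rips filtration threshold (default twice the grid
#'   maximum, sufficient for exact landscapes on the grid).
#' @return The dataset tibble with `points` replaced by a `features`
#'   list-column of flattened landscape vectors.
#' @export
compute_features <- function(dataset, dims_used = c(0, 1),
                             sample_points = default_grid(),
                             n_functions = NULL,
                             threshold = 2 * max(sample_points)) {
  feats <- purrr::map(dataset$points, function(cloud) {
    dg <- compute_diagram(cloud, threshold = threshold)
    lm <- landscape_matrix(dg, dims_used = dims_used,
                           sample_points = sample_points,
                           n_functions = n_functions)
    as.vector(t(unclass(lm)))
  })
  out <- dplyr::select(dataset, -"points")
  out$features <- feats
  out
}

#' Train repeated models per timepoint
#'
#' Mirrors the per-timepoint training workflow: for each requested frame,
#' `repeats` independent models are trained on that frame's colonies
#' (70/30 split by default), each from its own derived seed.
#'
#' @param features Feature table from [compute_features()].
#' @param timepoints Frames to train on (default: all present).
#' @param repeats Models per timepoint (default 10).
#' @param config A [training_config()].
#' @param labels Optional replacement label table (`colony_id`, `class`),
#'   e.g. from [randomize_labels()], applied to all frames.
#' @return A tibble with one row per (timepoint, repeat): columns
#'   `timepoint`, `repeat_id`, `val_accuracy` and list-column `fit`;
#'   attribute `n_classes`.
#' @export
train_timepoint_models <- function(features, timepoints = NULL, repeats = 10,
                                   config = training_config(),
                                   labels = NULL) {
  if (!is.null(labels)) {
    features <- dplyr::select(features, -"class")
    features <- dplyr::inner_join(
      features, dplyr::select(labels, "colony_id", "class"), by = "colony_id")
  }
  if (is.null(timepoints)) timepoints <- sort(unique(features$timepoint))
  class_levels <- sort(unique(features$class))

  rows <- purrr::map(timepoints, function(tp) {
    fr <- dplyr::arrange(features[features$timepoint == tp, ], .data$colony_id)
    x <- do.call(rbind, fr$features)
    purrr::map(seq_len(repeats), function(r) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, as.integer(tp), r)
      fit <- train_tdanet(x, fr$class, cfg, class_levels = class_levels,
                          ids = fr$colony_id)
      tibble::tibble(timepoint = as.integer(tp), repeat_id = r,
                     val_accuracy = fit$best_val_accuracy, fit = list(fit))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "n_classes") <- length(class_levels)
  out
}

#' Validation-set report for trained models
#'
#' Evaluates every trained model on its own held-out colonies and reports
#' the averaged confusion matrix and per-class precision/recall/F1 per
#' timepoint.
#'
#' @param models Output of [train_timepoint_models()].
#' @param features The feature table the models were trained from.
#' @return A list with `metrics` (long tibble: timepoint, class,
#'   precision, recall, f1, degenerate), `accuracy` (tibble: timepoint,
#'   mean validation accuracy), and `confusion` (named list of averaged
#'   `confusion_matrix` objects, one per timepoint).
#' @export
timepoint_report <- function(models, features) {
  class_levels <- sort(unique(features$class))
  by_tp <- split(seq_len(nrow(models)), models$timepoint)

  confusions <- lapply(by_tp, function(idx) {
    mats <- lapply(idx, function(i) {
      fit <- models$fit[[i]]
      tp <- models$timepoint[i]
      fr <- features[features$timepoint == tp, ]
      keep <- fr$colony_id %in% fit$split$validation
      x <- do.call(rbind, fr$features[keep])
      pred <- predict(fit, x, type = "class")
      confusion(pred, fr$class[keep], classes = class_levels)
    })
    average_confusion(mats)
  })

  metrics <- dplyr::bind_rows(lapply(names(confusions), function(tp) {
    dplyr::mutate(class_metrics(confusions[[tp]]),
                  timepoint = as.integer(tp), .before = 1)
  }))
  acc <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(models[c("timepoint", "val_accuracy")]),
                    .data$timepoint),
    mean_val_accuracy = mean(.data$val_accuracy), .groups = "drop")
  list(metrics = metrics, accuracy = acc, confusion = confusions)
}
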