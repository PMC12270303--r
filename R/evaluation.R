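#' Classification accuracy
#'
#' @param predictions Predicted class labels.
#' @param labels True class labels, same length.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0 || length(predictions) != length(labels)) {
    abort("predictions and labels must be nonempty and the same length",
          class = "colonytda_invalid_input")
  }
  mean(as.character(predictions) == as.character(labels))
}

#' Confusion matrix
#'
#' Cell `(i, j)` counts items whose true class is `i` and predicted class
#' is `j`. Matrices from repeated models can be averaged elementwise with
#' [average_confusion()], matching the convention of reporting the average
#' number of colonies per cell.
#'
#' @inheritParams accuracy
#' @param classes Ordered class list; every label and prediction must be a
#'   member.
#' @return A `confusion_matrix`: numeric matrix with dimnames
#'   `true`/`predicted`.
#' @export
confusion <- function(predictions, labels, classes = NULL) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(c(labels, predictions)))
  if (!all(c(labels, predictions) %in% classes)) {
    abort("labels or predictions outside the declared class list",
          class = "colonytda_invalid_label")
  }
  m <- table(factor(labels, classes), factor(predictions, classes))
  m <- matrix(as.numeric(m), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @rdname confusion
#' @param matrices List of conformable `confusion_matrix` objects.
#' @export
average_confusion <- function(matrices) {
  stopifnot(length(matrices) > 0)
  out <- Reduce(`+`, matrices) / length(matrices)
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Per-class precision, recall and F1
#'
#' Standard one-vs-rest definitions: precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, and their harmonic mean
#' `F1 = 2 * precision * recall / (precision + recall)`. A class never
#' predicted (or never present, or with zero F1 denominator) gets metric 0
#' and `degenerate = TRUE`.
#'
#' @param cm A `confusion_matrix` from [confusion()].
#' @return A tibble with columns `class`, `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @export
class_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0)) {
    abort("cm must be a square non-negative confusion matrix",
          class = "colonytda_invalid_input")
  }
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tibble::tibble(
    class = classes,
    precision = unname(precision),
    recall = unname(recall),
    f1 = unname(f1),
    degenerate = unname(tp + fp == 0 | tp + fn == 0 |
                          precision + recall == 0)
  )
}

#' Cross-timepoint accuracy grid
#'
#' For every training timepoint `T`, a model is trained on the colonies of
#' frame `T` (80/20 split by default, the cross-time preset) and evaluated
#' on the data of every test timepoint `S`: on the full colony set for
#' `S != T`, and on the held-out validation colonies only for `S = T`.
#'
#' @param features A feature table from [compute_features()]: one row per
#'   colony per timepoint with columns `colony_id`, `class`, `timepoint`
#'   and list-column `features`.
#' @param train_timepoints,test_timepoints Timepoints to use (defaults:
#'   all present).
#' @param config A [training_config()]; defaults to [crosstime_config()].
#' @param repeats Models trained per timepoint; accuracies are averaged.
#' @return An `accuracy_grid` tibble with columns `train_timepoint`,
#'   `test_timepoint`, `accuracy`.
#' @export
cross_time_grid <- function(features,
                            train_timepoints = NULL,
                            test_timepoints = NULL,
                            config = crosstime_config(),
                            repeats = 1) {
  tps <- sort(unique(features$timepoint))
  if (is.null(train_timepoints)) train_timepoints <- tps
  if (is.null(test_timepoints)) test_timepoints <- tps
  if (!all(c(train_timepoints, test_timepoints) %in% tps)) {
    abort("requested timepoints missing from the feature table",
          class = "colonytda_invalid_config")
  }
  dims <- unique(purrr::map_int(features$features, length))
  if (length(dims) != 1) {
    abort("feature dimension differs across timepoints",
          class = "colonytda_invalid_config")
  }

  frame_matrix <- function(tp) {
    fr <- dplyr::arrange(features[features$timepoint == tp, ], .data$colony_id)
    list(x = do.call(rbind, fr$features), y = fr$class, ids = fr$colony_id)
  }
  frames <- lapply(setNames(tps, tps), frame_matrix)
  class_levels <- sort(unique(features$class))

  rows <- purrr::map(train_timepoints, function(T) {
    accs <- matrix(0, nrow = repeats, ncol = length(test_timepoints))
    for (r in seq_len(repeats)) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, as.integer(T), r)
      fr <- frames[[as.character(T)]]
      fit <- train_tdanet(fr$x, fr$y, cfg, class_levels = class_levels,
                          ids = fr$ids)
      for (si in seq_along(test_timepoints)) {
        S <- test_timepoints[si]
        fs <- frames[[as.character(S)]]
        if (S == T) {
          keep <- fs$ids %in% fit$split$validation
          pred <- predict(fit, fs$x[keep, , drop = FALSE], type = "class")
          accs[r, si] <- accuracy(pred, fs$y[keep])
        } else {
          pred <- predict(fit, fs$x, type = "class")
          accs[r, si] <- accuracy(pred, fs$y)
        }
      }
    }
    tibble::tibble(
      train_timepoint = as.integer(T),
      test_timepoint = as.integer(test_timepoints),
      accuracy = colMeans(accs)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("accuracy_grid", class(out))
  out
}

#' Time-differential accuracy metric
#'
#' `<T,S> = Acc_T(S) - Acc_{S*}(S)`, where `S* = S - offset` is a nearby
#' earlier timepoint (default offset 10 frames = 50 minutes at 5-minute
#' spacing). It measures how much accuracy a `T`-trained model preserves on
#' frame `S` relative to a model trained just before `S`. The metric is
#' defined for distinct timepoints only, so `T = S` entries are undefined,
#' as are entries whose `S*` is not in the grid (`NA`, never extrapolated).
#'
#' @param grid An `accuracy_grid` from [cross_time_grid()].
#' @param offset Frames between `S` and `S*`.
#' @return A tibble `train_timepoint`, `test_timepoint`, `differential`
#'   with values in `[-1, 1]` or `NA` at undefined boundary entries.
#' @export
time_differential <- function(grid, offset = 10) {
  ref <- dplyr::transmute(
    grid,
    star_timepoint = .data$train_timepoint,
    test_timepoint = .data$test_timepoint,
    ref_accuracy = .data$accuracy
  )
  out <- dplyr::mutate(grid, star = .data$test_timepoint - offset)
  out <- dplyr::left_join(
    out,
    dplyr::rename(ref, star = "star_timepoint"),
    by = c("star", "test_timepoint")
  )
  dplyr::transmute(
    out,
    train_timepoint = .data$train_timepoint,
    test_timepoint = .data$test_timepoint,
    differential = ifelse(.data$train_timepoint == .data$test_timepoint,
                          NA_real_,
                          .data$accuracy - .data$ref_accuracy)
  )
}

#' Plot a cross-time accuracy grid
#'
#' @param object An `accuracy_grid`.
#' @param ... Unused.
#' @return A ggplot tile plot of `Acc_T(S)`.
#' @export
autoplot.accuracy_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$test_timepoint,
                                       .data$train_timepoint,
                                       fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Test timepoint S", y = "Train timepoint T",
                  fill = "Acc") +
    ggplot2::theme_minimal()
}

#' Accuracy-versus-timepoint curve
#'
#' @param results A tibble with columns `timepoint` and `val_accuracy`
#'   (e.g. from [train_timepoint_models()]).
#' @return A ggplot of mean validation accuracy over timepoints with a
#'   chance-level reference line.
#' @export
plot_accuracy_curve <- function(results) {
  n_classes <- if (!is.null(attr(results, "n_classes")))
    attr(results, "n_classes") else 5
  summ <- dplyr::summarise(
    dplyr::group_by(results, .data$timepoint),
    mean_accuracy = mean(.data$val_accuracy),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(.data$timepoint, .data$mean_accuracy)) +
    ggplot2::geom_hline(yintercept = 1 / n_classes, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Timepoint", y = "Mean validation accuracy") +
    ggplot2::theme_minimal()
}
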