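#' Build the TDANet architecture specification
#'
#' A four-layer feedforward classifier: three dense 20-neuron hidden layers
#' with ReLU activation and an `n_classes`-neuron softmax output layer,
#' trained with categorical cross-entropy. The input is a flattened
#' persistence-landscape matrix.
#'
#' @param input_dim Flattened input dimension (e.g. 800 for 20 landscape
#'   functions x 40 sample points, 1600 for 40 x 40).
#' @param n_classes Number of output classes (default 5).
#' @param hidden Hidden layer widths.
#' @return A `tdanet_spec` with `layer_sizes`, activations and loss.
#' @export
build_tdanet <- function(input_dim, n_classes = 5, hidden = c(20, 20, 20)) {
  if (input_dim < 1 || n_classes < 2 || any(hidden < 1)) {
    abort("layer sizes must be positive and n_classes >= 2",
          class = "colonytda_invalid_spec")
  }
  structure(
    list(
      layer_sizes = as.integer(c(input_dim, hidden, n_classes)),
      hidden_activation = "relu",
      output_activation = "softmax",
      loss = "categorical_crossentropy"
    ),
    class = "tdanet_spec"
  )
}

#' @export
print.tdanet_spec <- function(x, ...) {
  cat(sprintf("<tdanet_spec> layers %s (%s hidden, %s output), %s parameters\n",
              paste(x$layer_sizes, collapse = "-"),
              x$hidden_activation, x$output_activation,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a dense network
#'
#' Sum over consecutive layer pairs of `fan_in * fan_out + fan_out`
#' (weights plus biases). The canonical landscape classifier with an
#' 800-dimensional input has 16,965 parameters.
#'
#' @param spec A `tdanet_spec`, or an integer vector of layer sizes.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  sizes <- if (inherits(spec, "tdanet_spec")) spec$layer_sizes else as.integer(spec)
  if (length(sizes) < 2) {
    abort("need at least two layers", class = "colonytda_invalid_spec")
  }
  fan_in <- sizes[-length(sizes)]
  fan_out <- sizes[-1]
  sum(fan_in * fan_out + fan_out)
}

#' Count parameters of a replaced classification head
#'
#' The dense output layer that replaces the final layer of a frozen
#' pretrained image backbone: `feature_dim * n_classes + n_classes`. For a
#' 512-feature backbone and 5 classes this is 2,565 — the only trainable
#' parameters when everything else is frozen.
#'
#' @param feature_dim Backbone feature dimension.
#' @param n_classes Number of classes.
#' @return Integer parameter count.
#' @export
count_head_parameters <- function(feature_dim, n_classes) {
  if (feature_dim < 1 || n_classes < 1) {
    abort("dimensions must be positive", class = "colonytda_invalid_spec")
  }
  as.integer(feature_dim * n_classes + n_classes)
}

#' Parameter count of the 18-layer residual image classifier
#'
#' Closed-form arithmetic for the standard 18-layer residual network
#' (7x7 stem convolution, four stages of two basic blocks with batch
#' normalisation and 1x1 downsampling projections, 512-feature average
#' pool) with its fully connected output layer replaced by an
#' `n_classes`-way head. With a 5-class head the total is 11,179,077.
#'
#' @param n_classes Number of classes in the replacement head.
#' @return Integer total parameter count.
#' @export
count_resnet18_parameters <- function(n_classes = 5) {
  conv <- function(cin, cout, k) cin * cout * k * k   # no conv biases
  bn <- function(c) 2 * c                             # scale + shift
  basic_block <- function(cin, cout, downsample) {
    p <- conv(cin, cout, 3) + bn(cout) + conv(cout, cout, 3) + bn(cout)
    if (downsample) p <- p + conv(cin, cout, 1) + bn(cout)
    p
  }
  stage <- function(cin, cout) {
    basic_block(cin, cout, downsample = cin != cout) +
      basic_block(cout, cout, downsample = FALSE)
  }
  backbone <- conv(3, 64, 7) + bn(64) +
    stage(64, 64) + stage(64, 128) + stage(128, 256) + stage(256, 512)
  as.integer(backbone + count_head_parameters(512, n_classes))
}

#' Training configuration
#'
#' @param train_fraction Fraction of colonies used for training (default
#'   0.70; the cross-time experiments use the `crosstime` preset, 0.80).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Consecutive validation-accuracy decreases before early
#'   stopping (default 5).
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 16).
#' @param stratify Stratify the split by class (default FALSE: plain
#'   randomised split).
#' @param seed RNG seed controlling the split, initialisation and batch
#'   order.
#' @return A `training_config` list.
#' @export
training_config <- function(train_fraction = 0.70, max_epochs = 200,
                            patience = 5, optimizer = "adam",
                            learning_rate = 1e-3, batch_size = 16,
                            stratify = FALSE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)", class = "colonytda_invalid_spec")
  }
  if (max_epochs < 1 || patience < 1) {
    abort("max_epochs and patience must be >= 1",
          class = "colonytda_invalid_spec")
  }
  optimizer <- match.arg(optimizer, "adam")
  structure(
    list(train_fraction = train_fraction, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), optimizer = optimizer,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         stratify = isTRUE(stratify), seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Preset configuration for the cross-time experiments
#'
#' The cross-timepoint accuracy grids use an 80/20 train/validation split;
#' everything else matches [training_config()].
#'
#' @param ... Overrides passed to [training_config()].
#' @return A `training_config`.
#' @export
crosstime_config <- function(...) {
  args <- modifyList(list(train_fraction = 0.80), list(...))
  do.call(training_config, args)
}

#' Random train/validation split
#'
#' The validation side gets `ceiling((1 - train_fraction) * n)` items so
#' that 77 colonies at 0.70 split 53/24; both sides must be nonempty.
#'
#' @param ids Vector of item identifiers (e.g. colony ids).
#' @param train_fraction Fraction assigned to training.
#' @param seed RNG seed.
#' @param labels Optional class labels aligned with `ids`; when given and
#'   `stratify = TRUE` the split is stratified by class.
#' @param stratify Stratify by `labels`.
#' @return List with elements `train` and `validation` (disjoint,
#'   exhaustive subsets of `ids`).
#' @export
split_train_val <- function(ids, train_fraction = 0.70, seed = 1L,
                            labels = NULL, stratify = FALSE) {
  n <- length(ids)
  if (n < 2) {
    abort("need at least two items to split", class = "colonytda_invalid_split")
  }
  n_val <- ceiling((1 - train_fraction) * n - 1e-9)
  if (n_val == 0 || n_val == n) {
    abort("split leaves one side empty", class = "colonytda_invalid_split")
  }
  val_idx <- with_private_seed(seed, {
    if (stratify && !is.null(labels)) {
      unlist(lapply(split(seq_len(n), labels), function(idx) {
        k <- max(1L, round(length(idx) * (1 - train_fraction)))
        sample(idx, min(k, length(idx) - 1L))
      }), use.names = FALSE)
    } else {
      sample(n, n_val)
    }
  })
  list(train = ids[-val_idx], validation = ids[val_idx])
}

#' Randomise colony labels uniformly
#'
#' Each colony is independently assigned a label drawn uniformly from the
#' class set (i.i.d. draws, not a permutation), fixed across timepoints;
#' the original labels are retained for audit.
#'
#' @param labels A label table: tibble with `colony_id` and `class`.
#' @param classes Class set to draw from (default: classes present).
#' @param seed RNG seed.
#' @return The label table with `class` randomised and the original in
#'   `true_class`.
#' @export
randomize_labels <- function(labels, classes = NULL, seed = 1L) {
  if (nrow(labels) == 0) {
    abort("label table is empty", class = "colonytda_invalid_input")
  }
  if (is.null(classes)) classes <- sort(unique(labels$class))
  new_lab <- with_private_seed(seed,
    sample(classes, nrow(labels), replace = TRUE))
  dplyr::mutate(labels, true_class = .data$class, class = new_lab)
}
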