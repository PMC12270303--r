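# Dense feedforward network engine: ReLU hidden layers, softmax output,
# categorical cross-entropy, Adam updates on shuffled mini-batches. Written
# in plain matrix code; the networks involved are tiny (tens of thousands
# of parameters, tens of samples).

init_params <- function(sizes) {
  n_layers <- length(sizes) - 1
  lapply(seq_len(n_layers), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    # He-style initialisation for the ReLU layers, Glorot for the output
    sd <- if (l < n_layers) sqrt(2 / fan_in) else sqrt(2 / (fan_in + fan_out))
    list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

forward_pass <- function(params, x) {
  n_layers <- length(params)
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < n_layers) pmax(z, 0) else softmax_rows(z)
  }
  acts
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Gradient of mean cross-entropy w.r.t. all weights, by backpropagation.
backward_pass <- function(params, acts, y_onehot) {
  n_layers <- length(params)
  n <- nrow(y_onehot)
  grads <- vector("list", n_layers)
  delta <- (acts[[n_layers + 1]] - y_onehot) / n   # softmax + CE shortcut
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

cross_entropy <- function(prob, y_onehot) {
  -mean(rowSums(y_onehot * log(pmax(prob, 1e-12))))
}

adam_state <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW_hat <- s$mW / (1 - beta1^t); vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t); vb_hat <- s$vb / (1 - beta2^t)
    params[[l]]$W <- params[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

one_hot <- function(y, levels) {
  m <- matrix(0, length(y), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(y), match(as.character(y), levels))] <- 1
  m
}

#' Train the landscape classifier
#'
#' Splits the samples into train/validation sets, minimises categorical
#' cross-entropy with Adam on shuffled mini-batches, records per-epoch
#' train/validation accuracy, stops early after `patience` consecutive
#' decreases in validation accuracy (or at `max_epochs`), and returns the
#' parameters of the epoch with the highest validation accuracy (earliest
#' epoch on ties). Fully reproducible given `config$seed`.
#'
#' @param x Numeric feature matrix, one row per sample (flattened landscape
#'   matrices).
#' @param y Class labels (character or factor), one per row of `x`.
#' @param config A [training_config()].
#' @param class_levels Class set fixing the output order (default: sorted
#'   unique labels).
#' @param ids Optional sample identifiers recorded with the split.
#' @return A `tdanet_fit`: network spec, best parameters, per-epoch
#'   history, best epoch/accuracy, split membership and config.
#' @export
train_tdanet <- function(x, y, config = training_config(),
                         class_levels = NULL, ids = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) {
    abort("x and y lengths differ", class = "colonytda_invalid_input")
  }
  if (is.null(class_levels)) class_levels <- sort(unique(y))
  if (is.null(ids)) ids <- seq_len(nrow(x))

  split <- split_train_val(seq_len(nrow(x)), config$train_fraction,
                           seed = derive_seed(config$seed, 1L),
                           labels = y, stratify = config$stratify)
  tr <- split$train; va <- split$validation
  if (length(unique(y[tr])) < 2) {
    abort("training split contains a single class",
          class = "colonytda_degenerate_split")
  }

  spec <- build_tdanet(ncol(x), length(class_levels))
  y_tr <- one_hot(y[tr], class_levels)

  with_private_seed(derive_seed(config$seed, 2L), {
    params <- init_params(spec$layer_sizes)
    state <- adam_state(params)
    step <- 0L
    history <- vector("list", config$max_epochs)
    best <- list(acc = -Inf, epoch = 0L, params = params)
    decreases <- 0L
    prev_val <- NULL

    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- sample(length(tr))
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / config$batch_size))
      for (batch in batches) {
        acts <- forward_pass(params, x[tr[batch], , drop = FALSE])
        grads <- backward_pass(params, acts,
                               y_tr[batch, , drop = FALSE])
        step <- step + 1L
        upd <- adam_step(params, grads, state, config$learning_rate, step)
        params <- upd$params; state <- upd$state
      }
      prob_tr <- forward_pass(params, x[tr, , drop = FALSE])[[length(params) + 1]]
      prob_va <- forward_pass(params, x[va, , drop = FALSE])[[length(params) + 1]]
      acc_tr <- mean(class_levels[max.col(prob_tr)] == y[tr])
      acc_va <- mean(class_levels[max.col(prob_va)] == y[va])
      loss_tr <- cross_entropy(prob_tr, one_hot(y[tr], class_levels))
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = loss_tr,
        train_accuracy = acc_tr, val_accuracy = acc_va
      )
      if (acc_va > best$acc) {
        best <- list(acc = acc_va, epoch = epoch, params = params)
      }
      if (!is.null(prev_val) && acc_va < prev_val) {
        decreases <- decreases + 1L
      } else {
        decreases <- 0L
      }
      prev_val <- acc_va
      if (decreases >= config$patience) break
    }

    structure(
      list(
        spec = spec,
        params = best$params,
        class_levels = class_levels,
        history = dplyr::bind_rows(history),
        best_epoch = best$epoch,
        best_val_accuracy = best$acc,
        split = list(train = ids[tr], validation = ids[va]),
        split_index = list(train = tr, validation = va),
        config = config
      ),
      class = "tdanet_fit"
    )
  })
}

#' @export
print.tdanet_fit <- function(x, ...) {
  cat(sprintf(
    "<tdanet_fit> layers %s; %d epochs run; best val accuracy %.3f (epoch %d)\n",
    paste(x$spec$layer_sizes, collapse = "-"), nrow(x$history),
    x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' Predict class probabilities from a trained classifier
#'
#' @param object A `tdanet_fit`.
#' @param newdata Feature matrix (rows = samples) or a single flattened
#'   feature vector; column count must match the trained input dimension.
#' @param type `"prob"` for per-class probability vectors (rows sum to 1),
#'   `"class"` for argmax labels.
#' @param ... Unused.
#' @return Probability matrix or character vector of classes.
#' @export
predict.tdanet_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$layer_sizes[1]) {
    abort(sprintf("feature dimension %d does not match model input %d",
                  ncol(newdata), object$spec$layer_sizes[1]),
          class = "colonytda_invalid_input")
  }
  prob <- forward_pass(object$params, newdata)[[length(object$params) + 1]]
  colnames(prob) <- object$class_levels
  if (type == "class") object$class_levels[max.col(prob)] else prob
}

#' @describeIn train_tdanet Per-epoch training history as a tibble.
#' @param x A `tdanet_fit`.
#' @param ... Unused.
#' @export
tidy.tdanet_fit <- function(x, ...) x$history

#' @describeIn train_tdanet One-row model summary.
#' @export
glance.tdanet_fit <- function(x, ...) {
  tibble::tibble(
    n_parameters = count_parameters(x$spec),
    n_train = length(x$split$train),
    n_validation = length(x$split$validation),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_accuracy = x$best_val_accuracy
  )
}
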