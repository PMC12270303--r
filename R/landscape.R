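#' Default landscape sample grid
#'
#' The filtration parameter is sampled at the integer values 1..40; beyond
#' 40 (and beyond the 40th landscape function) colony barcodes carry little
#' information at the package's coordinate scale.
#'
#' @return Integer vector `1:40`.
#' @export
default_grid <- function() 1:40

#' Triangle (tent) function of a persistence bar
#'
#' The piecewise-linear function supported on `(b, d)` that rises with
#' slope 1 to its peak `(d - b) / 2` at the midpoint and falls back with
#' slope -1; the building block of the persistence landscape.
#'
#' @param b,d Finite birth and death, `b < d`.
#' @param t Evaluation point(s), `t >= 0`; vectorised.
#' @return Numeric vector of tent values.
#' @export
triangle_function <- function(b, d, t) {
  if (length(b) != 1 || length(d) != 1 || !is.finite(b) || !is.finite(d)) {
    abort("b and d must be single finite values",
          class = "colonytda_invalid_input")
  }
  if (d <= b) {
    abort("death must exceed birth", class = "colonytda_invalid_bar")
  }
  pmax(0, pmin(t - b, d - t))
}

finite_bars <- function(bars) {
  if (inherits(bars, "persistence_diagram") || is.data.frame(bars)) {
    bars <- bars[is.finite(bars$death), c("birth", "death"), drop = FALSE]
  } else if (is.matrix(bars)) {
    bars <- as.data.frame(bars[is.finite(bars[, 2]), , drop = FALSE])
    names(bars) <- c("birth", "death")
  } else {
    abort("bars must be a data frame or matrix with birth and death",
          class = "colonytda_invalid_input")
  }
  bars
}

# Tent values of all bars at all grid points: one row per bar.
tent_matrix <- function(bars, t) {
  if (nrow(bars) == 0) return(matrix(0, nrow = 0, ncol = length(t)))
  tm <- outer(bars$birth, t, function(b, tt) tt - b)
  dm <- outer(bars$death, t, function(d, tt) d - tt)
  pmax(matrix(0, nrow(tm), ncol(tm)), pmin(tm, dm))
}

#' k-th persistence landscape function at a point
#'
#' `lambda_k(t)` is the k-th largest tent-function value over all finite
#' bars; with fewer than `k` bars (or fewer than `k` positive values) it
#' is 0.
#'
#' @param bars Finite bars: a data frame/tibble with columns `birth`,
#'   `death` (a `persistence_diagram` is accepted; infinite bars are
#'   excluded).
#' @param k Landscape function index, `k >= 1`.
#' @param t Evaluation point(s); vectorised.
#' @return Numeric vector of landscape values.
#' @export
landscape_value <- function(bars, k, t) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("k must be a positive integer", class = "colonytda_invalid_index")
  }
  bars <- finite_bars(bars)
  vals <- tent_matrix(bars, t)
  apply_kmax(vals, k)
}

# k-th largest of each column of a (bars x t) matrix, 0 when exhausted.
apply_kmax <- function(vals, k) {
  if (nrow(vals) < k) return(rep(0, ncol(vals)))
  apply(vals, 2, function(col) sort(col, decreasing = TRUE)[k])
}

#' Persistence landscape matrix of a diagram
#'
#' Samples the first `n_functions` landscape functions of each selected
#' homology dimension on the grid and stacks them into the classifier's
#' input matrix: entry `(i, j)` is `lambda_i(t_j)`. With both dimensions
#' selected the dimension-0 block is stacked above the dimension-1 block
#' and `n_functions` applies per dimension (default 20 each, 40 for a
#' single dimension). Infinite-death bars are excluded.
#'
#' @param diagram A `persistence_diagram` (or data frame with `dimension`,
#'   `birth`, `death`).
#' @param dims_used Homology dimensions to featurise: `0`, `1`, or `c(0, 1)`.
#' @param sample_points Strictly increasing positive grid of filtration
#'   values (default `1:40`).
#' @param n_functions Landscape functions per dimension; default 40 for a
#'   single dimension, 20 per dimension when combined.
#' @return A `landscape_matrix`: numeric matrix (functions x grid) with
#'   attributes `dims_used`, `sample_points`, `colony_id`, `timepoint`.
#' @export
landscape_matrix <- function(diagram, dims_used = c(0, 1),
                             sample_points = default_grid(),
                             n_functions = NULL) {
  if (length(sample_points) < 1 || any(sample_points <= 0) ||
      any(diff(sample_points) <= 0)) {
    abort("sample_points must be strictly increasing and positive",
          class = "colonytda_invalid_input")
  }
  dims_used <- sort(unique(as.integer(dims_used)))
  if (!all(dims_used %in% c(0L, 1L))) {
    abort("dims_used must be a subset of {0, 1}",
          class = "colonytda_invalid_input")
  }
  if (is.null(n_functions)) {
    n_functions <- if (length(dims_used) == 1) 40L else 20L
  }
  if (n_functions < 1) {
    abort("n_functions must be at least 1", class = "colonytda_invalid_input")
  }

  blocks <- lapply(dims_used, function(dim) {
    bars <- finite_bars(diagram[diagram$dimension == dim, , drop = FALSE])
    vals <- tent_matrix(bars, sample_points)
    block <- matrix(0, nrow = n_functions, ncol = length(sample_points))
    if (nrow(vals) > 0) {
      kmax <- min(n_functions, nrow(vals))
      sorted <- apply(vals, 2, function(col)
        sort(col, decreasing = TRUE)[seq_len(kmax)])
      sorted <- matrix(sorted, nrow = kmax)
      block[seq_len(kmax), ] <- sorted
    }
    rownames(block) <- sprintf("dim%d_lambda%d", dim, seq_len(n_functions))
    block
  })
  out <- do.call(rbind, blocks)
  colnames(out) <- sprintf("t%g", sample_points)
  attr(out, "dims_used") <- dims_used
  attr(out, "sample_points") <- as.double(sample_points)
  attr(out, "n_functions") <- n_functions
  attr(out, "colony_id") <- attr(diagram, "colony_id", exact = TRUE)
  attr(out, "timepoint") <- attr(diagram, "timepoint", exact = TRUE)
  class(out) <- c("landscape_matrix", class(out))
  out
}

#' @export
print.landscape_matrix <- function(x, ...) {
  cat(sprintf("<landscape_matrix> %d functions x %d sample points (dims %s)\n",
              nrow(x), ncol(x),
              paste(attr(x, "dims_used"), collapse = ",")))
  invisible(x)
}

#' Plot landscape functions
#'
#' One line per landscape function over the sample grid, faceted by
#' homology dimension.
#'
#' @param object A `landscape_matrix`.
#' @param max_functions Plot at most this many functions per dimension.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.landscape_matrix <- function(object, max_functions = 10, ...) {
  t <- attr(object, "sample_points")
  df <- as.data.frame(unclass(object))
  df$fn <- rownames(object)
  long <- tidyr::pivot_longer(df, -"fn", names_to = "t", values_to = "value")
  long$t <- rep(t, times = nrow(object))
  long$dimension <- sub("_.*", "", long$fn)
  long$k <- as.integer(sub(".*lambda", "", long$fn))
  long <- long[long$k <= max_functions, ]
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     group = .data$fn,
                                     colour = .data$k)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~dimension) +
    ggplot2::labs(x = "Filtration value t", y = expression(lambda[k](t)),
                  colour = "k") +
    ggplot2::theme_minimal()
}
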