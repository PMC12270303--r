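#' Pairwise Euclidean distance matrix of a point cloud
#'
#' @param cloud A point cloud: any data frame with numeric columns `x`, `y`
#'   (or a two-column matrix).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(cloud) {
  xy <- as_xy_matrix(cloud)
  as.matrix(stats::dist(xy))
}

as_xy_matrix <- function(cloud) {
  if (is.matrix(cloud)) {
    xy <- cloud
  } else if (is.data.frame(cloud)) {
    if (!all(c("x", "y") %in% names(cloud))) {
      abort("point cloud must have columns x and y",
            class = "colonytda_invalid_input")
    }
    xy <- cbind(cloud$x, cloud$y)
  } else {
    abort("point cloud must be a data frame or matrix",
          class = "colonytda_invalid_input")
  }
  if (nrow(xy) < 1) {
    abort("point cloud must contain at least one point",
          class = "colonytda_invalid_input")
  }
  if (!all(is.finite(xy))) {
    abort("point cloud contains non-finite coordinates",
          class = "colonytda_invalid_input")
  }
  storage.mode(xy) <- "double"
  xy
}

validate_dist_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    abort("distance matrix must be square", class = "colonytda_invalid_input")
  }
  if (!all(is.finite(dm)) || any(dm < 0) || any(abs(diag(dm)) > 0) ||
      !isTRUE(all.equal(dm, t(dm), tolerance = 1e-12))) {
    abort("distance matrix must be finite, non-negative, symmetric with zero diagonal",
          class = "colonytda_invalid_input")
  }
  dm
}

new_diagram <- function(dimension, birth, death, threshold) {
  out <- tibble::tibble(
    dimension = as.integer(dimension),
    birth = as.double(birth),
    death = as.double(death)
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("persistence_diagram", class(out))
  out
}

#' Dimension-0 persistence barcode
#'
#' Connected-component persistence of the Rips filtration, computed by a
#' union-find sweep over edges in increasing length order with the elder
#' rule (the younger component dies at each merge; index ties go to the
#' smaller point index). All components are born at 0; the multiset of
#' finite deaths equals the edge-weight multiset of a Euclidean minimum
#' spanning tree, and exactly one essential bar survives to infinity.
#' Zero-length bars (from duplicated points) are dropped.
#'
#' @param dm A distance matrix from [pairwise_distances()].
#' @return A `persistence_diagram` tibble (`dimension`, `birth`, `death`)
#'   with `dimension == 0`.
#' @export
h0_barcode <- function(dm) {
  dm <- validate_dist_matrix(dm)
  res <- .rips_pairs_cpp(dm, -1)
  deaths <- sort(res$h0_deaths)
  deaths <- deaths[deaths > 0]
  new_diagram(0L, rep(0, length(deaths) + 1), c(deaths, Inf), Inf)
}

#' Dimension-1 persistence barcode
#'
#' Loop persistence of the Rips filtration restricted to simplices of
#' dimension at most 2 with filtration value at most `threshold`, by
#' standard boundary-matrix reduction over the two-element field. A
#' simplex's filtration value is the maximum pairwise distance of its
#' vertices. Bars still alive at the threshold are reported with death
#' `Inf`; zero-length bars are dropped.
#'
#' @inheritParams h0_barcode
#' @param threshold Positive maximum filtration value.
#' @return A `persistence_diagram` tibble with `dimension == 1`.
#' @export
h1_barcode <- function(dm, threshold) {
  dm <- validate_dist_matrix(dm)
  if (!is.finite(threshold) || threshold <= 0) {
    abort("threshold must be positive", class = "colonytda_invalid_input")
  }
  res <- .rips_pairs_cpp(dm, threshold)
  h1 <- res$h1
  ord <- order(h1[, "birth"], h1[, "death"])
  new_diagram(1L, h1[ord, "birth"], h1[ord, "death"], threshold)
}

#' Persistence diagram of a point cloud (dimensions 0 and 1)
#'
#' Computes the Rips filtration of the cloud and returns the union of the
#' dimension-0 and dimension-1 barcodes. The default threshold is twice the
#' maximum of the default landscape grid, which is sufficient for landscape
#' values on the grid to equal their full-filtration values: bars born above
#' the grid maximum `G` contribute nothing on `[0, G]`, and for `t <= G`
#' only the rising edge `t - b` of a bar with death `>= 2G` is ever sampled.
#'
#' @param cloud A point cloud (data frame with `x`, `y`, or matrix).
#' @param threshold Positive maximum filtration value for dimension 1.
#' @return A `persistence_diagram` tibble with attributes `threshold`,
#'   `colony_id`, `timepoint`.
#' @export
compute_diagram <- function(cloud, threshold = 2 * max(default_grid())) {
  dm <- pairwise_distances(cloud)
  if (!is.finite(threshold) || threshold <= 0) {
    abort("threshold must be positive", class = "colonytda_invalid_input")
  }
  res <- .rips_pairs_cpp(dm, threshold)
  deaths <- sort(res$h0_deaths)
  deaths <- deaths[deaths > 0]
  h1 <- res$h1
  ord <- order(h1[, "birth"], h1[, "death"])
  out <- new_diagram(
    c(rep(0L, length(deaths) + 1), rep(1L, nrow(h1))),
    c(rep(0, length(deaths) + 1), h1[ord, "birth"]),
    c(deaths, Inf, h1[ord, "death"]),
    threshold
  )
  attr(out, "colony_id") <- attr(cloud, "colony_id", exact = TRUE)
  attr(out, "timepoint") <- attr(cloud, "timepoint", exact = TRUE)
  out
}

#' @export
print.persistence_diagram <- function(x, ...) {
  n0 <- sum(x$dimension == 0)
  n1 <- sum(x$dimension == 1)
  cat(sprintf("<persistence_diagram> %d bars (H0: %d, H1: %d), threshold %g\n",
              nrow(x), n0, n1, attr(x, "threshold")))
  NextMethod()
}

#' Plot a persistence diagram
#'
#' Birth/death scatter with the diagonal; essential (infinite-death) bars
#' are drawn at the top margin with triangular markers.
#'
#' @param object A `persistence_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.persistence_diagram <- function(object, ...) {
  finite <- object[is.finite(object$death), ]
  ess <- object[!is.finite(object$death), ]
  top <- max(c(finite$death, finite$birth, 1)) * 1.05
  ess$death <- top
  df <- rbind(
    cbind(as.data.frame(finite), essential = FALSE),
    cbind(as.data.frame(ess), essential = TRUE)
  )
  df$dimension <- factor(df$dimension)
  ggplot2::ggplot(df, ggplot2::aes(.data$birth, .data$death,
                                   colour = .data$dimension,
                                   shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(x = "Birth", y = "Death", colour = "Dimension") +
    ggplot2::theme_minimal()
}
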