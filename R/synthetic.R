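#' Treatment classes and their spatial motifs
#'
#' The five differentiation treatments are distinguished by qualitative
#' spatial motifs of the cell layout: wild-type colonies are a homogeneous
#' disk; BMP4- and CHIR-treated colonies develop a sparse boundary "fringe";
#' dual-SMAD-inhibited (DS) colonies develop low-density circular "rosette"
#' voids; combined DS+CHIR colonies grow a visibly larger footprint.
#'
#' @return Character vector of the five canonical class names.
#' @export
treatment_classes <- function() {
  c("WT", "BMP4", "CHIR", "DS", "DS+CHIR")
}

# Motif assigned to each canonical class. Unknown classes cycle through the
# motif list so that arbitrary class sets remain separable.
class_motif <- function(classes) {
  canonical <- c(
    "WT" = "uniform", "BMP4" = "fringe", "CHIR" = "fringe",
    "DS" = "rosette", "DS+CHIR" = "enlarged"
  )
  motifs <- canonical[classes]
  pool <- c("uniform", "rosette", "fringe", "enlarged")
  unknown <- which(is.na(motifs))
  if (length(unknown) > 0) {
    motifs[unknown] <- pool[((seq_along(unknown) - 1) %% length(pool)) + 1]
  }
  unname(motifs)
}

#' Specify one synthetic colony
#'
#' A colony is a planar point pattern of cell centroids. At timepoint 0 every
#' class draws from the same homogeneous disk; the class motif emerges
#' linearly with time and is fully expressed from `differentiation_time`
#' onwards. Coordinates are in image units scaled so typical
#' nearest-neighbour spacing is a few units, which places topological
#' features inside the default landscape grid 1..40.
#'
#' @param class_label Treatment class name (any string; see
#'   [treatment_classes()] for the canonical five).
#' @param n_cells Number of cells (points). The real study's colonies carry
#'   500--2000 cells; the desk-scale default is smaller.
#' @param footprint_radius Colony radius in coordinate units.
#' @param motif One of `"uniform"`, `"fringe"`, `"rosette"`, `"enlarged"`;
#'   defaults to the motif conventionally associated with `class_label`.
#' @param fringe_width Width of the sparse boundary annulus (fringe motif).
#' @param fringe_density_ratio Target ratio of annulus density to interior
#'   density at full expression, in (0, 1].
#' @param rosette_count Number of circular exclusion voids (rosette motif).
#' @param rosette_radius Radius of each rosette void.
#' @param enlargement Footprint scale factor at full expression
#'   (enlarged motif).
#' @param differentiation_time Timepoint index at which the motif is fully
#'   expressed; 0 means fully expressed at every frame.
#' @param seed RNG seed for this colony.
#'
#' @return An object of class `colony_spec`.
#' @export
colony_spec <- function(class_label,
                        n_cells = 200,
                        footprint_radius = 50,
                        motif = NULL,
                        fringe_width = 10,
                        fringe_density_ratio = 0.35,
                        rosette_count = 3,
                        rosette_radius = 12,
                        enlargement = 1.4,
                        differentiation_time = 10,
                        seed = 1L) {
  if (is.null(motif)) motif <- class_motif(class_label)
  motif <- match.arg(motif, c("uniform", "fringe", "rosette", "enlarged"))
  num <- c(
    n_cells = n_cells, footprint_radius = footprint_radius,
    fringe_width = fringe_width, fringe_density_ratio = fringe_density_ratio,
    rosette_count = rosette_count, rosette_radius = rosette_radius,
    enlargement = enlargement, differentiation_time = differentiation_time
  )
  if (any(!is.finite(num))) {
    abort("all colony_spec parameters must be finite", class = "colonytda_invalid_spec")
  }
  if (n_cells < 1) {
    abort("n_cells must be at least 1", class = "colonytda_invalid_spec")
  }
  if (footprint_radius <= 0) {
    abort("footprint_radius must be positive", class = "colonytda_invalid_spec")
  }
  if (motif == "fringe" &&
      (fringe_width <= 0 || fringe_width >= footprint_radius ||
       fringe_density_ratio <= 0 || fringe_density_ratio > 1)) {
    abort("fringe parameters out of range", class = "colonytda_invalid_spec")
  }
  if (motif == "rosette" &&
      (rosette_count < 1 || rosette_radius <= 0 ||
       1.2 * rosette_radius >= footprint_radius)) {
    abort("rosette disks must fit inside the footprint",
          class = "colonytda_invalid_spec")
  }
  if (motif == "enlarged" && enlargement < 1) {
    abort("enlargement must be >= 1", class = "colonytda_invalid_spec")
  }
  structure(
    list(
      class_label = as.character(class_label),
      n_cells = as.integer(n_cells),
      footprint_radius = footprint_radius,
      motif = motif,
      fringe_width = fringe_width,
      fringe_density_ratio = fringe_density_ratio,
      rosette_count = rosette_count,
      rosette_radius = rosette_radius,
      enlargement = enlargement,
      differentiation_time = differentiation_time,
      seed = as.integer(seed)
    ),
    class = "colony_spec"
  )
}

#' @export
print.colony_spec <- function(x, ...) {
  cat(sprintf("<colony_spec> class %s, motif %s, %d cells, radius %g\n",
              x$class_label, x$motif, x$n_cells, x$footprint_radius))
  invisible(x)
}

# Place rosette centres inside the footprint, pairwise separated by at least
# 2.2 radii so displaced cells can never fall inside a neighbouring void.
place_rosettes <- function(spec) {
  rmax <- spec$footprint_radius - 1.2 * spec$rosette_radius
  with_private_seed(derive_seed(spec$seed, 991L), {
    centres <- matrix(numeric(0), ncol = 2)
    attempts <- 0L
    while (nrow(centres) < spec$rosette_count && attempts < 10000L) {
      attempts <- attempts + 1L
      r <- rmax * sqrt(runif(1))
      a <- 2 * pi * runif(1)
      cand <- c(r * cos(a), r * sin(a))
      if (nrow(centres) == 0 ||
          all(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) >=
              2.2 * spec$rosette_radius)) {
        centres <- rbind(centres, cand)
      }
    }
    if (nrow(centres) < spec$rosette_count) {
      abort("could not place non-overlapping rosettes inside the footprint",
            class = "colonytda_invalid_spec")
    }
    centres
  })
}

#' Generate one colony point cloud at one timepoint
#'
#' Deterministic for a fixed `(spec, timepoint)` pair: each frame is an
#' independent draw from the colony's morphology at that time, seeded from
#' the colony seed and the frame index. Motif strength grows linearly from 0
#' at timepoint 0 to 1 at `differentiation_time`.
#'
#' The motifs are simple generative models: homogeneous Poisson-style
#' scatter on a disk (uniform); a boundary annulus whose density is a fixed
#' ratio of the interior density (fringe); hard-core circular exclusion
#' voids whose trapped cells are displaced to the void rim (rosette); and a
#' scaled footprint radius (enlarged).
#'
#' @param spec A [colony_spec()].
#' @param timepoint Non-negative frame index (frames are 5 minutes apart in
#'   the imaging convention this mirrors).
#' @param colony_id Identifier stored on the result.
#'
#' @return A `point_cloud`: a tibble with columns `x`, `y` and attributes
#'   `colony_id`, `timepoint`, `label`.
#' @export
generate_colony <- function(spec, timepoint, colony_id = spec$class_label) {
  stopifnot(inherits(spec, "colony_spec"))
  if (!is.finite(timepoint) || timepoint < 0) {
    abort("timepoint must be a non-negative number",
          class = "colonytda_invalid_input")
  }
  s <- if (spec$differentiation_time <= 0) 1 else
    min(1, timepoint / spec$differentiation_time)
  n <- spec$n_cells
  R <- spec$footprint_radius

  pts <- with_private_seed(derive_seed(spec$seed, as.integer(timepoint)), {
    u1 <- runif(n); u2 <- runif(n); u3 <- runif(n); u4 <- runif(n)
    switch(spec$motif,
      uniform = {
        r <- R * sqrt(u1); a <- 2 * pi * u2
        cbind(r * cos(a), r * sin(a))
      },
      enlarged = {
        Reff <- R * (1 + s * (spec$enlargement - 1))
        r <- Reff * sqrt(u1); a <- 2 * pi * u2
        cbind(r * cos(a), r * sin(a))
      },
      fringe = {
        Ri <- R - spec$fringe_width
        rho <- 1 - s * (1 - spec$fringe_density_ratio)
        a_ann <- R^2 - Ri^2   # areas up to the common factor pi
        a_int <- Ri^2
        p_ann <- rho * a_ann / (a_int + rho * a_ann)
        in_ann <- u1 < p_ann
        r <- ifelse(in_ann, sqrt(Ri^2 + u2 * (R^2 - Ri^2)), Ri * sqrt(u2))
        a <- 2 * pi * u3
        cbind(r * cos(a), r * sin(a))
      },
      rosette = {
        centres <- place_rosettes(spec)
        r <- R * sqrt(u1); a <- 2 * pi * u2
        xy <- cbind(r * cos(a), r * sin(a))
        re <- s * spec$rosette_radius
        if (re > 0) {
          for (ci in seq_len(nrow(centres))) {
            dx <- xy[, 1] - centres[ci, 1]
            dy <- xy[, 2] - centres[ci, 2]
            d <- sqrt(dx^2 + dy^2)
            inside <- d < re
            if (any(inside)) {
              # displace to just outside the void rim, radially
              scl <- re * (1.02 + 0.08 * u3[inside]) / pmax(d[inside], 1e-9)
              xy[inside, 1] <- centres[ci, 1] + dx[inside] * scl
              xy[inside, 2] <- centres[ci, 2] + dy[inside] * scl
            }
          }
        }
        xy
      }
    )
  })

  out <- tibble::tibble(x = pts[, 1], y = pts[, 2])
  attr(out, "colony_id") <- as.character(colony_id)
  attr(out, "timepoint") <- as.integer(timepoint)
  attr(out, "label") <- spec$class_label
  class(out) <- c("point_cloud", class(out))
  out
}

#' Generate a labelled multi-colony time-series dataset
#'
#' One point-cloud time series per colony, with per-colony specs derived
#' reproducibly from a single master seed. Default class counts mirror the
#' study design this emulates (78 colonies over five treatments).
#'
#' @param class_counts Named integer vector, class name -> number of
#'   colonies.
#' @param n_timepoints Number of frames per colony (frame indices
#'   `1..n_timepoints`).
#' @param master_seed Master RNG seed; everything else derives from it.
#' @param n_cells Mean cells per colony; individual colonies vary uniformly
#'   within +/- 15%.
#' @param differentiation_time Frame at which motifs are fully expressed
#'   (default: the midpoint of the series, rounded up). Use 0 for a
#'   time-invariant dataset whose motifs are always fully expressed.
#' @param ... Further arguments passed to [colony_spec()] (e.g.
#'   `footprint_radius`).
#'
#' @return A tibble with one row per colony per frame: columns `colony_id`,
#'   `class`, `timepoint`, and `points` (list of point-cloud tibbles).
#' @export
generate_dataset <- function(class_counts = c("WT" = 12, "BMP4" = 16, "CHIR" = 16,
                                              "DS" = 17, "DS+CHIR" = 17),
                             n_timepoints = 1,
                             master_seed = 1L,
                             n_cells = 200,
                             differentiation_time = NULL,
                             ...) {
  if (length(class_counts) == 0 || any(class_counts < 0) ||
      sum(class_counts) == 0) {
    abort("class_counts must contain at least one colony",
          class = "colonytda_empty_dataset")
  }
  if (n_timepoints < 1) {
    abort("n_timepoints must be at least 1", class = "colonytda_invalid_input")
  }
  if (is.null(differentiation_time)) {
    differentiation_time <- ceiling(n_timepoints / 2)
  }
  classes <- names(class_counts)
  if (is.null(classes)) {
    abort("class_counts must be named by class",
          class = "colonytda_invalid_input")
  }
  motifs <- setNames(class_motif(classes), classes)

  colonies <- purrr::imap(class_counts, function(count, cls) {
    if (count == 0) return(NULL)
    purrr::map(seq_len(count), function(i) {
      list(id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", cls), i),
           class = cls, index = i)
    })
  })
  colonies <- unname(purrr::compact(purrr::flatten(colonies)))

  # CHIR fringes are wider and denser than BMP4 fringes so the two fringe
  # classes remain (imperfectly) separable, mirroring their partial
  # confusability in practice.
  rows <- purrr::map(seq_along(colonies), function(idx) {
    col <- colonies[[idx]]
    seed_i <- derive_seed(master_seed, idx)
    jitter <- with_private_seed(derive_seed(seed_i, 7L),
                                runif(1, 0.85, 1.15))
    extra <- list(...)
    args <- list(
      class_label = col$class,
      motif = motifs[[col$class]],
      n_cells = max(1L, as.integer(round(n_cells * jitter))),
      differentiation_time = differentiation_time,
      seed = seed_i
    )
    if (motifs[[col$class]] == "fringe" && col$class == "CHIR" &&
        is.null(extra$fringe_width) && is.null(extra$fringe_density_ratio)) {
      args$fringe_width <- 16
      args$fringe_density_ratio <- 0.6
    }
    spec <- do.call(colony_spec, modifyList(args, extra))
    purrr::map(seq_len(n_timepoints), function(tp) {
      tibble::tibble(
        colony_id = col$id,
        class = col$class,
        timepoint = as.integer(tp),
        points = list(generate_colony(spec, tp, colony_id = col$id))
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Label table of a dataset
#'
#' @param dataset A dataset tibble from [generate_dataset()].
#' @return A tibble with one row per colony: `colony_id`, `class`.
#' @export
dataset_labels <- function(dataset) {
  dplyr::distinct(dataset, .data$colony_id, .data$class)
}
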