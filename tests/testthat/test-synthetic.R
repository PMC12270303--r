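test_that("colony generation is deterministic and respects the spec", {
  spec <- colony_spec("DS", seed = 42)
  a <- generate_colony(spec, 3)
  b <- generate_colony(spec, 3)
  expect_identical(a, b)
  expect_false(identical(generate_colony(spec, 4)$x, a$x))

  cl <- generate_colony(colony_spec("WT", n_cells = 1000, seed = 1), 0)
  expect_equal(nrow(cl), 1000)
  expect_true(nrow(cl) >= 500 && nrow(cl) <= 2000)
  expect_true(all(is.finite(cl$x)) && all(is.finite(cl$y)))
})

test_that("invalid colony specs are rejected", {
  expect_error(colony_spec("WT", n_cells = 0), class = "colonytda_invalid_spec")
  expect_error(colony_spec("WT", footprint_radius = -1),
               class = "colonytda_invalid_spec")
  expect_error(colony_spec("DS", rosette_radius = 100),
               class = "colonytda_invalid_spec")
  expect_error(colony_spec("WT", footprint_radius = Inf),
               class = "colonytda_invalid_spec")
  expect_error(generate_colony(colony_spec("WT"), -1),
               class = "colonytda_invalid_input")
})

test_that("rosette voids are empty once the motif is fully expressed", {
  spec <- colony_spec("DS", differentiation_time = 6, seed = 9)
  cl <- generate_colony(spec, 6)
  centres <- colonytda:::place_rosettes(spec)
  for (ci in seq_len(nrow(centres))) {
    d <- sqrt((cl$x - centres[ci, 1])^2 + (cl$y - centres[ci, 2])^2)
    expect_true(all(d >= spec$rosette_radius))
  }
  # cells stay inside the footprint despite displacement
  expect_true(all(sqrt(cl$x^2 + cl$y^2) <= spec$footprint_radius + 1e-9))
})

test_that("fringe annulus reaches the configured density ratio", {
  spec <- colony_spec("BMP4", n_cells = 4000, differentiation_time = 5,
                      seed = 2)
  cl <- generate_colony(spec, 5)
  r <- sqrt(cl$x^2 + cl$y^2)
  R <- spec$footprint_radius
  Ri <- R - spec$fringe_width
  dens_ann <- sum(r >= Ri) / (pi * (R^2 - Ri^2))
  dens_int <- sum(r < Ri) / (pi * Ri^2)
  expect_equal(dens_ann / dens_int, spec$fringe_density_ratio,
               tolerance = 0.15)
})

test_that("dataset generation yields the study's colony counts and is reproducible", {
  ds <- generate_dataset(n_timepoints = 1, master_seed = 5, n_cells = 30)
  labs <- dataset_labels(ds)
  expect_equal(nrow(labs), 78)
  expect_equal(as.vector(table(labs$class)[c("WT", "BMP4", "CHIR", "DS", "DS+CHIR")]),
               c(12, 16, 16, 17, 17))
  ds2 <- generate_dataset(n_timepoints = 1, master_seed = 5, n_cells = 30)
  expect_identical(ds, ds2)

  small <- generate_dataset(c(A = 1), n_timepoints = 3, master_seed = 1,
                            n_cells = 20)
  expect_equal(nrow(small), 3)
  expect_equal(unique(small$colony_id), "A_01")

  expect_error(generate_dataset(c(A = 0)), class = "colonytda_empty_dataset")
})

test_that("rosette clouds carry more prominent loops than uniform clouds", {
  prominent <- function(motif, seed) {
    sp <- colony_spec("X", motif = motif, seed = seed,
                      differentiation_time = 0)
    d <- compute_diagram(generate_colony(sp, 1))
    h1 <- d[d$dimension == 1 & is.finite(d$death), ]
    sum(h1$death - h1$birth > 10)
  }
  ros <- vapply(1:20, function(s) prominent("rosette", s), numeric(1))
  uni <- vapply(1:20, function(s) prominent("uniform", s), numeric(1))
  expect_gt(mean(ros), mean(uni))
})

test_that("classes are indistinguishable before differentiation", {
  stats_of <- function(class, seed) {
    cl <- generate_colony(colony_spec(class, seed = seed,
                                      differentiation_time = 10), 0)
    dm <- pairwise_distances(cl)
    diag(dm) <- Inf
    c(radius = max(sqrt(cl$x^2 + cl$y^2)), nn = mean(apply(dm, 1, min)))
  }
  per_class <- lapply(treatment_classes(), function(cls)
    t(vapply(1:12, function(s) stats_of(cls, s), numeric(2))))
  radii <- vapply(per_class, function(m) mean(m[, "radius"]), numeric(1))
  nn <- vapply(per_class, function(m) mean(m[, "nn"]), numeric(1))
  expect_lt(diff(range(radii)) / mean(radii), 0.05)
  expect_lt(diff(range(nn)) / mean(nn), 0.10)
})
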