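test_that("triangle function matches its piecewise-linear definition", {
  expect_equal(triangle_function(2, 6, 4), 2)
  expect_equal(triangle_function(2, 6, 1), 0)
  expect_equal(triangle_function(2, 6, 7), 0)
  expect_equal(triangle_function(2, 6, 3), 1)
  expect_equal(triangle_function(2, 6, 5), 1)
  expect_equal(triangle_function(2, 6, 2), 0)  # closed at the left endpoint
  expect_error(triangle_function(6, 2, 3), class = "colonytda_invalid_bar")
  expect_error(triangle_function(1, Inf, 3),
               class = "colonytda_invalid_input")
})

test_that("landscape values take the k-th largest tent", {
  one <- tibble::tibble(birth = 0, death = 4)
  expect_equal(landscape_value(one, 1, 2), 2)
  expect_equal(landscape_value(one, 2, c(0, 1, 2, 3)), rep(0, 4))
  two <- tibble::tibble(birth = c(0, 2), death = c(4, 6))
  expect_equal(landscape_value(two, 2, 3), 1)
  expect_error(landscape_value(two, 0, 3), class = "colonytda_invalid_index")
})

test_that("landscape matrix reproduces the unit-square worked example", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  dg <- compute_diagram(sq, threshold = 3)
  lm <- landscape_matrix(dg, dims_used = 1, sample_points = c(1, 1.2, sqrt(2)),
                         n_functions = 3)
  expect_equal(unname(lm[1, ]), c(0, 0.2, 0))
  expect_equal(unname(lm[2, ]), rep(0, 3))
  expect_equal(unname(lm[3, ]), rep(0, 3))
})

test_that("empty bar sets give an all-zero matrix, not an error", {
  dg <- compute_diagram(data.frame(x = 0, y = 0), threshold = 3)
  lm <- landscape_matrix(dg, dims_used = c(0, 1))
  expect_true(all(lm == 0))
  expect_equal(dim(lm), c(40, 40))
})

test_that("combined dimensions stack dim-0 above dim-1 with per-dim functions", {
  cl <- random_cloud(30, 2, scale = 20)
  dg <- compute_diagram(cl, threshold = 80)
  lm <- landscape_matrix(dg, dims_used = c(0, 1))
  expect_equal(nrow(lm), 40)
  expect_true(all(grepl("^dim0", rownames(lm)[1:20])))
  expect_true(all(grepl("^dim1", rownames(lm)[21:40])))
  single <- landscape_matrix(dg, dims_used = 1)
  expect_equal(nrow(single), 40)
  expect_equal(unname(single[1:20, ]), unname(lm[21:40, ]))
})

test_that("landscapes are monotone in k and 1-Lipschitz in t", {
  fine <- seq(0.5, 40, by = 0.5)
  for (seed in 1:5) {
    cl <- random_cloud(40, seed + 30, scale = 25)
    dg <- compute_diagram(cl, threshold = 80)
    for (d in 0:1) {
      lm <- landscape_matrix(dg, dims_used = d, sample_points = fine,
                             n_functions = 10)
      expect_true(all(diff(unclass(lm)) <= 1e-12))        # lambda_k >= lambda_{k+1}
      steps <- abs(t(diff(t(unclass(lm)))))
      expect_true(all(steps <= 0.5 + 1e-9))               # 1-Lipschitz on the grid
      expect_true(all(lm >= 0))
    }
  }
})

test_that("landscapes vanish outside the support of the finite bars", {
  cl <- random_cloud(25, 77, scale = 15)
  dg <- compute_diagram(cl, threshold = 80)
  bars <- dg[dg$dimension == 1 & is.finite(dg$death), ]
  lo <- min(bars$birth); hi <- max(bars$death)
  t <- c(lo - 1, lo, hi, hi + 1)
  expect_equal(landscape_value(bars, 1, t), rep(0, 4))
})

test_that("landscape matrices match the brute-force evaluator on random barcodes", {
  for (seed in 1:8) {
    set.seed(seed + 500)
    nb <- sample(1:30, 1)
    b <- runif(nb, 0, 30)
    bars <- tibble::tibble(dimension = 1L, birth = b,
                           death = b + runif(nb, 0.1, 15))
    grid <- sort(runif(12, 0, 45))
    lm <- landscape_matrix(bars, dims_used = 1, sample_points = grid,
                           n_functions = 8)
    for (k in c(1, 3, 8)) {
      expect_equal(unname(lm[k, ]), oracle_landscape(bars, k, grid))
    }
  }
})

test_that("the 2G threshold yields the same matrix as a much larger threshold", {
  for (seed in 1:4) {
    cl <- generate_colony(colony_spec("DS", seed = seed,
                                      differentiation_time = 0), 1)
    a <- landscape_matrix(compute_diagram(cl, threshold = 80))
    b <- landscape_matrix(compute_diagram(cl, threshold = 1e6))
    expect_equal(unclass(a)[, ], unclass(b)[, ], tolerance = 1e-12)
  }
})
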