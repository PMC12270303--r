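test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(c("a", "b", "a", "b", "b"),
                        c("a", "b", "b", "a", "b")), 0.6)
  expect_error(accuracy(character(0), character(0)),
               class = "colonytda_invalid_input")
  expect_error(accuracy("a", c("a", "b")), class = "colonytda_invalid_input")
})

test_that("confusion matrices count, average and reduce to accuracy", {
  pred <- c("A", "A", "B", "B", "A")
  true <- c("A", "B", "B", "B", "A")
  cm <- confusion(pred, true, classes = c("A", "B"))
  expect_equal(unclass(cm)[, ],
               matrix(c(2, 1, 0, 2), 2, 2,
                      dimnames = list(true = c("A", "B"),
                                      predicted = c("A", "B"))))
  expect_equal(sum(diag(cm)) / sum(cm), accuracy(pred, true))

  perfect <- confusion(true, true, classes = c("A", "B"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))

  avg <- average_confusion(list(cm, perfect))
  expect_equal(unname(unclass(avg)[1, 1]), (2 + 2) / 2)

  expect_error(confusion(c("A", "Z"), c("A", "A"), classes = c("A", "B")),
               class = "colonytda_invalid_label")
})

test_that("per-class metrics follow the standard formulas", {
  cm <- matrix(c(5, 2, 0, 3), 2, 2,
               dimnames = list(true = c("c1", "c2"),
                               predicted = c("c1", "c2")))
  m <- class_metrics(cm)
  expect_equal(m$precision[m$class == "c1"], 5 / 7, tolerance = 1e-12)
  expect_equal(m$recall[m$class == "c1"], 1)
  expect_equal(m$f1[m$class == "c1"], 2 * (5 / 7) / (1 + 5 / 7),
               tolerance = 1e-12)

  perfect <- diag(3)
  dimnames(perfect) <- list(true = letters[1:3], predicted = letters[1:3])
  mp <- class_metrics(perfect)
  expect_true(all(mp$precision == 1 & mp$recall == 1 & mp$f1 == 1))
  expect_false(any(mp$degenerate))

  # class never present and never predicted: zeros with a flag
  cm0 <- matrix(c(4, 0, 0, 0), 2, 2,
                dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  m0 <- class_metrics(cm0)
  expect_equal(m0$precision[2], 0)
  expect_equal(m0$recall[2], 0)
  expect_equal(m0$f1[2], 0)
  expect_true(m0$degenerate[2])
})

test_that("micro-averaged recall equals accuracy", {
  set.seed(13)
  for (i in 1:5) {
    classes <- c("A", "B", "C", "D")
    true <- sample(classes, 60, TRUE)
    pred <- ifelse(runif(60) < 0.6, true, sample(classes, 60, TRUE))
    cm <- confusion(pred, true, classes)
    tp <- diag(cm)
    expect_equal(sum(tp) / sum(cm), accuracy(pred, true))
  }
})

test_that("time differential is the exact grid difference with NA boundaries", {
  grid <- tibble::tibble(
    train_timepoint = rep(1:3, each = 3),
    test_timepoint = rep(1:3, 3),
    accuracy = c(0.7, 0.7, 0.6, 0.5, 0.8, 0.7, 0.4, 0.6, 0.9)
  )
  class(grid) <- c("accuracy_grid", class(grid))
  d <- time_differential(grid, offset = 1)
  # reference is the S*-trained model, S* = S - 1: <T,S> = Acc_T(S) - Acc_{S*}(S)
  expect_equal(d$differential[d$train_timepoint == 3 & d$test_timepoint == 2],
               0.6 - 0.7)
  expect_equal(d$differential[d$train_timepoint == 1 & d$test_timepoint == 3],
               0.6 - 0.7)
  # T = S* compares a model list with itself: identically zero
  expect_equal(d$differential[d$train_timepoint == 1 & d$test_timepoint == 2],
               0)
  expect_equal(d$differential[d$train_timepoint == 2 & d$test_timepoint == 3],
               0)
  # undefined where S* is off the grid or where T = S
  expect_true(all(is.na(d$differential[d$test_timepoint == 1])))
  expect_true(all(is.na(d$differential[d$train_timepoint ==
                                         d$test_timepoint])))
  ok <- !is.na(d$differential)
  expect_true(all(d$differential[ok] >= -1 & d$differential[ok] <= 1))
})

test_that("cross-time grids are flat for time-invariant data", {
  ds <- generate_dataset(setNames(c(4, 4), c("WT", "DS")), n_timepoints = 3,
                         master_seed = 21, n_cells = 60,
                         differentiation_time = 0)
  feats <- compute_features(ds, threshold = 40)
  grid <- cross_time_grid(feats,
                          config = crosstime_config(max_epochs = 40, seed = 2))
  expect_equal(nrow(grid), 9)
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  d <- time_differential(grid, offset = 1)
  expect_true(all(abs(d$differential) <= 1, na.rm = TRUE))
  # diagonal entries use only held-out colonies: 2 of 8, so accuracy is a
  # multiple of 1/2; off-diagonal uses all 8
  diag_acc <- grid$accuracy[grid$train_timepoint == grid$test_timepoint]
  expect_true(all(abs(diag_acc * 2 - round(diag_acc * 2)) < 1e-9))
})
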