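test_that("partitioning stratifies exactly on balanced class sizes", {
  d <- tibble::tibble(c1 = rep(c(1L, 2L), c(60, 40)))
  p <- partition_windows(d, frac = 0.75, seed = 1)
  tab <- table(p$split, p$c1)
  expect_equal(as.numeric(tab["learning", ]), c(45, 30))
  expect_equal(as.numeric(tab["test", ]), c(15, 10))
})

test_that("partitioning is deterministic, disjoint and exhaustive", {
  d <- tibble::tibble(c1 = sample(rep(1:4, 250)))
  p1 <- partition_windows(d, frac = 0.9, seed = 7)
  p2 <- partition_windows(d, frac = 0.9, seed = 7)
  expect_identical(p1$split, p2$split)
  expect_equal(sum(p1$split == "learning"), 900)
  expect_equal(sum(p1$split == "test"), 100)
})

test_that("singleton classes go to the learning split with a warning", {
  d <- tibble::tibble(c1 = c(rep(1L, 10), 7L))
  expect_warning(p <- partition_windows(d, seed = 1), "single member")
  expect_equal(as.character(p$split[11]), "learning")
})

test_that("scoring counts correct predictions and builds the confusion matrix", {
  s <- score_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$accuracy, 100)
  s <- score_predictions(rep(1, 100), rep(1:4, 25))
  expect_equal(s$accuracy, 25)
  set.seed(16)
  pred <- sample(1:4, 100, replace = TRUE)
  act <- c(pred[1:83], (sample(1:3, 17, replace = TRUE) + pred[84:100] - 1) %% 4 + 1)
  s <- score_predictions(pred, act)
  expect_equal(s$accuracy, 83)
  # confusion rows sum to the per-class actual counts
  expect_equal(
    as.numeric(rowSums(s$confusion)),
    as.numeric(table(factor(act, levels = sort(unique(c(pred, act))))))
  )
  expect_error(score_predictions(1:3, 1:4), "equal length")
})

test_that("scoring matches a naive recount on random label pairs", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    pred <- sample(1:8, n, replace = TRUE)
    act <- sample(1:8, n, replace = TRUE)
    expect_equal(score_predictions(pred, act)$accuracy, naive_accuracy(pred, act))
  }
})

test_that("partition sensitivity reproduces a single run and validates input", {
  study <- small_study()
  sens <- suppressWarnings(sensitivity_over_partitions(
    study$labels, study$features, fractions = 0.75, seeds = 1
  ))
  direct <- suppressWarnings(herdsense:::fit_split(
    study$labels, study$features, frac = 0.75, seed = 1
  ))
  expect_equal(
    sens$accuracy[sens$classifier == "S6"],
    direct$accuracies$accuracy[6]
  )
  expect_error(
    sensitivity_over_partitions(study$labels, study$features, seeds = integer(0)),
    "at least one seed"
  )
})

test_that("actual time follows the per-sample count times the sampling period", {
  w <- tibble::tibble(
    window = 1L, t_index = 0:14999, behavior = rep(c(1L, 5L), each = 7500)
  )
  tb <- time_budget(w, tibble::tibble(window = 1L, s6 = 1L))
  expect_equal(tb$per_class$actual_s[tb$per_class$behavior == 1], 300)
  expect_equal(tb$per_class$actual_s[tb$per_class$behavior == 5], 300)
  expect_equal(tb$per_class$estimated_s[tb$per_class$behavior == 1], 600)
})

test_that("perfect estimates on pure windows give zero error and 100% accuracy", {
  w <- tibble::tibble(
    window = rep(1:2, each = 15000), t_index = rep(0:14999, 2),
    behavior = rep(c(2L, 4L), each = 15000)
  )
  tb <- time_budget(w, tibble::tibble(window = 1:2, s6 = c(2L, 4L)))
  present <- tb$per_class$behavior %in% c(2, 4)
  expect_equal(tb$per_class$rel_error_pct[present], c(0, 0))
  expect_true(all(is.na(tb$per_class$rel_error_pct[!present])))
  expect_equal(tb$time_accuracy, 100)
})

test_that("a fully wrong estimate scores zero time accuracy", {
  w <- tibble::tibble(window = 1L, t_index = 0:14999, behavior = rep(2L, 15000))
  tb <- time_budget(w, tibble::tibble(window = 1L, s6 = 4L))
  expect_equal(tb$time_accuracy, 0)
  expect_equal(tb$per_class$estimated_s[tb$per_class$behavior == 4], 600)
})

test_that("per-window actual time sums to the window duration", {
  study <- small_study()
  per_window <- study$windows |>
    dplyr::count(window) |>
    dplyr::mutate(seconds = n / 25)
  expect_true(all(per_window$seconds == 600))
  tb <- study$time_budget
  expect_equal(sum(tb$per_class$actual_s), tb$n_windows * 600)
  expect_equal(sum(tb$per_class$estimated_s), tb$n_windows * 600)
})

test_that("the study object summarizes through tidy and glance", {
  study <- small_study()
  td <- tidy(study)
  expect_equal(td$classifier, paste0("S", 1:6))
  expect_true(all(td$accuracy >= 0 & td$accuracy <= 100))
  g <- glance(study)
  expect_equal(g$n_windows, nrow(study$labels))
  expect_true(g$time_accuracy >= 0 && g$time_accuracy <= 100)
  b <- tidy(study$fit$bank)
  expect_equal(b$classifier, paste0("S", 1:5))
  expect_true(all(b$n_leaves >= 1))
})
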