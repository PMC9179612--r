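#' Stratified learning/test partition
#'
#' Splits rows into a learning and a test set, preserving per-class
#' proportions within one item of exact stratification. Classes with a
#' single member go to the learning split with a warning; classes with at
#' least two members contribute at least one row to each split when the
#' rounding would empty one.
#'
#' @param data Data frame of windows (one row each).
#' @param frac Learning fraction in (0, 1) (default 0.75).
#' @param stratify_by Column name holding the actual class (default
#'   `"c1"`, the most frequent behavior of the window).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return `data` with an added `split` factor column
#'   (`"learning"` / `"test"`).
#' @examples
#' d <- tibble::tibble(c1 = rep(c(1, 2), c(60, 40)))
#' table(partition_windows(d, 0.75, seed = 1)$split, d$c1)
#' @export
partition_windows <- function(data, frac = 0.75, stratify_by = "c1", seed = 1L) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) abort("empty dataset.")
  if (frac <= 0 || frac >= 1) abort("`frac` must be in (0, 1).")
  if (!stratify_by %in% names(data)) {
    abort(sprintf("stratification column `%s` not found.", stratify_by))
  }
  set.seed(as.integer(seed))
  cls <- as.character(data[[stratify_by]])
  split <- character(nrow(data))
  for (k in sort(unique(cls))) {
    idx <- which(cls == k)
    n <- length(idx)
    if (n == 1L) {
      warn(sprintf("class %s has a single member; assigned to the learning split.", k))
      split[idx] <- "learning"
      next
    }
    n_learn <- round(frac * n)
    n_learn <- min(max(n_learn, 1L), n - 1L)
    learn <- sample(idx, n_learn)
    split[learn] <- "learning"
    split[setdiff(idx, learn)] <- "test"
  }
  data$split <- factor(split, levels = c("learning", "test"))
  data
}

#' Score predictions against actual labels
#'
#' @param predicted,actual Equal-length vectors of labels.
#' @return An object of class `herdsense_score`: list with `accuracy`
#'   (percent correct), `n`, and `confusion` (contingency table indexed
#'   actual x predicted).
#' @examples
#' score_predictions(c(1, 2, 2), c(1, 2, 3))
#' @export
score_predictions <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length.")
  }
  if (length(actual) == 0) abort("nothing to score.")
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  lev <- sort(unique(c(predicted, actual)))
  confusion <- table(
    actual = factor(actual, levels = lev),
    predicted = factor(predicted, levels = lev)
  )
  structure(
    list(
      accuracy = 100 * mean(predicted == actual),
      n = length(actual),
      confusion = confusion
    ),
    class = "herdsense_score"
  )
}

#' @export
print.herdsense_score <- function(x, ...) {
  cat(sprintf("<herdsense_score> accuracy %.2f%% on %d windows\n", x$accuracy, x$n))
  invisible(x)
}

# Fit the bank on one stratified split and score every classifier.
# `labels` must carry window, c1, c2, s1..s4 (s5 is re-derived from the
# learning-split pair frequencies to avoid leakage); `features` carries
# window + feature columns aligned by `window`.
fit_split <- function(labels, features, frac = 0.75, seed = 1L,
                      weights = rep(1, 5), flow = 0.01,
                      reduce = TRUE, threshold = 0.75,
                      config = tree_config()) {
  stopifnot(identical(labels$window, features$window))
  part <- partition_windows(labels, frac = frac, stratify_by = "c1", seed = seed)
  learn <- part$split == "learning"
  pf <- pair_frequency_table(part[learn, c("c1", "c2")])
  relump <- lump_class_pair(part[, c("c1", "c2")], pf, flow = flow)
  part$s5 <- paste0(relump$l1, relump$l2)
  subset <- NULL
  reduction <- NULL
  if (reduce) {
    reduction <- suppressWarnings(
      reduce_features(features[learn, , drop = FALSE], threshold = threshold)
    )
    subset <- reduction$selected
  }
  bank <- train_classifier_bank(
    features[learn, , drop = FALSE], part[learn, , drop = FALSE],
    feature_subset = subset, weights = weights, config = config
  )
  test <- part[part$split == "test", , drop = FALSE]
  test_feats <- features[part$split == "test", , drop = FALSE]
  preds <- predict_bank(bank, test_feats)
  comb <- combine_estimates(preds, weights = bank$weights)
  scores <- c(
    lapply(1:5, function(i) {
      score_predictions(preds[[paste0("s", i)]], test[[paste0("s", i)]])
    }),
    list(score_predictions(comb$s6, test$c1))
  )
  names(scores) <- paste0("S", 1:6)
  list(
    partition = part, pair_freqs = pf, reduction = reduction, bank = bank,
    test = test, predictions = comb, scores = scores,
    accuracies = tibble(
      classifier = paste0("S", 1:6),
      accuracy = map_dbl(scores, "accuracy")
    )
  )
}

#' Classifier accuracy across learning/test partitionings
#'
#' Re-runs the full fit (stratified split, leakage-free S5 relabeling,
#' feature reduction on the learning split, bank training, scoring) for
#' every combination of learning fraction and seed.
#'
#' @param labels Window label table ([window_labels()]).
#' @param features Window feature table ([window_features()]), aligned by
#'   `window`.
#' @param fractions Learning fractions (default `c(0.25, 0.5, 0.75, 0.9)`).
#' @param seeds Integer vector of partition seeds (at least one).
#' @param ... Passed on to the fitting routine (`weights`, `flow`,
#'   `reduce`, `threshold`, `config`).
#' @return Tibble with one row per (classifier, fraction, seed):
#'   `classifier`, `fraction`, `seed`, `accuracy`; summarize with e.g.
#'   `dplyr::summarise(mean(accuracy))` over seeds.
#' @export
sensitivity_over_partitions <- function(labels, features,
                                        fractions = c(0.25, 0.5, 0.75, 0.9),
                                        seeds = 1:5, ...) {
  if (length(seeds) == 0) abort("`seeds` must contain at least one seed.")
  if (length(fractions) == 0) abort("`fractions` must contain at least one fraction.")
  grid <- tidyr::expand_grid(fraction = fractions, seed = as.integer(seeds))
  purrr::pmap(grid, function(fraction, seed) {
    fit <- fit_split(labels, features, frac = fraction, seed = seed, ...)
    fit$accuracies |> mutate(fraction = fraction, seed = seed)
  }) |>
    list_rbind() |>
    select("classifier", "fraction", "seed", "accuracy")
}

#' Time budget: actual versus estimated time per behavior
#'
#' The actual time spent in behavior b within a window is the number of
#' samples labeled b times the sampling period (40 ms at 25 Hz). The
#' estimated time credits the whole window duration to the window's
#' combined estimate and zero to all other behaviors. The overall time
#' accuracy is `100 * (1 - sum_b |T_est,b - T_act,b| / (2 * sum_b
#' T_act,b))`, a normalized-L1 agreement between the two budgets; the mean
#' absolute per-class relative error is reported alongside.
#'
#' @param windows Windowed stream rows ([split_windows()]) restricted to
#'   the evaluated (e.g. test) windows.
#' @param estimates Tibble with columns `window` and `s6` (integer
#'   estimated class per window), e.g. from [combine_estimates()].
#' @param fs Sampling frequency in Hz (sampling period is `1/fs`).
#' @param tw Window duration in seconds.
#' @return An object of class `herdsense_timebudget`: list with
#'   `per_class` (tibble `behavior`, `actual_s`, `estimated_s`,
#'   `rel_error_pct` — signed, `NA` for classes with zero actual time),
#'   `time_accuracy` (percent), `mean_abs_rel_error_pct`, `n_windows`.
#' @examples
#' w <- tibble::tibble(window = 1, t_index = 0:14999,
#'                     behavior = rep(c(1L, 5L), each = 7500))
#' time_budget(w, tibble::tibble(window = 1, s6 = 1L))
#' @export
time_budget <- function(windows, estimates, fs = HS_FS, tw = 600) {
  stopifnot(
    is.data.frame(windows), all(c("window", "behavior") %in% names(windows)),
    is.data.frame(estimates), all(c("window", "s6") %in% names(estimates))
  )
  if (!setequal(unique(windows$window), estimates$window)) {
    abort("`estimates` must cover exactly the windows present in `windows`.")
  }
  dt <- 1 / fs
  actual <- windows |>
    count(.data$behavior, name = "n_samples") |>
    mutate(actual_s = .data$n_samples * dt) |>
    select("behavior", "actual_s")
  estimated <- estimates |>
    count(.data$s6, name = "n_windows") |>
    mutate(estimated_s = .data$n_windows * tw) |>
    select(behavior = "s6", "estimated_s")
  per_class <- tibble(behavior = 1:8) |>
    left_join(actual, by = "behavior") |>
    left_join(estimated, by = "behavior") |>
    mutate(
      actual_s = coalesce(.data$actual_s, 0),
      estimated_s = coalesce(.data$estimated_s, 0),
      rel_error_pct = if_else(
        .data$actual_s > 0,
        100 * (.data$estimated_s - .data$actual_s) / .data$actual_s,
        NA_real_
      )
    )
  time_accuracy <- 100 * (1 -
    sum(abs(per_class$estimated_s - per_class$actual_s)) /
      (2 * sum(per_class$actual_s)))
  structure(
    list(
      per_class = per_class,
      time_accuracy = time_accuracy,
      mean_abs_rel_error_pct = mean(abs(per_class$rel_error_pct), na.rm = TRUE),
      n_windows = length(unique(windows$window)),
      tw = tw, dt = dt
    ),
    class = "herdsense_timebudget"
  )
}

#' @export
print.herdsense_timebudget <- function(x, ...) {
  cat(sprintf(
    "<herdsense_timebudget> %d windows: time accuracy %.2f%% (mean |rel. error| %.2f%%)\n",
    x$n_windows, x$time_accuracy, x$mean_abs_rel_error_pct
  ))
  print(x$per_class)
  invisible(x)
}
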