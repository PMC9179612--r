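#' Run the full simulation-to-evaluation study
#'
#' End-to-end pipeline on synthetic data: for each seed, simulate a
#' decorated stream of `hours` hours, window it, label the windows and
#' extract features; pool all runs; then perform one stratified
#' learning/test fit (feature reduction and the S5 pair-frequency table are
#' computed on the learning split only), score the five classifiers and
#' the combined classifier under both the supplied weights and
#' accuracy-derived weights, and compute the time budget of the test
#' windows.
#'
#' @param hours Stream duration per run in hours (default 6).
#' @param seeds Integer seeds, one simulated run each (default 1:5).
#' @param signatures Per-behavior signatures (default
#'   [behavior_signatures()]).
#' @param schedule Base [schedule_config()]; its `duration_s` and `seed`
#'   are overridden per run.
#' @param tw,tsw Window and sub-window durations in seconds.
#' @param fmin,flow Labeling thresholds (see [assign_class_pair()],
#'   [lump_class_pair()]).
#' @param frac Learning fraction (default 0.75).
#' @param partition_seed Seed of the stratified split (default the first
#'   element of `seeds`).
#' @param weights Length-5 combiner weights (default all 1).
#' @param reduce,threshold Feature-reduction switches
#'   (see [reduce_features()]).
#' @param config Tree hyperparameters ([tree_config()]).
#' @return An object of class `herdsense_study`: list with `windows`
#'   (pooled windowed stream), `labels`, `features`, `fit` (the split fit:
#'   partition, reduction, bank, predictions, per-classifier scores),
#'   `accuracies`, `combined_accuracy`, `combined_accuracy_acc_weighted`,
#'   `time_budget`, and the run parameters.
#' @examples
#' \donttest{
#' study <- run_study(hours = 2, seeds = 1:2)
#' glance(study)
#' }
#' @export
run_study <- function(hours = 6, seeds = 1:5,
                      signatures = behavior_signatures(),
                      schedule = schedule_config(),
                      tw = 600, tsw = 5,
                      fmin = 0.4, flow = 0.01,
                      frac = 0.75, partition_seed = seeds[1],
                      weights = rep(1, 5),
                      reduce = TRUE, threshold = 0.75,
                      config = tree_config()) {
  stopifnot(length(seeds) >= 1)
  all_windows <- list()
  all_features <- list()
  offset <- 0L
  for (seed in seeds) {
    cfg <- schedule
    cfg$duration_s <- hours * 3600
    cfg$seed <- as.integer(seed)
    stream <- simulate_stream(cfg, signatures)
    win <- split_windows(stream, tw = tw)
    win$window <- win$window + offset
    feats <- window_features(win, tsw = tsw)
    offset <- max(win$window)
    all_windows[[length(all_windows) + 1L]] <- win
    all_features[[length(all_features) + 1L]] <- feats
  }
  windows <- list_rbind(all_windows)
  features <- list_rbind(all_features)
  labels <- window_labels(windows, fmin = fmin, flow = flow)

  fit <- fit_split(labels, features,
    frac = frac, seed = partition_seed, weights = weights,
    flow = flow, reduce = reduce, threshold = threshold, config = config
  )

  # accuracy-weighted combining for comparison with equal weights
  acc_w <- fit$accuracies$accuracy[1:5] / 100
  comb_acc <- combine_estimates(fit$predictions[paste0("s", 1:5)], weights = acc_w)
  acc_weighted <- score_predictions(comb_acc$s6, fit$test$c1)$accuracy

  test_windows <- windows |> filter(.data$window %in% fit$test$window)
  tb <- time_budget(
    test_windows,
    fit$predictions |> select("window", "s6"),
    tw = tw
  )

  structure(
    list(
      windows = windows, labels = labels, features = features,
      fit = fit,
      accuracies = fit$accuracies,
      combined_accuracy = fit$accuracies$accuracy[6],
      combined_accuracy_acc_weighted = acc_weighted,
      time_budget = tb,
      params = list(
        hours = hours, seeds = seeds, tw = tw, tsw = tsw,
        fmin = fmin, flow = flow, frac = frac,
        partition_seed = partition_seed, threshold = threshold
      )
    ),
    class = "herdsense_study"
  )
}

#' @export
print.herdsense_study <- function(x, ...) {
  cat(sprintf(
    "<herdsense_study> %d windows (%d test), %d retained features\n",
    nrow(x$labels), nrow(x$fit$test),
    length(x$fit$bank$feature_subset)
  ))
  acc <- x$accuracies
  cat("  accuracy:", paste(sprintf("%s %.1f%%", acc$classifier, acc$accuracy),
    collapse = ", "
  ), "\n")
  cat(sprintf("  time accuracy: %.2f%%\n", x$time_budget$time_accuracy))
  invisible(x)
}
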