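#' Tidy a feature-reduction result
#'
#' @param x A `herdsense_reduction`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `retained`,
#'   `mean_abs_corr` (mean absolute correlation to all other features).
#' @method tidy herdsense_reduction
#' @export
tidy.herdsense_reduction <- function(x, ...) {
  fn <- colnames(x$correlation)
  tibble(
    feature = fn,
    retained = fn %in% x$selected,
    mean_abs_corr = map_dbl(fn, function(f) {
      mean(abs(x$correlation[f, setdiff(fn, f)]))
    })
  )
}

#' @rdname tidy.herdsense_reduction
#' @method glance herdsense_reduction
#' @export
glance.herdsense_reduction <- function(x, ...) {
  tibble(
    n_features = ncol(x$correlation),
    n_retained = length(x$selected),
    threshold = x$threshold
  )
}

#' Tidy a score: the confusion matrix in long form
#'
#' @param x A `herdsense_score`.
#' @param ... Unused.
#' @return Tibble `actual`, `predicted`, `n`.
#' @method tidy herdsense_score
#' @export
tidy.herdsense_score <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion)) |>
    rename(n = "Freq") |>
    mutate(across(c("actual", "predicted"), as.character))
}

#' @rdname tidy.herdsense_score
#' @method glance herdsense_score
#' @export
glance.herdsense_score <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n)
}

#' Tidy a classifier bank: one row per tree
#'
#' @param x A `herdsense_bank`.
#' @param ... Unused.
#' @return Tibble `classifier`, `weight`, `n_nodes`, `n_leaves`,
#'   `n_classes`.
#' @method tidy herdsense_bank
#' @export
tidy.herdsense_bank <- function(x, ...) {
  tibble(
    classifier = names(x$models),
    weight = x$weights,
    n_nodes = map_int(x$models, ~ nrow(.x$nodes)),
    n_leaves = map_int(x$models, ~ sum(is.na(.x$nodes$var))),
    n_classes = map_int(x$models, ~ length(.x$levels))
  )
}

#' Tidy a time budget: per-class actual vs estimated seconds
#'
#' @param x A `herdsense_timebudget`.
#' @param ... Unused.
#' @return The `per_class` tibble.
#' @method tidy herdsense_timebudget
#' @export
tidy.herdsense_timebudget <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.herdsense_timebudget
#' @method glance herdsense_timebudget
#' @export
glance.herdsense_timebudget <- function(x, ...) {
  tibble(
    time_accuracy = x$time_accuracy,
    mean_abs_rel_error_pct = x$mean_abs_rel_error_pct,
    n_windows = x$n_windows
  )
}

#' Tidy a study: per-classifier accuracies
#'
#' @param x A `herdsense_study`.
#' @param ... Unused.
#' @return `tidy()`: the per-classifier accuracy tibble. `glance()`: a
#'   one-row summary with the combined accuracies (equal and
#'   accuracy-derived weights), the time accuracy and the problem sizes.
#' @method tidy herdsense_study
#' @export
tidy.herdsense_study <- function(x, ...) {
  x$accuracies
}

#' @rdname tidy.herdsense_study
#' @method glance herdsense_study
#' @export
glance.herdsense_study <- function(x, ...) {
  tibble(
    n_windows = nrow(x$labels),
    n_test = nrow(x$fit$test),
    n_features_retained = length(x$fit$bank$feature_subset),
    combined_accuracy = x$combined_accuracy,
    combined_accuracy_acc_weighted = x$combined_accuracy_acc_weighted,
    time_accuracy = x$time_budget$time_accuracy
  )
}
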