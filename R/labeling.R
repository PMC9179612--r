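#' Class-set definitions for the five basic classifiers
#'
#' S1 is the finest classifier (all eight codes); S2 groups by rumination
#' (non-ruminating 1,2 / ruminating 3,4 / eating 5 / other 6,7,8); S3 by
#' posture (standing 1,3 / lying 2,4 / eating 5 / other 6,7,8); S4 by
#' eating (5 / non-eating 1--4 / other 6,7,8); S5 enumerates the 15 lumped
#' class pairs. A group label is the concatenation of its member codes
#' (e.g. `"678"` contains codes 6, 7 and 8).
#'
#' Definitions are shipped as a versioned YAML resource
#' (`extdata/class_sets.yaml`).
#'
#' @return Named list of character vectors of group labels, names
#'   `S1`..`S5`.
#' @examples
#' class_sets()$S2
#' @export
class_sets <- function() {
  path <- system.file("extdata", "class_sets.yaml", package = "herdsense")
  yaml::read_yaml(path)$sets
}

#' Behavior frequencies within a window
#'
#' Counts the per-sample behavior codes of one window and returns
#' behavior-frequency pairs sorted by descending frequency; ties are broken
#' by ascending behavior code.
#'
#' @param labels Integer vector of per-sample behavior codes (1--8), or a
#'   data frame with a `behavior` column.
#' @return Tibble with columns `behavior`, `freq` (fractions summing to 1),
#'   one row per behavior present.
#' @examples
#' behavior_frequencies(c(5, 5, 5, 1, 1))
#' @export
behavior_frequencies <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$behavior
  labels <- as.integer(labels)
  if (length(labels) == 0) abort("window has no labeled samples.")
  if (any(labels < 1L | labels > 8L)) abort("behavior codes must be in 1..8.")
  counts <- tabulate(labels, nbins = 8L)
  present <- which(counts > 0)
  freq <- counts[present] / length(labels)
  ord <- order(-freq, present)
  tibble(behavior = present[ord], freq = freq[ord])
}

#' Assign the class pair (C1, C2) of a window
#'
#' C1 is always the most frequent behavior. C2 is the second most frequent
#' behavior if its fraction reaches `fmin`; otherwise the second behavior is
#' not considered significant and C2 collapses to C1.
#'
#' @param freqs A behavior-frequency table from [behavior_frequencies()].
#' @param fmin Minimum fraction for the second behavior to count
#'   (default 0.4). Exposed as a parameter: sources disagree on whether the
#'   significance cut sits at 0.4 or 0.6 of the window.
#' @return Tibble with one row: `c1`, `c2` (integer codes), `f1`, `f2`
#'   (fractions; `f2` is 0 when only one behavior is present).
#' @examples
#' assign_class_pair(behavior_frequencies(c(rep(2, 55), rep(4, 45))))
#' @export
assign_class_pair <- function(freqs, fmin = 0.4) {
  if (!is.data.frame(freqs) || nrow(freqs) == 0) abort("empty frequency table.")
  if (fmin <= 0 || fmin >= 1) abort("`fmin` must be in (0, 1).")
  c1 <- freqs$behavior[1]
  f1 <- freqs$freq[1]
  if (nrow(freqs) >= 2 && freqs$freq[2] >= fmin) {
    tibble(c1 = c1, c2 = freqs$behavior[2], f1 = f1, f2 = freqs$freq[2])
  } else {
    tibble(c1 = c1, c2 = c1, f1 = f1, f2 = if (nrow(freqs) >= 2) freqs$freq[2] else 0)
  }
}

#' Empirical frequency of class pairs over a set of windows
#'
#' @param pairs Data frame with integer columns `c1`, `c2` (one row per
#'   window).
#' @return Tibble `c1`, `c2`, `freq`, normalized over all observed pairs.
#' @export
pair_frequency_table <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("c1", "c2") %in% names(pairs)))
  pairs |>
    count(.data$c1, .data$c2, name = "n") |>
    mutate(freq = .data$n / sum(.data$n)) |>
    select("c1", "c2", "freq")
}

#' Lump rare class pairs
#'
#' Applies the lumping rule: pairs led by a rare behavior (C1 >= 6, i.e.
#' drinking, walking, other) become the residual pair (8, 8); pairs whose
#' empirical frequency falls below `flow` keep C1 but lose C2 to the
#' residual code 8; all other pairs pass through. The rule is idempotent.
#'
#' @param pairs Data frame with integer columns `c1`, `c2`.
#' @param pair_freqs Empirical pair-frequency table
#'   ([pair_frequency_table()]), normally computed on the training split
#'   only and then frozen; pairs absent from the table have frequency 0.
#' @param flow Rarity threshold on the pair frequency (default 0.01).
#' @return `pairs` with added integer columns `l1`, `l2` (the lumped pair).
#' @examples
#' pf <- tibble::tibble(c1 = c(2L, 2L), c2 = c(2L, 3L), freq = c(0.995, 0.005))
#' lump_class_pair(tibble::tibble(c1 = c(7L, 2L, 2L), c2 = c(1L, 3L, 2L)), pf)
#' @export
lump_class_pair <- function(pairs, pair_freqs, flow = 0.01) {
  stopifnot(is.data.frame(pairs), all(c("c1", "c2") %in% names(pairs)))
  if (flow <= 0 || flow >= 1) abort("`flow` must be in (0, 1).")
  out <- pairs |>
    left_join(pair_freqs, by = c("c1", "c2")) |>
    mutate(freq = coalesce(.data$freq, 0)) |>
    mutate(
      l1 = case_when(.data$c1 >= 6L ~ 8L, TRUE ~ .data$c1),
      l2 = case_when(
        .data$c1 >= 6L ~ 8L,
        .data$freq < flow ~ 8L,
        TRUE ~ .data$c2
      )
    ) |>
    select(-"freq")
  out
}

#' Map a behavior code (or lumped pair) onto a class-set group label
#'
#' For S1--S4, returns the label of the group containing the code; for S5,
#' validates the lumped pair against the 15 admissible pairs and returns it
#' as a two-digit label.
#'
#' @param x Integer behavior codes (S1--S4) or two-digit pair label strings
#'   (S5, e.g. `"24"`).
#' @param set_id One of `"S1"`..`"S5"`.
#' @return Character vector of group labels.
#' @examples
#' map_to_class_set(3, "S2") # ruminating group "34"
#' map_to_class_set(3, "S3") # standing group "13"
#' @export
map_to_class_set <- function(x, set_id) {
  sets <- class_sets()
  if (!set_id %in% names(sets)) abort(sprintf("unknown class set `%s`.", set_id))
  groups <- sets[[set_id]]
  if (set_id == "S5") {
    x <- as.character(x)
    bad <- setdiff(unique(x), groups)
    if (length(bad) > 0) {
      abort(sprintf("pair(s) %s not in class set S5.", paste(bad, collapse = ", ")))
    }
    return(x)
  }
  x <- as.integer(x)
  if (any(is.na(x) | x < 1L | x > 8L)) abort("behavior codes must be in 1..8.")
  lookup <- character(8)
  for (g in groups) lookup[group_members(g)] <- g
  lookup[x]
}

# Integer member codes of a group label such as "678".
group_members <- function(label) {
  as.integer(unique(strsplit(label, "")[[1]]))
}

#' Label all windows with class pairs, lumped pairs and class-set targets
#'
#' Runs the full labeling chain for each window: behavior frequencies,
#' class-pair assignment, lumping, and projection onto the five class sets.
#' The pair-frequency table used for lumping should come from the training
#' split ([pair_frequency_table()]) to avoid leakage; when `pair_freqs` is
#' `NULL` it is computed from the windows being labeled.
#'
#' @param windows Output of [split_windows()].
#' @param fmin Significance threshold for the second class (default 0.4).
#' @param flow Rarity threshold for lumping (default 0.01).
#' @param pair_freqs Optional frozen pair-frequency table.
#' @return Tibble with one row per window: `window`, `c1`, `c2`, `f1`,
#'   `f2`, `l1`, `l2`, and label columns `s1`..`s5`.
#' @examples
#' stream <- simulate_stream(schedule_config(duration_s = 3600, seed = 1))
#' labs <- window_labels(split_windows(stream))
#' @export
window_labels <- function(windows, fmin = 0.4, flow = 0.01, pair_freqs = NULL) {
  stopifnot(is.data.frame(windows), all(c("window", "behavior") %in% names(windows)))
  pairs <- windows |>
    group_by(window) |>
    group_modify(~ assign_class_pair(behavior_frequencies(.x$behavior), fmin = fmin)) |>
    ungroup()
  if (is.null(pair_freqs)) pair_freqs <- pair_frequency_table(pairs)
  lumped <- lump_class_pair(pairs, pair_freqs, flow = flow)
  lumped |>
    mutate(
      s1 = map_to_class_set(.data$c1, "S1"),
      s2 = map_to_class_set(.data$c1, "S2"),
      s3 = map_to_class_set(.data$c1, "S3"),
      s4 = map_to_class_set(.data$c1, "S4"),
      s5 = paste0(.data$l1, .data$l2)
    )
}
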