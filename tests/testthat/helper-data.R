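# Small fixture builders, all generated in code at test time.

# A window data frame with constant acceleration.
constant_window <- function(x, y, z, n = 15000) {
  tibble::tibble(x_g = rep(x, n), y_g = rep(y, n), z_g = rep(z, n))
}

# A window of Gaussian noise around a gravity-like orientation.
random_window <- function(n = 15000, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    x_g = rnorm(n, 0.1, 0.3),
    y_g = rnorm(n, -0.2, 0.3),
    z_g = rnorm(n, -0.9, 0.3)
  )
}

# A depth-1 decision stump splitting on one feature.
stump <- function(feature = "vebda", threshold = 1.05,
                  low = "low", high = "high") {
  herdsense:::new_tree(
    tibble::tibble(
      id = 1:3,
      var = c(feature, NA, NA),
      threshold = c(threshold, NA, NA),
      left = c(2L, NA, NA),
      right = c(3L, NA, NA),
      label = c(low, low, high)
    ),
    class_set = "S1", features = feature, levels = c(low, high)
  )
}

# Random group-label tuples (s1..s5) drawn from the five class sets.
random_estimates <- function(n, seed = 1) {
  set.seed(seed)
  sets <- class_sets()
  tibble::tibble(
    s1 = sample(sets$S1, n, replace = TRUE),
    s2 = sample(sets$S2, n, replace = TRUE),
    s3 = sample(sets$S3, n, replace = TRUE),
    s4 = sample(sets$S4, n, replace = TRUE),
    s5 = sample(sets$S5, n, replace = TRUE)
  )
}

# One pooled synthetic study at reduced scale, cached per test session.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(suppressWarnings(
        run_study(hours = 2, seeds = 1:2)
      ))
    }
    cache
  }
})

# The full-scale study (6 h per run, 5 seeds), cached; used where the
# property under test depends on the dataset size (e.g. the 1% pair-rarity
# threshold needs >100 windows to bite).
full_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(suppressWarnings(
        run_study(hours = 6, seeds = 1:5)
      ))
    }
    cache
  }
})
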