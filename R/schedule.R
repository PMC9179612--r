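#' Configure a synthetic behavior schedule
#'
#' A schedule is a sequence of behavior bouts drawn from per-behavior dwell
#' (bout-duration) distributions. Two sampling modes are supported:
#'
#' * **quota mode** (default, `transition_matrix = NULL`): bout types are
#'   drawn with probability proportional to each behavior's remaining time
#'   quota divided by its mean dwell, which keeps the realized time budget
#'   close to `target_prevalence`. A short-duration behavior (drinking,
#'   walking, other; codes 6--8) is always followed by one of the sustained
#'   behaviors (codes 1--5), reflecting that cows return to lying, standing
#'   or feeding after brief interruptions;
#' * **semi-Markov mode**: an explicit 8x8 row-stochastic
#'   `transition_matrix` drives bout-to-bout transitions (a self-transition
#'   simply extends the current behavior by another bout).
#'
#' Dwell times are gamma-distributed with the given per-behavior mean and
#' standard deviation, rounded to whole seconds (minimum 1 s).
#'
#' @param duration_s Total schedule length in seconds (> 0).
#' @param target_prevalence Length-8 numeric, fraction of time per behavior;
#'   must sum to 1 within 1e-6. Default emulates commonly observed herd time
#'   budgets with drinking/walking/other each below 5%.
#' @param transition_matrix Optional 8x8 row-stochastic matrix (rows sum to
#'   1 within 1e-9); enables semi-Markov mode.
#' @param dwell_mean,dwell_sd Length-8 numeric, mean and standard deviation
#'   of bout duration in seconds per behavior; means must be > 0.
#' @param start Optional behavior code for the first bout (default: drawn).
#' @param seed Integer RNG seed; all schedule randomness derives from it.
#' @return An object of class `herdsense_schedule_config`.
#' @examples
#' cfg <- schedule_config(duration_s = 3600, seed = 7)
#' @export
schedule_config <- function(duration_s = 6 * 3600,
                            target_prevalence =
                              c(0.12, 0.26, 0.08, 0.28, 0.20, 0.02, 0.02, 0.02),
                            transition_matrix = NULL,
                            dwell_mean = c(1800, 4200, 2400, 3900, 2400, 90, 120, 180),
                            dwell_sd = c(700, 1500, 900, 1400, 900, 40, 60, 90),
                            start = NULL,
                            seed = 1L) {
  if (length(duration_s) != 1L || !is.finite(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be a single positive number.")
  }
  if (length(target_prevalence) != 8L || any(target_prevalence < 0) ||
      abs(sum(target_prevalence) - 1) > 1e-6) {
    abort("`target_prevalence` must be 8 non-negative fractions summing to 1 (tol 1e-6).")
  }
  if (!is.null(transition_matrix)) {
    tm <- as.matrix(transition_matrix)
    if (!all(dim(tm) == c(8L, 8L)) || any(tm < 0) ||
        any(abs(rowSums(tm) - 1) > 1e-9)) {
      abort("`transition_matrix` must be 8x8 with non-negative rows summing to 1 (tol 1e-9).")
    }
    transition_matrix <- tm
  }
  if (length(dwell_mean) != 8L || any(dwell_mean <= 0)) {
    abort("`dwell_mean` must be 8 positive values (seconds).")
  }
  if (length(dwell_sd) != 8L || any(dwell_sd <= 0)) {
    abort("`dwell_sd` must be 8 positive values (seconds).")
  }
  if (!is.null(start)) {
    start <- as.integer(start)
    if (length(start) != 1L || start < 1L || start > 8L) {
      abort("`start` must be a single behavior code in 1..8.")
    }
  }
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")
  structure(
    list(
      duration_s = duration_s, target_prevalence = target_prevalence,
      transition_matrix = transition_matrix,
      dwell_mean = dwell_mean, dwell_sd = dwell_sd,
      start = start, seed = seed
    ),
    class = "herdsense_schedule_config"
  )
}

#' Read or write a schedule configuration as YAML
#'
#' @param config A `herdsense_schedule_config`.
#' @param path File path.
#' @return `read_schedule_config()` returns a `herdsense_schedule_config`;
#'   `write_schedule_config()` returns `path` invisibly.
#' @export
write_schedule_config <- function(config, path) {
  stopifnot(inherits(config, "herdsense_schedule_config"))
  lst <- unclass(config)
  if (!is.null(lst$transition_matrix)) {
    lst$transition_matrix <- apply(lst$transition_matrix, 1, identity, simplify = FALSE)
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_schedule_config
#' @export
read_schedule_config <- function(path) {
  lst <- yaml::read_yaml(path)
  tm <- lst$transition_matrix
  if (!is.null(tm)) tm <- do.call(rbind, tm)
  schedule_config(
    duration_s = lst$duration_s,
    target_prevalence = as.numeric(lst$target_prevalence),
    transition_matrix = tm,
    dwell_mean = as.numeric(lst$dwell_mean),
    dwell_sd = as.numeric(lst$dwell_sd),
    start = lst$start,
    seed = lst$seed
  )
}

#' Generate a per-sample behavior schedule
#'
#' Draws a bout sequence according to `config` and expands it to one
#' behavior code per 25 Hz sample. Deterministic given `config$seed`.
#'
#' @param config A [schedule_config()].
#' @param fs Sampling frequency in Hz (default 25).
#' @return A tibble with columns `t_index` (0-based sample index) and
#'   `behavior` (integer 1--8), of `config$duration_s * fs` rows.
#' @examples
#' sched <- generate_schedule(schedule_config(duration_s = 1200, seed = 2))
#' table(sched$behavior)
#' @export
generate_schedule <- function(config, fs = HS_FS) {
  stopifnot(inherits(config, "herdsense_schedule_config"))
  set.seed(config$seed)
  n_s <- config$duration_s
  used <- numeric(8)
  codes <- integer(0)
  lens <- integer(0)
  state <- NA_integer_
  total <- 0
  while (total < n_s) {
    if (!is.null(config$transition_matrix)) {
      state <- if (is.na(state)) {
        config$start %||% sample.int(8L, 1L, prob = config$target_prevalence)
      } else {
        sample.int(8L, 1L, prob = config$transition_matrix[state, ])
      }
    } else if (!is.na(config$start %||% NA) && is.na(state)) {
      state <- config$start
    } else {
      deficit <- pmax(config$target_prevalence * n_s - used, 0)
      w <- deficit / config$dwell_mean
      if (sum(w) <= 0) w <- config$target_prevalence / config$dwell_mean
      if (!is.na(state) && state >= 6L) {
        # brief behaviors are followed by a sustained one (codes 1..5)
        w[6:8] <- 0
        if (sum(w) <= 0) w[1:5] <- config$target_prevalence[1:5] / config$dwell_mean[1:5]
      }
      state <- sample.int(8L, 1L, prob = w)
    }
    m <- config$dwell_mean[state]
    s <- config$dwell_sd[state]
    d <- max(1, round(rgamma(1L, shape = (m / s)^2, rate = m / s^2)))
    if (is.null(config$transition_matrix)) {
      # keep the realized time budget near the target: a bout does not
      # overshoot its behavior's remaining quota by more than a minute
      quota_left <- config$target_prevalence[state] * n_s - used[state]
      d <- min(d, max(ceiling(quota_left), 60))
    }
    d <- min(d, n_s - total)
    codes <- c(codes, state)
    lens <- c(lens, d)
    used[state] <- used[state] + d
    total <- total + d
  }
  behavior <- rep(codes, times = lens * fs)
  tibble(t_index = seq_along(behavior) - 1L, behavior = behavior)
}
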