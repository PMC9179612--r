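# Canonical sub-window series order: per-axis mean, mean absolute value,
# standard deviation.
HS_SERIES <- c(
  "ave_x", "ave_y", "ave_z",
  "abs_x", "abs_y", "abs_z",
  "std_x", "std_y", "std_z"
)

#' Canonical names of the 23 window features, in fixed order
#'
#' For each of the nine sub-window series (per-axis mean `ave`, mean
#' absolute value `abs`, standard deviation `std`): the root-mean-square
#' `vstd` and the maximum absolute value `vmax` (18 statistical features);
#' then the dynamic features `vebda` and `obda`; then the three inter-axis
#' correlations `rho_xy`, `rho_xz`, `rho_yz`.
#'
#' @return Character vector of length 23.
#' @export
feature_names <- function() {
  c(
    as.vector(rbind(paste0("vstd_", HS_SERIES), paste0("vmax_", HS_SERIES))),
    "vebda", "obda", "rho_xy", "rho_xz", "rho_yz"
  )
}

#' Aggregate a window into 5-second sub-window series
#'
#' Splits one observation window into sub-windows of `tsw` seconds and
#' computes, per sub-window and axis: the mean, the mean of the absolute
#' value, and the (population) standard deviation of the acceleration.
#' At the defaults (600 s window, 5 s sub-windows) each series has
#' 120 entries. Sub-windowing suppresses accidental high-frequency
#' accelerations (knocks, contacts) before feature computation.
#'
#' @param window Data frame with columns `x_g`, `y_g`, `z_g`
#'   (one complete window).
#' @param fs Sampling frequency in Hz.
#' @param tsw Sub-window duration in seconds (default 5); the window length
#'   must be divisible by `fs * tsw`.
#' @return Tibble with columns `k` (0-based sub-window index) and the nine
#'   series `ave_x` .. `std_z`.
#' @examples
#' w <- tibble::tibble(x_g = rnorm(750), y_g = rnorm(750), z_g = rnorm(750))
#' subwindow_aggregate(w, tsw = 5)
#' @export
subwindow_aggregate <- function(window, fs = HS_FS, tsw = 5) {
  stopifnot(is.data.frame(window), all(c("x_g", "y_g", "z_g") %in% names(window)))
  m <- fs * tsw
  if (abs(m - round(m)) > 1e-9) abort("`fs * tsw` must be an integer sample count.")
  m <- as.integer(round(m))
  n <- nrow(window)
  if (n == 0 || n %% m != 0) {
    abort(sprintf("window length %d is not divisible by the sub-window length %d.", n, m))
  }
  s <- n %/% m
  agg <- function(v) {
    x <- matrix(v, nrow = m)
    ave <- colMeans(x)
    list(
      ave = ave,
      abs = colMeans(abs(x)),
      std = sqrt(pmax(colMeans(x^2) - ave^2, 0))
    )
  }
  ax <- agg(window$x_g)
  ay <- agg(window$y_g)
  az <- agg(window$z_g)
  tibble(
    k = 0:(s - 1L),
    ave_x = ax$ave, ave_y = ay$ave, ave_z = az$ave,
    abs_x = ax$abs, abs_y = ay$abs, abs_z = az$abs,
    std_x = ax$std, std_y = ay$std, std_z = az$std
  )
}

#' Normalize a sub-window series by its maximum absolute value
#'
#' Each element is divided by the largest absolute element of the series
#' within the window, so the normalized series spans \[-1, 1\]. An all-zero
#' series is returned unchanged with attribute `degenerate = TRUE`.
#'
#' @param series Numeric vector.
#' @return Normalized numeric vector (attribute `degenerate` flags the
#'   zero-max case).
#' @examples
#' normalize_series(c(2, -4, 1))
#' @export
normalize_series <- function(series) {
  if (length(series) == 0) abort("empty series.")
  m <- max(abs(series))
  if (m == 0) {
    attr(series, "degenerate") <- TRUE
    return(series)
  }
  out <- series / m
  attr(out, "degenerate") <- FALSE
  out
}

#' Extract the 23 features of one observation window
#'
#' From the nine sub-window series of [subwindow_aggregate()]:
#'
#' * `vstd_*`: root-mean-square of each series, `sqrt(mean(V_k^2))`;
#' * `vmax_*`: maximum absolute value of each series;
#' * `vebda`: vectorial body dynamic acceleration, the mean over
#'   sub-windows of the Euclidean norm of the mean-acceleration vector;
#' * `obda`: overall body dynamic acceleration, the mean over sub-windows
#'   of the L1 deviation of the mean-acceleration vector from its
#'   window-mean;
#' * `rho_xy`, `rho_xz`, `rho_yz`: Pearson correlations between the
#'   normalized per-axis mean series ([normalize_series()]).
#'
#' By default `vstd`/`vmax` are computed on the raw (non-normalized)
#' series; set `normalize_stats = TRUE` to compute them on the
#' max-normalized series instead. A zero-variance series makes the affected
#' correlation 0 and sets the `degenerate` attribute.
#'
#' @param window Data frame with columns `x_g`, `y_g`, `z_g`.
#' @param fs Sampling frequency in Hz.
#' @param tsw Sub-window duration in seconds.
#' @param normalize_stats Compute `vstd`/`vmax` on normalized series
#'   (default FALSE).
#' @return One-row tibble with the 23 columns of [feature_names()];
#'   attribute `degenerate` is TRUE when any correlation was degenerate.
#' @examples
#' w <- tibble::tibble(x_g = rnorm(15000, sd = .05), y_g = rnorm(15000, sd = .05),
#'                     z_g = -1 + rnorm(15000, sd = .05))
#' extract_features(w)
#' @export
extract_features <- function(window, fs = HS_FS, tsw = 5, normalize_stats = FALSE) {
  agg <- subwindow_aggregate(window, fs = fs, tsw = tsw)
  out <- numeric(0)
  for (sname in HS_SERIES) {
    v <- agg[[sname]]
    if (normalize_stats) v <- as.numeric(normalize_series(v))
    out[paste0("vstd_", sname)] <- sqrt(mean(v^2))
    out[paste0("vmax_", sname)] <- max(abs(v))
  }
  out <- out[feature_names()[1:18]]
  out["vebda"] <- mean(sqrt(agg$ave_x^2 + agg$ave_y^2 + agg$ave_z^2))
  out["obda"] <- mean(
    abs(agg$ave_x - mean(agg$ave_x)) +
      abs(agg$ave_y - mean(agg$ave_y)) +
      abs(agg$ave_z - mean(agg$ave_z))
  )
  nx <- normalize_series(agg$ave_x)
  ny <- normalize_series(agg$ave_y)
  nz <- normalize_series(agg$ave_z)
  degenerate <- FALSE
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      degenerate <<- TRUE
      return(0)
    }
    cor(as.numeric(a), as.numeric(b))
  }
  out["rho_xy"] <- safe_cor(nx, ny)
  out["rho_xz"] <- safe_cor(nx, nz)
  out["rho_yz"] <- safe_cor(ny, nz)
  res <- as_tibble(as.list(out))
  attr(res, "degenerate") <- degenerate
  res
}

#' Feature vectors for every window of a windowed stream
#'
#' @param windows Output of [split_windows()].
#' @inheritParams extract_features
#' @return Tibble with one row per window: `window` plus the 23 feature
#'   columns.
#' @examples
#' stream <- simulate_stream(schedule_config(duration_s = 1800, seed = 1))
#' feats <- window_features(split_windows(stream))
#' @export
window_features <- function(windows, fs = HS_FS, tsw = 5, normalize_stats = FALSE) {
  stopifnot(is.data.frame(windows), "window" %in% names(windows))
  windows |>
    group_by(window) |>
    group_modify(~ extract_features(.x, fs = fs, tsw = tsw,
                                    normalize_stats = normalize_stats)) |>
    ungroup()
}

# Axis family of a feature: the name with its axis suffix stripped, so
# vstd_ave_x/y/z form one family, rho_xy/xz/yz another; vebda and obda are
# singleton families.
feature_family <- function(name) {
  sub("_(x|y|z|xy|xz|yz)$", "", name)
}

#' Screen redundant features by cross-correlation
#'
#' Computes the Pearson correlation matrix of the 23 features across
#' windows and greedily discards features until no retained pair has
#' `|r| > threshold`: at each step the most correlated offending pair is
#' examined and the member with the larger mean absolute correlation to the
#' other retained features is dropped. Ties favor the feature whose axis
#' family (e.g. `vstd_ave_x/y/z`) retains more siblings — preserving
#' symmetric, homogeneous feature sets — then the lower feature index.
#' Anti-correlated features are treated as redundant (absolute value).
#'
#' @param features Data frame of feature vectors (a `window` column, if
#'   present, is ignored); at least 2 rows, and at least 30 for stable
#'   correlations (fewer triggers a warning).
#' @param threshold Absolute-correlation threshold above which a pair is
#'   redundant (default 0.75).
#' @return An object of class `herdsense_reduction`: list with
#'   `correlation` (signed matrix), `threshold`, `selected` (retained
#'   feature names in canonical order) and `discarded` (tibble
#'   `feature`, `against`, `abs_r`).
#' @examples
#' stream <- simulate_stream(schedule_config(duration_s = 4 * 3600, seed = 1))
#' red <- reduce_features(window_features(split_windows(stream)))
#' red$selected
#' @export
reduce_features <- function(features, threshold = 0.75) {
  stopifnot(is.data.frame(features))
  fn <- intersect(names(features), feature_names())
  if (length(fn) < 2) abort("need at least 2 feature columns.")
  x <- as.matrix(features[fn])
  if (nrow(x) < 2) abort("need at least 2 feature vectors.")
  if (nrow(x) < 30) warn("fewer than 30 feature vectors: correlations may be unstable.")
  cm <- suppressWarnings(cor(x))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  retained <- fn
  discarded <- list()
  repeat {
    a <- abs(cm[retained, retained, drop = FALSE])
    diag(a) <- 0
    if (max(a) <= threshold) break
    idx <- which(a == max(a), arr.ind = TRUE)[1, ]
    pair <- retained[sort(as.integer(idx))]
    mean_abs <- vapply(pair, function(f) {
      others <- setdiff(retained, f)
      mean(abs(cm[f, others]))
    }, numeric(1))
    drop <- if (abs(diff(mean_abs)) > 1e-12) {
      pair[which.max(mean_abs)]
    } else {
      sibs <- vapply(pair, function(f) {
        sum(feature_family(setdiff(retained, f)) == feature_family(f))
      }, numeric(1))
      if (sibs[1] != sibs[2]) {
        # keep the member whose family retains more siblings
        pair[which.min(sibs)]
      } else {
        pair[which.max(match(pair, fn))]
      }
    }
    discarded[[drop]] <- tibble(
      feature = drop,
      against = setdiff(pair, drop),
      abs_r = max(a)
    )
    retained <- setdiff(retained, drop)
  }
  structure(
    list(
      correlation = cm,
      threshold = threshold,
      selected = fn[fn %in% retained],
      discarded = if (length(discarded)) list_rbind(unname(discarded)) else
        tibble(feature = character(), against = character(), abs_r = numeric())
    ),
    class = "herdsense_reduction"
  )
}

#' @export
print.herdsense_reduction <- function(x, ...) {
  cat(sprintf(
    "<herdsense_reduction> |r| > %.2f screening: %d of %d features retained\n",
    x$threshold, length(x$selected), ncol(x$correlation)
  ))
  cat("  retained:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
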