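#' Write a decorated stream to CSV
#'
#' Dialect: comma-separated, UTF-8, header
#' `t_index,x_g,y_g,z_g,behavior`, accelerations in G as decimals,
#' 0-based `t_index`. Round-trips losslessly with [read_stream()].
#'
#' @param stream A decorated stream tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(is.data.frame(stream))
  cols <- c("t_index", "x_g", "y_g", "z_g", "behavior")
  if (!all(cols %in% names(stream))) {
    abort(sprintf("stream must have columns %s", paste(cols, collapse = ", ")))
  }
  readr::write_csv(stream[cols], path)
  invisible(path)
}

#' Read a decorated stream from CSV
#'
#' Validates the header, rejects ragged rows, requires behavior codes in
#' 1--8 and a strictly increasing sample index; parse errors name the
#' offending file line (header is line 1).
#'
#' @param path CSV file path (dialect of [write_stream()]).
#' @return A decorated stream tibble with columns
#'   `t_index`, `x_g`, `y_g`, `z_g`, `behavior`.
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cols <- c("t_index", "x_g", "y_g", "z_g", "behavior")
  dat <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      t_index = readr::col_integer(),
      x_g = readr::col_double(),
      y_g = readr::col_double(),
      z_g = readr::col_double(),
      behavior = readr::col_integer()
    ),
    progress = FALSE
  ))
  if (!identical(names(dat), cols)) {
    abort(sprintf(
      "unexpected header: got `%s`, want `%s`",
      paste(names(dat), collapse = ","), paste(cols, collapse = ",")
    ))
  }
  if (nrow(dat) == 0) abort("no samples")
  probs <- readr::problems(dat)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "parse error at line %d: %s", probs$row[1] + 1L, probs$expected[1]
    ))
  }
  bad <- which(is.na(dat$behavior) | dat$behavior < 1L | dat$behavior > 8L)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid behavior code %s at line %d (codes must be 1..8)",
      dat$behavior[bad[1]], bad[1] + 1L
    ))
  }
  if (anyNA(dat$t_index) || any(diff(dat$t_index) <= 0)) {
    bad_t <- if (anyNA(dat$t_index)) which(is.na(dat$t_index))[1] else which(diff(dat$t_index) <= 0)[1] + 1L
    abort(sprintf("non-monotone sample index at line %d", bad_t + 1L))
  }
  as_tibble(dat)
}

#' Split a decorated stream into fixed-length observation windows
#'
#' Windows are contiguous, non-overlapping, and aligned to the stream
#' start. A trailing partial window is dropped (the number of dropped
#' samples is reported and attached as attribute `dropped_samples`). At the
#' defaults (25 Hz, 600 s) every window holds exactly 15,000 triaxial
#' samples.
#'
#' @param stream A decorated stream tibble.
#' @param tw Window duration in seconds (default 600).
#' @param fs Sampling frequency in Hz (default 25); `fs * tw` must be a
#'   whole number of samples.
#' @return The stream rows belonging to complete windows, with a leading
#'   `window` column (1-based window index). If the stream is shorter than
#'   one window, an empty tibble with a warning.
#' @examples
#' stream <- simulate_stream(schedule_config(duration_s = 1800, seed = 1))
#' w <- split_windows(stream)
#' dplyr::count(w, window)
#' @export
split_windows <- function(stream, tw = 600, fs = HS_FS) {
  stopifnot(is.data.frame(stream))
  if (tw <= 0) abort("`tw` must be > 0.")
  wlen <- fs * tw
  if (abs(wlen - round(wlen)) > 1e-9) abort("`fs * tw` must be an integer sample count.")
  wlen <- as.integer(round(wlen))
  n <- nrow(stream)
  n_win <- n %/% wlen
  dropped <- n - n_win * wlen
  if (n_win == 0) {
    warn(sprintf("stream shorter than one %d s window; no windows produced.", tw))
    out <- bind_cols(tibble(window = integer(0)), stream[0, ])
    attr(out, "dropped_samples") <- dropped
    return(out)
  }
  if (dropped > 0) {
    inform(sprintf("dropped %d trailing samples (partial window).", dropped))
  }
  out <- stream[seq_len(n_win * wlen), , drop = FALSE]
  out <- bind_cols(tibble(window = rep(seq_len(n_win), each = wlen)), out)
  attr(out, "dropped_samples") <- dropped
  attr(out, "tw") <- tw
  attr(out, "fs") <- fs
  as_tibble(out)
}

#' Window manifest
#'
#' @param windows Output of [split_windows()].
#' @return Tibble `window_index`, `start_t`, `end_t` (sample indices,
#'   inclusive).
#' @export
window_manifest <- function(windows) {
  windows |>
    group_by(window) |>
    summarise(start_t = min(.data$t_index), end_t = max(.data$t_index), .groups = "drop") |>
    rename(window_index = window)
}
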