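#' Plot a slice of a decorated stream
#'
#' Triaxial acceleration traces with the observed behavior code shown
#' underneath, mirroring how collar acquisitions are usually inspected.
#'
#' @param stream A decorated stream tibble.
#' @param from,to Time range in seconds (defaults: whole stream).
#' @param fs Sampling frequency in Hz.
#' @return A ggplot object.
#' @export
plot_stream <- function(stream, from = NULL, to = NULL, fs = HS_FS) {
  d <- stream |> mutate(t_s = .data$t_index / fs)
  if (!is.null(from)) d <- d |> filter(.data$t_s >= from)
  if (!is.null(to)) d <- d |> filter(.data$t_s <= to)
  long <- d |>
    tidyr::pivot_longer(c("x_g", "y_g", "z_g"),
      names_to = "axis", values_to = "acceleration_g"
    ) |>
    bind_rows(
      d |> transmute(.data$t_s, axis = "behavior", acceleration_g = .data$behavior)
    ) |>
    mutate(axis = factor(.data$axis, levels = c("x_g", "y_g", "z_g", "behavior")))
  ggplot(long, aes(x = .data$t_s, y = .data$acceleration_g)) +
    geom_line(linewidth = 0.2) +
    facet_grid(rows = vars(.data$axis), scales = "free_y") +
    labs(x = "time (s)", y = "acceleration (G) / behavior code") +
    theme_minimal()
}

#' @method autoplot herdsense_reduction
#' @export
autoplot.herdsense_reduction <- function(object, ...) {
  d <- as_tibble(as.data.frame(as.table(abs(object$correlation)))) |>
    rlang::set_names(c("feature_a", "feature_b", "abs_r"))
  ggplot(d, aes(x = .data$feature_a, y = .data$feature_b, fill = .data$abs_r)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(
      x = NULL, y = NULL, fill = "|r|",
      title = sprintf(
        "Feature cross-correlation (|r| > %.2f screened, %d retained)",
        object$threshold, length(object$selected)
      )
    ) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' @method autoplot herdsense_timebudget
#' @export
autoplot.herdsense_timebudget <- function(object, ...) {
  d <- object$per_class |>
    tidyr::pivot_longer(c("actual_s", "estimated_s"),
      names_to = "kind", values_to = "seconds"
    ) |>
    mutate(kind = if_else(.data$kind == "actual_s", "actual", "estimated"))
  ggplot(d, aes(x = factor(.data$behavior), y = .data$seconds / 3600, fill = .data$kind)) +
    geom_col(position = "dodge") +
    labs(
      x = "behavior class", y = "time (h)", fill = NULL,
      title = sprintf("Time budget (time accuracy %.1f%%)", object$time_accuracy)
    ) +
    theme_minimal()
}

#' @method autoplot herdsense_study
#' @export
autoplot.herdsense_study <- function(object, ...) {
  ggplot(object$accuracies, aes(x = .data$classifier, y = .data$accuracy)) +
    geom_col(fill = "steelblue") +
    coord_cartesian(ylim = c(0, 100)) +
    labs(
      x = NULL, y = "window accuracy (%)",
      title = "Per-classifier and combined window accuracy"
    ) +
    theme_minimal()
}
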