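#' Plot a chronoamperometry or voltage trace
#'
#' @param trace Trace tibble (`time_h` plus `current_A` or `voltage_V`).
#' @param peaks Optional peak table ([find_current_peak()] output) to mark.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, peaks = NULL) {
  ycol <- if ("current_A" %in% names(trace)) "current_A" else "voltage_V"
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_h, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (h)",
                  y = if (ycol == "current_A") "current (A)" else "voltage (V)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$peak_time, y = .data$peak_current),
      colour = "firebrick", size = 2
    )
  }
  p
}

#' @export
autoplot.balance_report <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$pool != "current")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$partition, y = .data$share_pct,
                                   fill = .data$pool)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(title = object$reactor_id,
                  x = NULL, y = "share of consumed substrate (%)",
                  fill = "pool") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nmds_ordination <- function(object, metadata = NULL, ...) {
  df <- object$points
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  aes <- if (!is.null(metadata) && "group" %in% names(df)) {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(caption = sprintf("stress-1 = %.3f", object$stress)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Boxplots of the alpha-diversity panel by group
#'
#' @param alpha Output of [alpha_diversity()].
#' @param metadata Tibble with `sample_id` and `group`.
#' @return A ggplot object, faceted per index.
#' @export
plot_alpha_diversity <- function(alpha, metadata) {
  df <- dplyr::left_join(alpha, metadata, by = "sample_id") |>
    tidyr::pivot_longer(c("shannon", "observed_species", "chao1", "faith_pd"),
                        names_to = "index", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked family-composition bars
#'
#' @param profile Output of [family_profile()].
#' @return A ggplot object.
#' @export
plot_family_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$sample_id,
                                        y = .data$proportion,
                                        fill = .data$family)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
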