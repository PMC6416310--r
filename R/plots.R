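#' @export
autoplot.soft_threshold_scan <- function(object, ...) {
  chosen <- attr(object, "chosen_power")
  ggplot2::ggplot(object, ggplot2::aes(.data$power, .data$scale_free_r2)) +
    ggplot2::geom_hline(
      yintercept = attr(object, "r2_cutoff"),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$power == chosen),
      show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(
      x = "soft-thresholding power",
      y = expression("signed scale-free fit " * R^2),
      title = sprintf("Soft-threshold scan (chosen power %d)", chosen)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.module_partition <- function(object, ...) {
  sizes <- module_sizes(object)
  sizes$module <- factor(sizes$module, levels = sizes$module)
  ggplot2::ggplot(sizes, ggplot2::aes(.data$module, .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes", title = "Module sizes") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' @param rows Output of [enrich_module()].
#' @param top_n Terms shown per module (smallest q first).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows, top_n = 10) {
  rows <- rows |>
    dplyr::group_by(.data$module) |>
    dplyr::slice_min(.data$q_value, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(
    rows,
    ggplot2::aes(.data$module, .data$term,
      size = .data$k, colour = -log10(.data$q_value)
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] * "(q)")) +
    ggplot2::labs(x = NULL, y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' Degree distribution with hubs highlighted
#'
#' @param graph A `ppi_graph`.
#' @param top_n Number of top-degree nodes to label as hubs.
#' @return A ggplot object.
#' @export
plot_hub_degrees <- function(graph, top_n = 5) {
  ranking <- hub_ranking(graph)
  ranking$rank <- seq_len(nrow(ranking))
  ggplot2::ggplot(ranking, ggplot2::aes(.data$rank, .data$degree)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rank <= top_n),
      show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(
      x = "degree rank", y = "degree",
      title = "PPI degree ranking"
    ) +
    ggplot2::theme_minimal()
}
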