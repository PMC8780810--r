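# ggplot2 views of the report objects.

#' Heatmap of a cross-method comparison
#'
#' Tiles methods against metrics, colouring by the min-max position of
#' each method within each metric so that the best method per metric is
#' darkest; raw values are printed in the tiles.
#'
#' @param object A `loop_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loop_comparison <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"method", names_to = "metric", values_to = "value") |>
    filter(is.finite(.data$value)) |>
    group_by(.data$metric) |>
    mutate(scaled = if (dplyr::n_distinct(.data$value) > 1)
      scale_scores(.data$value) else 1) |>
    ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$method,
                                     fill = .data$scaled)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 name = "within-metric\nscaled") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a resolution-level profile
#'
#' @param loops A loop tibble (passed to [resolution_levels()]).
#' @return A ggplot object.
#' @export
plot_resolution_levels <- function(loops) {
  res <- resolution_levels(loops)
  res$bin <- factor(res$bin, levels = c("le10k", "10k_100k", "100k_1m"),
                    labels = c("≤ 10 kb", "10–100 kb", "100 kb–1 Mb"))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = "anchor distance", y = "fraction of loops") +
    ggplot2::theme_minimal()
}
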