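#' Plot Precision@K curves
#'
#' @param object A `kge_eval` tibble (several subjects may be stacked with
#'   `dplyr::bind_rows()` before plotting).
#' @param ... Unused.
#' @return A ggplot object: precision against K, one line per subject.
#' @method autoplot kge_eval
#' @export
autoplot.kge_eval <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$k, y = .data$precision, colour = .data$subject)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "K (top predictions evaluated)", y = "Precision@K", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot pairwise top-K agreement heatmaps
#'
#' @param object A `kge_agreement` object.
#' @param ... Unused.
#' @return A ggplot object: true-positive and false-positive overlap
#'   heatmaps, facetted side by side.
#' @method autoplot kge_agreement
#' @export
autoplot.kge_agreement <- function(object, ...) {
  long <- tidy(object) %>%
    tidyr::pivot_longer(c("tp_overlap", "fp_overlap"),
      names_to = "partition", values_to = "overlap"
    ) %>%
    mutate(partition = ifelse(.data$partition == "tp_overlap",
      "true positives", "false positives"
    ))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$model_i, y = .data$model_j, fill = .data$overlap)
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~partition) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Pairwise top-%d overlap", object$k)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot normalized score distributions per model
#'
#' Visualizes how thresholded, normalized score distributions compare across
#' models on the common `[0, 1]` scale.
#'
#' @param topk A [normalize_scores()] result.
#' @return A ggplot object: one density per model over the normalized scores.
#' @export
plot_score_distributions <- function(topk) {
  assert_columns(topk, c("model", "normalized"), "topk")
  ggplot2::ggplot(
    as_tibble(topk),
    ggplot2::aes(x = .data$normalized, colour = .data$model)
  ) +
    ggplot2::geom_density() +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "normalized score", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
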