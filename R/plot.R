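#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of MDCA scores
#'
#' Mirrors the conventional matrix layout: columns are the first unit of the
#' combination, rows the second. Attraction is red, repulsion blue.
#'
#' @param object A `colloc_mdca` result (run with `all = TRUE` for the full
#'   matrix).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.colloc_mdca <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$first, y = .data$second,
                                       fill = .data$score)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$score, 1)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "first call", y = "second call", fill = "pbin",
                  title = "Multiple Distinctive Collocation Analysis") +
    ggplot2::theme_minimal()
}

#' Dot plot of MICA scores
#'
#' @param object A `colloc_mica` result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.colloc_mica <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      pair = paste(.data$call_a, .data$call_b, sep = "-"))
  df$pair <- stats::reorder(df$pair, df$score)
  ggplot2::ggplot(df[is.finite(df$score), ],
                  ggplot2::aes(x = .data$score, y = .data$pair,
                               colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "MICA score (bits)", y = NULL, colour = NULL,
                  title = "Mutual Information Collocation Analysis") +
    ggplot2::theme_minimal()
}

#' Score-matrix heatmap for any corpus
#'
#' Convenience wrapper: tabulates, scores every ordered pair with [mdca()]
#' and draws the heatmap.
#'
#' @param data Anything [tabulate_bigrams()] accepts.
#' @param ... Passed to [tabulate_bigrams()].
#' @return A ggplot.
#' @export
plot_score_matrix <- function(data, ...) {
  autoplot(mdca(data, all = TRUE, ...))
}
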