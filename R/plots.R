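#' Plot an evaluation report
#'
#' Bar chart of Top1% (and average rank) per ranking metric and stratum.
#'
#' @param object a `meftop_evaluation` from [evaluate_selection()].
#' @param statistic column to plot (default `"top1_pct"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.meftop_evaluation <- function(object, statistic = "top1_pct", ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data[[statistic]],
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = statistic, fill = "metric") +
    ggplot2::theme_minimal()
}

#' Scatter of predicted score against true TM-score
#'
#' @param scored tibble with columns `tm`, the score column, and `target_id`.
#' @param score score column to plot (default `"p"`).
#' @return a ggplot object.
#' @export
plot_score_scatter <- function(scored, score = "p") {
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$tm, y = .data[[score]])) +
    ggplot2::geom_point(alpha = 0.4, ggplot2::aes(colour = .data$target_id)) +
    ggplot2::guides(colour = "none") +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = "TM-score to native", y = paste(score, "score")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
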