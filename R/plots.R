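#' Heatmap of the grid-search accuracy surface
#'
#' Tiles inner-CV accuracy over the (log2 C, log2 gamma) exponent lattice and
#' marks the selected pair.
#'
#' @param object An `ai_grid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ai_grid <- function(object, ...) {
  tab <- object$cv_table
  best <- tab[tab$C == object$C & tab$gamma == object$gamma, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$c_exponent,
                                    y = .data$gamma_exponent,
                                    fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = best, colour = "white", shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "CV accuracy") +
    ggplot2::labs(x = expression(log[2] ~ C),
                  y = expression(log[2] ~ gamma),
                  title = "Grid-search accuracy surface") +
    ggplot2::theme_minimal()
}

#' Metric bars for an evaluation result
#'
#' Bar chart of sensitivity, specificity, accuracy, and MCC.
#'
#' @param object An `ai_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ai_eval <- function(object, ...) {
  df <- tidy(object)
  df$metric <- factor(toupper(df$metric), levels = c("SN", "SP", "ACC", "MCC"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::ylim(min(0, min(df$value)), 1) +
    ggplot2::labs(x = NULL, y = "value",
                  title = paste0(object$protocol, " evaluation")) +
    ggplot2::theme_minimal()
}

#' Decision-score distribution by true class
#'
#' Histogram of per-sample decision values split by the true label; the
#' vertical line is the classification threshold at zero.
#'
#' @param eval_result An `ai_eval` object.
#' @param bins Number of histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(eval_result, bins = 30) {
  stopifnot(inherits(eval_result, "ai_eval"))
  ggplot2::ggplot(eval_result$predictions,
                  ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "decision score", y = "windows", fill = "true class") +
    ggplot2::theme_minimal()
}
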