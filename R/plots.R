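#' Plot smallest-best-confidence distributions
#'
#' Side-by-side histogram of the binned smallest-best-confidence fractions
#' for concordant and discordant pairs.
#'
#' @param object a [confidence_distributions()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot confidence_distributions
#' @export
autoplot.confidence_distributions <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin_lo + (object$bin_width / 2),
                               y = .data$fraction, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge",
                      width = object$bin_width * 0.9) +
    ggplot2::labs(x = "smallest best-candidate confidence",
                  y = "fraction of pairs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a subfamily drift matrix
#'
#' Heatmap of pairwise subfamily-conversion probabilities (log10 fill;
#' zero-probability cells are blank).
#'
#' @param object a [conversion_matrix()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot drift_matrix
#' @export
autoplot.drift_matrix <- function(object, ...) {
  d <- tidy(object)
  d$log10_p <- ifelse(d$probability > 0, log10(d$probability), NA_real_)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "converted to", y = "inserted as",
                  fill = "log10 P") +
    ggplot2::theme_minimal()
}

#' Plot per-family discordance rates
#'
#' @param summary a [summarize_discordance()] result.
#' @return a ggplot object.
#' @export
plot_discordance <- function(summary) {
  ggplot2::ggplot(summary$by_family,
                  ggplot2::aes(x = .data$family,
                               y = .data$percent_discordant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% discordant pairs") +
    ggplot2::theme_minimal()
}
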