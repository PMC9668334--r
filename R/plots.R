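# Result-type plots. Each returns a ggplot object so callers can restyle.

#' QQ plot of an association scan
#'
#' Observed vs expected -log10 p quantiles with the identity line; the
#' standard diagnostic for scan calibration.
#'
#' @param object An [lmm_scan()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assoc_scan <- function(object, ...) {
  qq <- qq_table(object)
  ggplot2::ggplot(qq, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = sprintf("QQ plot (%s response)",
                                  object$response_kind[1])) +
    ggplot2::theme_minimal()
}

#' Heritability bar chart from a quantitative-genetics table
#'
#' @param qg A [quantgen_table()] result.
#' @return A ggplot of per-trait broad-sense heritability.
#' @export
plot_heritability <- function(qg) {
  ggplot2::ggplot(qg, ggplot2::aes(stats::reorder(.data$trait, .data$H2),
                                   .data$H2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(H^2),
                  title = "Broad-sense heritability by trait") +
    ggplot2::theme_minimal()
}

#' Probability heat map of a PSSM
#'
#' @param object A `pssm`.
#' @param ... Unused.
#' @return A ggplot tile map of per-position base probabilities.
#' @export
autoplot.pssm <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$mat), .name_repair = "minimal")
  names(d) <- c("base", "position", "probability")
  d$position <- as.integer(factor(d$position, levels = unique(d$position)))
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$base,
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s (%s)", object$id, object$consensus),
                  x = "Position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Pearson-residual bar chart of a category bias test
#'
#' @param object A [category_bias_test()] result.
#' @param ... Unused.
#' @return A ggplot of per-category Pearson residuals.
#' @export
autoplot.category_bias <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$category, .data$residual,
                               fill = .data$residual > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Pearson residual",
                  title = "Genomic-location bias of candidate variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
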