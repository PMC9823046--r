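# ggplot2 helpers for the main result types.

#' Plot a required-sample-size power curve
#'
#' @param curve Output of [required_n_curve()].
#' @param log_y Plot the pair count on a log scale (default TRUE).
#' @return A ggplot.
#' @export
plot_power_curve <- function(curve, log_y = TRUE) {
  p <- ggplot2::ggplot(
    dplyr::filter(curve, !.data$flagged),
    ggplot2::aes(x = .data$r2_instrument, y = .data$n_pairs_80)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = expression(R^2 ~ "of Ph1 on PS1"),
      y = "twin pairs for 80% power",
      title = "Sample size required to reject g1 = 0"
    ) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot per-parameter bias from a violation study
#'
#' @param bias An `mrdoc_bias` object.
#' @param terms Parameters to show (default: the causal paths, instrument
#'   paths and background correlations).
#' @return A ggplot.
#' @export
plot_bias <- function(bias,
                      terms = c("g1", "g2", "b1", "b3", "e1", "e2",
                                "ra", "rc", "re")) {
  d <- dplyr::filter(bias$estimates, .data$term %in% terms) |>
    dplyr::mutate(term = factor(.data$term, levels = terms))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "bias (estimate - truth)",
                  title = paste0("Parameter bias: ", bias$experiment)) +
    ggplot2::theme_minimal()
  if ("mc_se" %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$bias - 2 * .data$mc_se,
                   ymax = .data$bias + 2 * .data$mc_se),
      width = 0.2
    )
  }
  p
}

#' Plot power across the cells of a factorial design run
#'
#' @param cells Output of [run_design()].
#' @param test Which test's power to show (`"g1"`, `"g2"`, `"joint"`).
#' @param x Parameter to place on the abscissa (default `"b1"`).
#' @return A ggplot.
#' @export
plot_design_power <- function(cells, test = "g1", x = "b1") {
  pow_col <- paste0("pow_", test)
  stopifnot(pow_col %in% names(cells), x %in% names(cells))
  ggplot2::ggplot(
    cells,
    ggplot2::aes(x = factor(round(.data[[x]]^2, 3)), y = .data[[pow_col]])
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = paste0(x, "^2 (variance scale)"),
                  y = paste0("power to reject ", test, " = 0")) +
    ggplot2::theme_minimal()
}
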