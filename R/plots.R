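# Plotting helpers (ggplot2).

#' Forest-style plot of odds ratios
#'
#' @param results Named list of `l1_assoc` objects (names become labels) or
#'   a single `l1_assoc`.
#' @return A ggplot.
#' @export
plot_odds_ratios <- function(results) {
  if (inherits(results, "l1_assoc")) results <- list(association = results)
  df <- purrr::imap(results, function(x, nm) {
    dplyr::mutate(tidy(x), label = nm)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci95_low, xmax = .data$ci95_high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname chisq_or
#' @param object An `l1_assoc`.
#' @method autoplot l1_assoc
#' @export
autoplot.l1_assoc <- function(object, ...) plot_odds_ratios(object)

#' Volcano-style view of a feature screen
#'
#' @param screen [run_feature_screen()] output.
#' @return A ggplot of -log10 p by feature, coloured by direction.
#' @export
plot_feature_screen <- function(screen) {
  ggplot2::ggplot(screen, ggplot2::aes(
    x = .data$feature, y = -log10(pmax(.data$p, 1e-300)),
    fill = .data$direction
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~mode, scales = "free_x") +
    ggplot2::geom_hline(yintercept = -log10(0.001), linetype = 2) +
    ggplot2::labs(x = NULL, y = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
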