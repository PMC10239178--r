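#' Forest plot of mediation-effect confidence intervals
#'
#' One point-range per mediation test (ACME with its bootstrap CI),
#' faceted by outcome, coloured by FDR significance.
#'
#' @param object An `eaa_grid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eaa_grid <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$acme, y = .data$mediator,
                                      colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$acme_low,
                                          xmax = .data$acme_high)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$exposure),
                        cols = ggplot2::vars(.data$outcome)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "FDR < alpha") +
    ggplot2::labs(x = "Mediation effect (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Confidence-interval plot for a single mediation result
#'
#' @param object An `eaa_mediation` object.
#' @param ... Unused.
#' @return A ggplot object showing ACME, ADE and total effect with their
#'   bootstrap CIs.
#' @export
autoplot.eaa_mediation <- function(object, ...) {
  est <- object$estimates
  est$effect <- factor(est$effect, levels = c("total", "ade", "acme"))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      title = sprintf("%s -> %s -> %s", object$exposure, object$mediator,
                      object$outcome),
      x = "Effect (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap
#'
#' @param cohort A data frame.
#' @param vars Numeric columns to correlate (see [correlation_matrix()]).
#' @return A ggplot tile heatmap of pairwise Pearson correlations.
#' @export
plot_correlation_heatmap <- function(cohort, vars) {
  r <- correlation_matrix(cohort, vars)
  df <- as.data.frame(as.table(r))
  names(df) <- c("var1", "var2", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
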