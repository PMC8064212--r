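#' Forest plot of category association estimates
#'
#' @param object An `aaci_assoc` result.
#' @param ... Unused.
#' @return A ggplot: estimates with confidence intervals per category,
#'   faceted by model, on a log scale with the reference line at 1.
#' @method autoplot aaci_assoc
#' @export
autoplot.aaci_assoc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ .data$model, nrow = 1) +
    ggplot2::labs(
      x = attr(object, "exposure"), y = "RR (odds ratio, 95% CI)",
      title = sprintf("Association with %s", attr(object, "outcome"))
    ) +
    ggplot2::theme_minimal()
}

#' Mediation decomposition plot
#'
#' @param object An `aaci_mediation` result.
#' @param ... Unused.
#' @return A ggplot of per-mediator indirect effects (with bootstrap
#'   intervals) and the percent mediated as labels.
#' @method autoplot aaci_mediation
#' @export
autoplot.aaci_mediation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mediator, y = .data$indirect)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$indirect_low, ymax = .data$indirect_high)
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
      vjust = -1, size = 3
    ) +
    ggplot2::labs(
      x = NULL, y = "standardized indirect effect (a x b)",
      title = sprintf("Mediation of %s -> %s", object$spec$exposure,
                      object$spec$outcome)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap-style plot of standardized serum associations
#'
#' @param data Output of [fit_linear_std()] across serum outcomes and
#'   ladder models.
#' @return A ggplot tile map of standardized coefficients with
#'   significance stars.
#' @export
plot_serum_associations <- function(data) {
  d <- dplyr::mutate(
    data,
    outcome = sub("^serum_", "", .data$outcome),
    label = sprintf("%.3f%s", .data$beta, .data$stars)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$outcome,
                                  fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "standardized\nbeta") +
    ggplot2::theme_minimal()
}
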