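# ggplot2 displays for the main result types.

#' @rdname visit_summary
#' @param object A `visit_summary`.
#' @param ... Unused.
#' @method autoplot visit_summary
#' @export
autoplot.visit_summary <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$visit, y = .data$mean, group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "Visit", y = object$metric,
                  title = sprintf("%s across visits (mean +/- SD)", object$metric)) +
    ggplot2::theme_minimal()
}

#' @rdname standardize
#' @param object A `clpm_fit`.
#' @param ... Unused.
#' @method autoplot clpm_fit
#' @export
autoplot.clpm_fit <- function(object, ...) {
  d <- standardize(object) %>%
    filter(!grepl("^b_", .data$label)) %>% # structural paths only
    mutate(path = paste(.data$predictor, "→", .data$outcome))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$std_estimate,
                                  y = stats::reorder(.data$path, .data$std_estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$std_estimate - 1.96 * .data$std_se,
      xmax = .data$std_estimate + 1.96 * .data$std_se
    )) +
    ggplot2::labs(x = "Standardized coefficient (95% CI)", y = NULL,
                  title = "Structural path coefficients") +
    ggplot2::theme_minimal()
}

#' @rdname decompose
#' @param object An `effect_decomposition`.
#' @param ... Unused.
#' @method autoplot effect_decomposition
#' @export
autoplot.effect_decomposition <- function(object, ...) {
  d <- tibble(
    component = factor(c("direct", "indirect", "total"),
                       levels = c("direct", "indirect", "total")),
    estimate = c(object$direct, object$indirect, object$total),
    se = c(object$direct_se, object$indirect_se, object$total_se)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - 1.96 * .data$se,
                                        ymax = .data$estimate + 1.96 * .data$se),
                           width = 0.2) +
    ggplot2::labs(
      x = NULL, y = "Standardized effect",
      title = sprintf("%s → %s", object$predictor, object$outcome)
    ) +
    ggplot2::theme_minimal()
}
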