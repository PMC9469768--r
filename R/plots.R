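# ggplot2 displays for the package's result types.

#' Plot a confusion matrix as a tile heatmap
#'
#' @param object A `tier_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tier_confusion <- function(object, ...) {
  df <- tidy.tier_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "true class", y = "predicted class",
                  title = paste(attr(object, "scheme"), "confusion matrix")) +
    ggplot2::theme_minimal()
}

#' Residuals-vs-fitted plot for a calibration
#'
#' @param object A fitted `chlorine_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chlorine_calibration <- function(object, ...) {
  d <- residual_diagnostics(object)
  ggplot2::ggplot(d$residuals_fitted,
                  ggplot2::aes(x = .data$fitted, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::labs(x = "fitted concentration (mg/L)", y = "residual (mg/L)",
                  title = paste("residuals vs fitted:", object$family)) +
    ggplot2::theme_minimal()
}

#' Plot the concentration-to-color model
#'
#' Shows the interpolated mean channel values and the RGB sum against
#' concentration, with the per-tier channel boxes.
#'
#' @param model A [color_model()].
#' @param max_conc Upper concentration bound for the curves.
#' @return A ggplot.
#' @export
plot_color_model <- function(model = color_model(), max_conc = 4) {
  cs <- seq(0, max_conc, length.out = 200)
  cols <- anchor_color(model, cs)
  df <- tibble::tibble(
    concentration = rep(cs, 4),
    value = c(cols[, 1], cols[, 2], cols[, 3], rowSums(cols)),
    channel = rep(c("R", "G", "B", "RGB sum"), each = length(cs))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration, y = .data$value,
                                   color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(R = "red3", G = "green4",
                                           B = "blue3", `RGB sum` = "gray30")) +
    ggplot2::labs(x = "free chlorine (mg/L)", y = "color value",
                  title = "pad color model") +
    ggplot2::theme_minimal()
}
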