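#' Plot a density-dependence curve
#'
#' Scatter of pcgr against starting density with the fitted regression line;
#' excluded influential points, if any, are drawn as open triangles.
#'
#' @param object A `dd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dd_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n_start, y = .data$pcgr)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$mu, slope = object$alpha,
                         colour = "steelblue") +
    ggplot2::labs(x = "starting density (cells/mL)",
                  y = "per-capita growth rate (/day)",
                  title = object$condition_id,
                  subtitle = sprintf("mu = %.3f, alpha = %.2e, K = %.0f",
                                     object$mu, object$alpha,
                                     -object$mu / object$alpha)) +
    ggplot2::theme_minimal()
  if (nrow(object$excluded) > 0) {
    p <- p + ggplot2::geom_point(data = object$excluded, shape = 2, size = 3,
                                 colour = "firebrick")
  }
  p
}

#' Plot the AICc comparison of linkage variants
#'
#' Dot plot of AICc per model variant, faceted by demographic response, best
#' model highlighted.
#'
#' @param object A `linkage_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_selection <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = rev(model_variants()$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$AICc, y = .data$model,
                                    colour = .data$is_best)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~response, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot index responses by treatment
#'
#' @param responses Output of [index_response()].
#' @param which `"delta_mean"` or `"delta_variance"`.
#' @return A ggplot object: responses by strain, coloured by pollutant level,
#'   faceted by species x temperature.
#' @export
plot_index_response <- function(responses, which = "delta_mean") {
  ggplot2::ggplot(responses,
                  ggplot2::aes(x = .data$strain, y = .data[[which]],
                               colour = factor(.data$pollutant))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_grid(.data$species ~ .data$temperature) +
    ggplot2::labs(colour = "pollutant (ug/mL)", y = which) +
    ggplot2::theme_minimal()
}

#' Show one rendered frame
#'
#' @param stack Image stack array.
#' @param frame 1-based frame index.
#' @return A ggplot raster plot of the frame.
#' @export
plot_frame <- function(stack, frame = 1) {
  img <- stack[, , frame]
  d <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  d$value <- as.vector(img)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
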