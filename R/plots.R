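#' Plot an alpha-angle measurement
#'
#' Draws the outline landmarks, the circle of best fit, the narrowest-neck
#' line with its midpoint, and (when an index point was found) the two
#' rays defining the alpha angle together with the intersection position.
#' Coordinates are shown in mm with the y axis reversed, matching image
#' orientation.
#'
#' @param object An [compute_alpha()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot alpha_result
#' @export
autoplot.alpha_result <- function(object, ...) {
  op <- object$points
  s <- attr(op, "pixel_spacing_mm")
  pts <- tibble::tibble(landmark = op$landmark, x = op$x * s, y = op$y * s,
                        fit = op$landmark >= 15 & op$landmark <= 28)
  th <- seq(0, 2 * pi, length.out = 181)
  circ <- tibble::tibble(x = object$circle$centre[1] +
                           object$circle$radius * cos(th),
                         y = object$circle$centre[2] +
                           object$circle$radius * sin(th))
  neck <- tibble::tibble(x = c(object$neck$endpoint_a[1],
                               object$neck$endpoint_b[1]),
                         y = c(object$neck$endpoint_a[2],
                               object$neck$endpoint_b[2]))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, colour = "steelblue") +
    ggplot2::geom_path(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fit), size = 1.5,
                        show.legend = FALSE) +
    ggplot2::geom_line(data = neck, colour = "darkorange") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey30")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = if (object$status == "OK")
                    sprintf("alpha angle %.1f° (model %d)%s",
                            object$alpha_deg, object$model_version,
                            if (isTRUE(object$cam)) ", cam" else "")
                  else sprintf("NO_DEVIATION (model %d)",
                               object$model_version)) +
    ggplot2::theme_minimal()
  if (object$status == "OK") {
    ctr <- object$circle$centre
    rays <- tibble::tibble(
      x = rep(ctr[1], 2),
      y = rep(ctr[2], 2),
      xend = c(object$neck$midpoint[1], object$intersection$coords[1]),
      yend = c(object$neck$midpoint[2], object$intersection$coords[2]))
    p <- p +
      ggplot2::geom_segment(data = rays,
                            ggplot2::aes(xend = .data$xend,
                                         yend = .data$yend),
                            colour = "firebrick") +
      ggplot2::annotate("point", x = object$intersection$coords[1],
                        y = object$intersection$coords[2],
                        colour = "firebrick", size = 2.5, shape = 17)
  }
  p
}

#' @rdname autoplot.alpha_result
#' @param x An [compute_alpha()] result.
#' @param y Unused.
#' @export
plot.alpha_result <- function(x, y, ...) print(autoplot.alpha_result(x, ...))

#' Bland-Altman plot
#'
#' Differences against pairwise means, with the mean difference (solid)
#' and the limits of agreement (dashed); outliers beyond the limits are
#' labelled with their ids.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$diff)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier),
                        show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_text(data = dplyr::filter(object$data, .data$outlier),
                       ggplot2::aes(label = .data$id),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30")) +
    ggplot2::labs(x = "pairwise mean", y = "difference") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bland_altman
#' @param x A [bland_altman()] result.
#' @param y Unused.
#' @export
plot.bland_altman <- function(x, y, ...) print(autoplot.bland_altman(x, ...))
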