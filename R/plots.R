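#' Plot a gray image or mask
#'
#' Renders an image matrix (or logical mask) with ggplot2, origin top-left
#' as in image viewers.
#'
#' @param img Gray matrix in `[0, 255]` or logical mask.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_gray_image <- function(img, title = NULL) {
  if (is.logical(img)) img <- ifelse(img, 255, 0)
  assert_gray_image(img)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)),
                           col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "gray") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_gray_image Plot a synthetic scene's rendered image.
#' @param x Object to plot.
#' @param ... Unused.
#' @export
plot.mii_scene <- function(x, ...) {
  plot_gray_image(x$image,
                  title = sprintf("synthetic scene (true biomass %d px)",
                                  x$true_biomass_px))
}

#' @describeIn plot_gray_image Plot a transformed micrograph.
#' @export
plot.mii_transform <- function(x, ...) {
  plot_gray_image(x$transformed, title = sprintf("MII = %.2f", x$mii))
}

#' Calibration scatter with the fitted line
#'
#' @param object An `mii_fit`.
#' @param ... Unused.
#' @return A ggplot: MII against DCW with the OLS line and its 95%
#'   confidence band.
#' @export
autoplot.mii_fit <- function(object, ...) {
  grid <- tibble::tibble(mii = seq(min(object$data$mii),
                                   max(object$data$mii),
                                   length.out = 100))
  x0 <- mean(object$data$mii)
  sxx <- sum((object$data$mii - x0)^2)
  se_fit <- object$sigma *
    sqrt(1 / object$n + (grid$mii - x0)^2 / sxx)
  tq <- stats::qt(0.975, object$df_residual)
  grid$fit <- object$beta0 + object$beta1 * grid$mii
  grid$lo <- grid$fit - tq * se_fit
  grid$hi <- grid$fit + tq * se_fit
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mii, y = .data$dcw)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(x = .data$mii, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$mii, y = .data$fit),
                       inherit.aes = FALSE, linewidth = 0.8,
                       colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "microscopic image intensity (MII)",
      y = "dry cell weight (mg/L)",
      title = sprintf("DCW = %.2f + %.3f MII   (R² = %.3f, n = %d)",
                      object$beta0, object$beta1, object$r_squared,
                      object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Per-dilution-group calibration quality
#'
#' @param object An `mii_dilution` report from [dilution_analysis()].
#' @param ... Unused.
#' @return A ggplot bar chart of R^2 per dilution group.
#' @export
autoplot.mii_dilution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$dilution_label <- factor(df$dilution_label,
                              levels = df$dilution_label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dilution_label,
                                   y = .data$r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f",
                                                    .data$r_squared)),
                       vjust = -0.4, na.rm = TRUE) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = "dilution factor", y = expression(R^2),
                  title = "Calibration quality by dilution factor") +
    ggplot2::theme_minimal()
}
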