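# ggplot2 graphics for fitted objects.

#' Plot a feature-weight profile
#'
#' Weights against feature index, with retained features highlighted.
#'
#' @param object A `wld_weights` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wld_weights
#' @export
autoplot.wld_weights <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$weight,
                                  color = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature, yend = 0),
                          linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey70", `TRUE` = "#21618c")) +
    ggplot2::labs(
      x = "feature index", y = "relevance weight",
      title = sprintf("Feature relevances (sigma = %g, lambda = %g)",
                      object$sigma, object$lambda)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated ROC curves
#'
#' One curve per fold plus the chance diagonal; the subtitle reports the
#' mean Az across folds.
#'
#' @param object An `mswld_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom rlang .data
#' @method autoplot mswld_eval
#' @export
autoplot.mswld_eval <- function(object, ...) {
  pts <- roc_points(object, by_fold = TRUE)
  s <- eval_summary(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    group = .data$fold,
                                    color = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity", color = "fold",
      title = "Cross-validated ROC",
      subtitle = sprintf("mean Az = %.3f +/- %.3f", s$az, s$az_sd)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a grayscale ROI
#'
#' @param img Intensity matrix.
#' @param title Optional plot title.
#' @return A ggplot rendering of the image.
#' @export
plot_roi <- function(img, title = NULL) {
  assert_gray_image(img)
  d <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  d$intensity <- as.vector(img)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
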