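# ggplot2 views of the result objects.

#' Plot an evaluation report
#'
#' `type = "histogram"` draws the median-of-runs signed-error histogram
#' (positive errors = under-counting); `type = "fit"` draws the bubble plot
#' of predicted against true counts (bubble area proportional to tile
#' multiplicity) with the least-squares line and the identity line.
#'
#' @param object An `eval_report` from [evaluate_model()].
#' @param type `"histogram"` or `"fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, type = c("histogram", "fit"), ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$error, y = .data$n)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::labs(x = "count error (truth - prediction)", y = "tiles",
                    title = sprintf("%.1f%% of errors within ±3",
                                    100 * object$fraction_within_3)) +
      ggplot2::theme_minimal()
  } else {
    p <- ggplot2::ggplot(object$bubble,
                         ggplot2::aes(x = .data$truth, y = .data$pred,
                                      size = .data$n_tiles)) +
      ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::scale_size_area() +
      ggplot2::labs(x = "ground-truth count", y = "predicted count (median of runs)",
                    size = "tiles") +
      ggplot2::theme_minimal()
    if (!is.null(object$fit)) {
      p <- p + ggplot2::geom_abline(slope = object$fit$slope,
                                    intercept = object$fit$intercept,
                                    colour = "firebrick")
    }
    p
  }
}

#' Plot a density map
#'
#' @param object A [density_map()].
#' @param ... Unused.
#' @return A ggplot raster of the map (origin top-left, as in image
#'   coordinates).
#' @export
autoplot.density_map <- function(object, ...) {
  v <- object$values
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$value <- v[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("density map, global count %.2f",
                                  sum(v))) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene with its ground-truth points
#'
#' @param object A `boll_scene`.
#' @param show_points Overlay the ground-truth boll centres.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boll_scene <- function(object, show_points = TRUE, ...) {
  img <- object$image
  h <- nrow(img); w <- ncol(img)
  df <- tidyr::expand_grid(y = seq_len(h) - 1L, x = seq_len(w) - 1L)
  df$fill <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%d boll(s)", object$count))
  if (show_points && object$count > 0) {
    p <- p + ggplot2::geom_point(data = object$points, colour = "red",
                                 shape = 3, size = 2)
  }
  p
}
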