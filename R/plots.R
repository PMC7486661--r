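#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RGC mosaic
#' @param object An `rgc_mosaic`.
#' @param ... Unused.
#' @export
autoplot.rgc_mosaic <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, colour = .data$polarity)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a rendered map (orientation, similarity, activity or correlation)
#' @param object An `rw_map`.
#' @param ... Unused.
#' @export
autoplot.rw_map <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(object$xs, length(object$ys)),
    y = rep(object$ys, each = length(object$xs)),
    value = as.vector(object$values)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = object$kind) +
    ggplot2::theme_minimal()
  if (object$kind == "orientation") {
    p + ggplot2::scale_fill_gradientn(
      colours = c("#d73027", "#fee090", "#1a9850", "#4575b4", "#d73027"),
      limits = c(0, 180), na.value = "grey90")
  } else {
    p + ggplot2::scale_fill_gradient2(na.value = "grey90")
  }
}

#' Plot a group trend (mean value per orientation-difference bin)
#' @param object An `rw_trend`.
#' @param ... Unused.
#' @export
autoplot.rw_trend <- function(object, ...) {
  ggplot2::ggplot(object$groups, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "orientation difference bin", y = "group mean",
                  subtitle = sprintf("%s trend: z = %.2f, p = %.2g",
                                     object$method, object$z, object$p)) +
    ggplot2::theme_minimal()
}
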