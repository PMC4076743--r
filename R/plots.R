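# ggplot2 views of the result objects.

#' @export
autoplot.parcellation <- function(object, coords = NULL, ...) {
  df <- tidy(object)
  if (is.null(coords))
    stop_bad_arg("supply `coords` (Q x 2 matrix) to draw a parcellation")
  df$x <- coords[, 1L]
  df$y <- coords[, 2L]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = factor(.data$parcel))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "parcel") +
    ggplot2::theme_minimal()
}

#' Plot a labeling over a 2D grid
#'
#' @param labels integer labels, a [new_parcellation()] or a
#'   `ground_truth`.
#' @param grid_shape integer pair of pixel dimensions.
#' @return A ggplot object.
#' @export
plot_labeling <- function(labels, grid_shape) {
  if (inherits(labels, "parcellation")) labels <- labels$labels
  if (inherits(labels, "ground_truth")) {
    grid_shape <- labels$grid_shape
    labels <- labels$labeling
  }
  coords <- arrayInd(seq_along(labels), grid_shape)
  df <- tibble(x = coords[, 2L], y = coords[, 1L],
               parcel = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$parcel)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}

#' @export
autoplot.criterion_curve <- function(object, ...) {
  K_star <- select_K(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$K, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = K_star, linetype = "dashed") +
    ggplot2::labs(y = attr(object, "criterion"),
                  subtitle = sprintf("selected K* = %d", K_star)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.parcel_experiment <- function(object, ...) {
  K_true <- object$config$simulation$K_true
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$method, .data$K_star)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = K_true, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::labs(y = "selected K*",
                  caption = "dashed line: true number of parcels") +
    ggplot2::theme_minimal()
}

#' Plot variance components against the number of parcels
#'
#' @param curve output of [variance_component_curve()].
#' @return A ggplot object.
#' @export
plot_variance_components <- function(curve) {
  df <- tidyr::pivot_longer(curve[, c("K", "sigma1", "sigma2")],
                            c("sigma1", "sigma2"),
                            names_to = "component", values_to = "sd")
  ggplot2::ggplot(df, ggplot2::aes(.data$K, .data$sd,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "estimated standard deviation") +
    ggplot2::theme_minimal()
}
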