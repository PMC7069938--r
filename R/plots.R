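#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a delay-and-sum image
#'
#' @param object A `sparsus_das`.
#' @param what `"envelope"` (default) or `"amplitude"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sparsus_das <- function(object, what = c("envelope", "amplitude"), ...) {
  what <- match.arg(what)
  img <- object[[what]]
  g <- object$grid
  df <- tidyr::expand_grid(x = g$x, z = g$z)
  df$value <- as.vector(t(img)) # row = z, col = x; expand_grid is x-major
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e3, y = .data$z * 1e3,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral position (mm)", y = "depth (mm)",
                  fill = what, title = "Delay-and-sum reconstruction") +
    ggplot2::scale_fill_viridis_c()
}

#' Plot a post-processed display image
#'
#' @param object A `sparsus_display`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sparsus_display <- function(object, ...) {
  df <- tidyr::expand_grid(x = object$x, z = object$z)
  df$value <- as.vector(t(object$pixels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e3, y = .data$z * 1e3,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral position (mm)", y = "depth (mm)",
                  fill = "amplitude",
                  title = "Sparse model-based reconstruction") +
    ggplot2::scale_fill_viridis_c()
}

#' Heat map of mean correlation against SNR and element count
#'
#' @param object A `sparsus_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sparsus_sweep <- function(object, ...) {
  df <- object$mean_C
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$N),
                                   y = factor(round(.data$snr, 2)),
                                   fill = .data$mean_C)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "number of elements N", y = "SNR",
                  fill = "mean C",
                  title = "Reconstruction quality vs SNR and element count") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1))
}
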