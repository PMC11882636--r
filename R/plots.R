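#' Plot the size distribution of measured aggregates
#'
#' Histogram of equivalent spherical diameters of the measured 3D
#' components, optionally split by their dominant compartment (inside or
#' outside the soma).
#'
#' @param records An `aggregate_records` tibble from
#'   [measure_components()] (or a `stack_quant` result).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(records, bins = 30) {
  if (inherits(records, "stack_quant")) records <- records$records
  df <- as_tibble(records)
  df$compartment <- ifelse(df$inside_volume >= df$outside_volume,
                           "inside soma", "outside soma")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$equivalent_diameter,
                                   fill = .data$compartment)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8, position = "stack") +
    ggplot2::labs(x = "equivalent diameter (µm)", y = "aggregates",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_size_distribution
#' @param object A `stack_quant` result.
#' @param ... Unused.
#' @export
autoplot.stack_quant <- function(object, ...) plot_size_distribution(object)

#' Map of segmented nuclei and their double-positive calls
#'
#' Plots particle centroids sized by area and colored by the
#' double-positive call, a quick QC view of a counting run.
#'
#' @param calls A `neuron_calls` tibble or `mn_count` result.
#' @return A ggplot object.
#' @export
plot_neuron_calls <- function(calls) {
  if (inherits(calls, "mn_count")) calls <- calls$calls
  df <- as_tibble(calls)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                                   size = .data$area, color = .data$positive)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "double positive",
                  size = "area") +
    ggplot2::theme_minimal()
}

#' @rdname plot_neuron_calls
#' @param object An `mn_count` result.
#' @param ... Unused.
#' @export
autoplot.mn_count <- function(object, ...) plot_neuron_calls(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
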