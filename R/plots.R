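# ggplot2 views of the pipeline's result tables.

#' Map of per-pixel Kd(490) trends
#'
#' Tile map of either the trend classification (red = increasing / darker
#' water, blue = decreasing, white = no change, grey = insufficient data)
#' or the fitted slope.
#'
#' @param object A `kd_trends` tibble.
#' @param what `"classification"` or `"slope"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kd_trends
#' @export
autoplot.kd_trends <- function(object, what = c("classification", "slope"),
                               ...) {
  what <- match.arg(what)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat))
  if (what == "classification") {
    p <- p +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$classification)) +
      ggplot2::scale_fill_manual(values = c(
        increasing = "#b2182b", decreasing = "#2166ac",
        no_change = "white", insufficient_data = "grey70"))
  } else {
    p <- p +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$slope)) +
      ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b", midpoint = 0)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = if (what == "slope")
                    expression(Delta * K[d](490) ~ (m^-1 ~ yr^-1)) else NULL)
}

#' Map of photic-zone depth change
#'
#' @param object A `photic_change` tibble.
#' @param ... Unused.
#' @return A ggplot object faceted by luminary; red = shallower photic
#'   zone.
#' @method autoplot photic_change
#' @export
autoplot.photic_change <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data$delta_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::facet_wrap(~luminary) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = expression(Delta * Z[photic] ~ (m)))
}

#' Latitude-by-month surface irradiance heat map
#'
#' @param object An `irradiance_field` tibble.
#' @param luminary `"sun"` or `"moon"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot irradiance_field
#' @export
autoplot.irradiance_field <- function(object, luminary = c("sun", "moon"),
                                      ...) {
  luminary <- match.arg(luminary)
  col <- paste0(luminary, "_band")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$month, y = .data$latitude,
                                       fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Month", y = "Latitude",
                  fill = expression(W ~ m^-2 ~ "(485-495 nm)"))
}

#' Area histogram of photic-depth change
#'
#' Bar chart of ocean area per depth-change bin, the companion of the
#' threshold-area summaries.
#'
#' @param histogram Output of [delta_histogram()].
#' @return A ggplot object faceted by luminary.
#' @export
plot_delta_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$bin_lo + (.data$bin_hi - .data$bin_lo) / 2,
                               y = .data$area_km2, fill = .data$direction)) +
    ggplot2::geom_col(width = (histogram$bin_hi - histogram$bin_lo)[1] * 0.9) +
    ggplot2::scale_fill_manual(values = c(reduction = "#b2182b",
                                          increase = "#2166ac")) +
    ggplot2::facet_wrap(~luminary) +
    ggplot2::labs(x = expression("|" * Delta * Z[photic] * "| bin (m)"),
                  y = expression(Area ~ (km^2)))
}

#' Region ranking bar chart
#'
#' Regions ranked by the percentage of their assessed area over which
#' Kd(490) is increasing.
#'
#' @param summary Output of [region_summary()].
#' @return A ggplot object.
#' @export
plot_region_ranking <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$region,
                                                  -.data$pct_increasing),
                               y = .data$pct_increasing)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::labs(x = NULL, y = "% of area with increasing Kd(490)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
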