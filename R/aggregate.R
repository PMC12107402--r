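# Area-based summaries: per-region darkening fractions, threshold areas and
# 10 m-increment histograms of photic-zone change.

EARTH_RADIUS_KM <- 6371.0088

#' Ground area of a grid cell
#'
#' Two conventions are provided. `"spherical"` (default) is exact on the
#' sphere: `R^2 * dlon * (sin(lat + h) - sin(lat - h))` for a cell of
#' half-height `h`. `"mercator_grid"` reproduces the footprint of a point
#' grid spaced `spacing_m` metres apart in a World Mercator projection,
#' `(spacing * cos(lat))^2` -- the convention of analyses that count
#' Mercator-spaced points; it is not equal-area, and the discrepancy
#' between the two modes is a feature to surface, not hide.
#'
#' @param latitude Cell-centre latitude(s), degrees.
#' @param cell_lat,cell_lon Cell size in degrees (spherical mode).
#' @param spacing_m Point spacing in projected metres (mercator_grid mode,
#'   default 9000).
#' @param mode `"spherical"` or `"mercator_grid"`.
#' @return Area(s) in km^2.
#' @examples
#' pixel_area(0, cell_lat = 1, cell_lon = 1)            # ~12364 km^2
#' pixel_area(60, mode = "mercator_grid")               # (9 * 0.5)^2 km^2
#' @export
pixel_area <- function(latitude, cell_lat = 1, cell_lon = 1,
                       spacing_m = 9000,
                       mode = c("spherical", "mercator_grid")) {
  mode <- match.arg(mode)
  if (any(abs(latitude) > 90)) stop("latitude out of range", call. = FALSE)
  if (mode == "spherical") {
    h <- cell_lat / 2
    lat_hi <- pmin(90, latitude + h) * DEG
    lat_lo <- pmax(-90, latitude - h) * DEG
    EARTH_RADIUS_KM^2 * (cell_lon * DEG) * (sin(lat_hi) - sin(lat_lo))
  } else {
    (spacing_m / 1000 * cos(latitude * DEG))^2
  }
}

# attach a pixel area column, using the grid cell size when available
.with_area <- function(data, grid = NULL, mode = "spherical",
                       spacing_m = 9000) {
  cl_lat <- if (!is.null(grid)) grid$cell_lat else 1
  cl_lon <- if (!is.null(grid)) grid$cell_lon else 1
  dplyr::mutate(data, area_km2 = pixel_area(
    .data$lat, cell_lat = cl_lat, cell_lon = cl_lon,
    spacing_m = spacing_m, mode = mode))
}

#' Per-region darkening summary
#'
#' Joins a per-pixel trend classification with a region labelling,
#' area-weights each pixel, and ranks regions by the percentage of their
#' assessed area over which Kd(490) is increasing. Pixels classified
#' `insufficient_data` are excluded from the percentage denominator and
#' reported separately.
#'
#' @param trends A `kd_trends` tibble ([kd_trends()]).
#' @param regions Data frame with `pixel`, `region_id`, `region`
#'   ([simulate_regions()]).
#' @param mode,spacing_m Area convention (see [pixel_area()]).
#' @return A tibble of class `region_summary`, ranked by `pct_increasing`:
#'   per region the total and per-classification areas (km^2), the
#'   assessed area and `pct_increasing`.
#' @export
region_summary <- function(trends, regions,
                           mode = c("spherical", "mercator_grid"),
                           spacing_m = 9000) {
  mode <- match.arg(mode)
  grid <- attr(trends, "grid")
  dat <- dplyr::inner_join(
    tibble::as_tibble(trends),
    dplyr::select(tibble::as_tibble(regions), "pixel", "region_id", "region"),
    by = "pixel"
  ) |>
    .with_area(grid, mode, spacing_m)
  out <- dat |>
    dplyr::group_by(.data$region_id, .data$region) |>
    dplyr::summarise(
      total_area = sum(.data$area_km2),
      area_increasing = sum(.data$area_km2[.data$classification == "increasing"]),
      area_decreasing = sum(.data$area_km2[.data$classification == "decreasing"]),
      area_no_change = sum(.data$area_km2[.data$classification == "no_change"]),
      area_insufficient = sum(.data$area_km2[.data$classification == "insufficient_data"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      assessed_area = .data$total_area - .data$area_insufficient,
      pct_increasing = dplyr::if_else(
        .data$assessed_area > 0,
        100 * .data$area_increasing / .data$assessed_area, NA_real_),
      pct_decreasing = dplyr::if_else(
        .data$assessed_area > 0,
        100 * .data$area_decreasing / .data$assessed_area, NA_real_)
    ) |>
    dplyr::arrange(dplyr::desc(.data$pct_increasing)) |>
    dplyr::mutate(rank = dplyr::row_number())
  tibble::new_tibble(out, class = "region_summary")
}

#' Ocean areas beyond photic-depth loss thresholds
#'
#' Areas (km^2) over which the photic zone shallowed by strictly more than
#' each depth threshold (default 10/50/100 m) and each percentage threshold
#' (default 10%/50%), per luminary, with percentages relative to the total
#' assessed area.
#'
#' @param change A `photic_change` tibble ([photic_change()]).
#' @param grid Optional [grid_spec()] providing the cell size (taken from
#'   the `change` attributes when present).
#' @param thresholds_m Depth-loss thresholds, m.
#' @param thresholds_pct Percent-loss thresholds.
#' @param mode,spacing_m Area convention (see [pixel_area()]).
#' @return Tibble: `luminary`, `threshold`, `kind` (`depth_m` or
#'   `percent`), `area_km2`, `pct_of_total`.
#' @export
threshold_areas <- function(change, grid = NULL, thresholds_m = c(10, 50, 100),
                            thresholds_pct = c(10, 50),
                            mode = c("spherical", "mercator_grid"),
                            spacing_m = 9000) {
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- attr(change, "grid")
  dat <- .with_area(tibble::as_tibble(change), grid, mode, spacing_m)
  per_lum <- dat |> dplyr::group_by(.data$luminary)
  totals <- per_lum |> dplyr::summarise(total = sum(.data$area_km2))
  rows <- list()
  for (th in thresholds_m) {
    rows[[length(rows) + 1]] <- per_lum |>
      dplyr::summarise(area_km2 = sum(.data$area_km2[-.data$delta_z > th]),
                       .groups = "drop") |>
      dplyr::mutate(threshold = th, kind = "depth_m")
  }
  for (th in thresholds_pct) {
    rows[[length(rows) + 1]] <- per_lum |>
      dplyr::summarise(area_km2 = sum(.data$area_km2[-.data$pct_change > th]),
                       .groups = "drop") |>
      dplyr::mutate(threshold = th, kind = "percent")
  }
  dplyr::bind_rows(rows) |>
    dplyr::left_join(totals, by = "luminary") |>
    dplyr::mutate(pct_of_total = 100 * .data$area_km2 / .data$total) |>
    dplyr::select("luminary", "kind", "threshold", "area_km2",
                  "pct_of_total") |>
    dplyr::arrange(.data$luminary, .data$kind, .data$threshold)
}

#' Histogram of photic-depth change by area
#'
#' Bins the reduction in photic depth into left-open intervals
#' `(0, w], (w, 2w], ...` of width `bin_width` metres (default 10 m) and
#' sums pixel areas per bin; increases in depth are binned the same way
#' under `direction = "increase"`. Bin areas over both directions sum to
#' the total area with nonzero change.
#'
#' @param change A `photic_change` tibble.
#' @param bin_width Bin width in metres.
#' @param grid Optional [grid_spec()].
#' @param mode,spacing_m Area convention (see [pixel_area()]).
#' @return Tibble: `luminary`, `direction`, `bin_lo`, `bin_hi`,
#'   `area_km2`.
#' @export
delta_histogram <- function(change, bin_width = 10, grid = NULL,
                            mode = c("spherical", "mercator_grid"),
                            spacing_m = 9000) {
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- attr(change, "grid")
  dat <- .with_area(tibble::as_tibble(change), grid, mode, spacing_m) |>
    dplyr::filter(.data$delta_z != 0) |>
    dplyr::mutate(
      direction = dplyr::if_else(.data$delta_z < 0, "reduction", "increase"),
      mag = abs(.data$delta_z),
      bin = ceiling(.data$mag / bin_width)
    )
  if (nrow(dat) == 0) {
    return(tibble::tibble(luminary = character(), direction = character(),
                          bin_lo = numeric(), bin_hi = numeric(),
                          area_km2 = numeric()))
  }
  dat |>
    dplyr::group_by(.data$luminary, .data$direction, .data$bin) |>
    dplyr::summarise(area_km2 = sum(.data$area_km2), .groups = "drop") |>
    dplyr::mutate(bin_lo = (.data$bin - 1) * bin_width,
                  bin_hi = .data$bin * bin_width) |>
    dplyr::select("luminary", "direction", "bin_lo", "bin_hi", "area_km2") |>
    dplyr::arrange(.data$luminary, .data$direction, .data$bin_lo)
}
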