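# Plain-text raster interchange: long-format CSV with a JSON sidecar
# carrying the grid definition, year list and nodata sentinel, plus the
# Mercator point-grid resampler.

NODATA <- -999

#' Write a Kd stack to CSV with a JSON sidecar
#'
#' Writes the long-format pixel table to `<name>.csv` (missing values as
#' the nodata sentinel -999) and the grid definition, years and nodata
#' value to `<name>.json`. The round trip through [read_kd_stack()] is
#' lossless, including the missingness mask.
#'
#' @param stack A `kd_stack` tibble.
#' @param dir Output directory (created if needed).
#' @param name Basename for the file pair (default `"kd_stack"`).
#' @return The CSV path, invisibly.
#' @export
write_kd_stack <- function(stack, dir, name = "kd_stack") {
  grid <- attr(stack, "grid")
  years <- attr(stack, "years")
  if (is.null(grid) || is.null(years))
    stop("stack must carry grid and years attributes", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  out <- tibble::as_tibble(stack)
  out$kd[is.na(out$kd)] <- NODATA
  readr::write_csv(out, csv)
  jsonlite::write_json(
    list(grid = grid_as_list(attr(stack, "grid")), years = years,
         nodata = NODATA, crs = "EPSG:4326",
         registration = "cell-center", row1 = "northernmost"),
    file.path(dir, paste0(name, ".json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(csv)
}

#' Read a Kd stack written by [write_kd_stack()]
#'
#' @param path Path to the CSV file (the `.json` sidecar must sit next to
#'   it).
#' @return A `kd_stack` tibble with `grid` and `years` attributes; nodata
#'   values are mapped back to `NA`.
#' @export
read_kd_stack <- function(path) {
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(path) || !file.exists(sidecar))
    stop("missing stack file or sidecar: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- grid_from_list(meta$grid)
  dat <- readr::read_csv(path, show_col_types = FALSE)
  dat$kd[dat$kd == meta$nodata] <- NA_real_
  years <- sort(unique(dat$year))
  if (!identical(as.integer(years), as.integer(meta$years)))
    stop("years in ", path, " disagree with the sidecar", call. = FALSE)
  if (any(diff(years) != 1))
    stop("years must be consecutive in ", path, call. = FALSE)
  if (nrow(dat) != grid$n_pixels * length(years))
    stop("pixel count in ", path, " does not match the sidecar grid",
         call. = FALSE)
  if (any(dat$kd <= 0 | dat$kd > KD_MAX, na.rm = TRUE))
    stop("Kd values outside (0, 6.4] in ", path, call. = FALSE)
  new_kd_stack(dat, grid, years)
}

# World Mercator (spherical) forward/inverse, metres
.mercator_fwd <- function(lat, lon) {
  R <- EARTH_RADIUS_KM * 1000
  list(x = R * lon * DEG, y = R * log(tan(pi / 4 + lat * DEG / 2)))
}

.mercator_inv <- function(x, y) {
  R <- EARTH_RADIUS_KM * 1000
  list(lat = (2 * atan(exp(y / R)) - pi / 2) / DEG, lon = x / R / DEG)
}

#' Sample a Kd stack at arbitrary coordinates (nearest neighbour)
#'
#' @param stack A `kd_stack` tibble.
#' @param lat,lon Coordinate vectors of equal length, degrees.
#' @return Tibble: `point`, `lat`, `lon`, `year`, `kd` (`NA` outside the
#'   grid); the same point set for every year.
#' @export
sample_points <- function(stack, lat, lon) {
  grid <- attr(stack, "grid")
  if (is.null(grid)) stop("stack must carry a grid attribute", call. = FALSE)
  years <- attr(stack, "years")
  row <- floor((grid$lat_max - lat) / grid$cell_lat) + 1
  col <- floor((lon - grid$lon_min) / grid$cell_lon) + 1
  inside <- row >= 1 & row <= grid$n_rows & col >= 1 & col <= grid$n_cols
  pixel <- ifelse(inside, (row - 1) * grid$n_cols + col, NA_integer_)
  pts <- tibble::tibble(point = seq_along(lat), lat = lat, lon = lon,
                        pixel = as.integer(pixel))
  vals <- dplyr::select(tibble::as_tibble(stack), "pixel", "year", "kd")
  tidyr::crossing(pts, year = years) |>
    dplyr::left_join(vals, by = c("pixel", "year")) |>
    dplyr::select("point", "lat", "lon", "year", "kd") |>
    dplyr::arrange(.data$point, .data$year)
}

#' Resample a Kd stack onto a Mercator-spaced point grid
#'
#' Builds a point grid at a fixed spacing (default 9 km) in World Mercator
#' projected coordinates over the stack's bounding box, reprojects the
#' points to geographic coordinates, and samples every year of the stack at
#' those points by nearest neighbour. The point set is identical across
#' years; points falling outside the raster are missing.
#'
#' @param stack A `kd_stack` tibble.
#' @param spacing_m Point spacing in projected metres (default 9000).
#' @return Tibble: `point`, `x_m`, `y_m` (projected), `lat`, `lon`,
#'   `year`, `kd`.
#' @export
resample_to_point_grid <- function(stack, spacing_m = 9000) {
  grid <- attr(stack, "grid")
  if (is.null(grid)) stop("stack must carry a grid attribute", call. = FALSE)
  ll <- .mercator_fwd(c(grid$lat_min, grid$lat_max),
                      c(grid$lon_min, grid$lon_max))
  xs <- seq(ll$x[1] + spacing_m / 2, ll$x[2], by = spacing_m)
  ys <- seq(ll$y[1] + spacing_m / 2, ll$y[2], by = spacing_m)
  pts_xy <- expand.grid(x_m = xs, y_m = ys)
  geo <- .mercator_inv(pts_xy$x_m, pts_xy$y_m)
  sampled <- sample_points(stack, geo$lat, geo$lon)
  dplyr::left_join(
    tibble::tibble(point = seq_len(nrow(pts_xy)), x_m = pts_xy$x_m,
                   y_m = pts_xy$y_m),
    sampled, by = "point"
  )
}

# classification <-> integer code used in exported tables
CLASS_CODES <- c(increasing = 1L, decreasing = -1L, no_change = 0L,
                 insufficient_data = -9L)

#' Encode trend classifications as integer codes
#'
#' Convention: 1 = increasing (map colour red), -1 = decreasing (blue),
#' 0 = no change (white), -9 = insufficient data.
#'
#' @param classification Character vector of classifications.
#' @return Integer vector.
#' @export
classification_code <- function(classification) {
  unname(CLASS_CODES[classification])
}
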