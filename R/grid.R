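#' Define a regular latitude/longitude grid
#'
#' All rasters handled by the package live on a regular, cell-centre
#' registered plate carree grid: row 1 is the northernmost row, column 1 the
#' westernmost column, and the coordinates attached to a pixel are the centre
#' of its cell.
#'
#' @param n_rows,n_cols Number of grid rows (latitude) and columns
#'   (longitude).
#' @param lat_min,lat_max Latitude bounds of the grid edges, degrees, within
#'   \[-90, 90\].
#' @param lon_min,lon_max Longitude bounds of the grid edges, degrees, within
#'   \[-180, 180\].
#' @return An object of class `oceandark_grid`: a list with the bounds, the
#'   cell sizes in degrees (`cell_lat`, `cell_lon`) and the pixel count.
#' @examples
#' grid_spec(16, 16, lat_min = 40, lat_max = 56, lon_min = -20, lon_max = -4)
#' @export
grid_spec <- function(n_rows, n_cols, lat_min = -90, lat_max = 90,
                      lon_min = -180, lon_max = 180) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (lat_min >= lat_max || lat_min < -90 || lat_max > 90)
    stop("latitude bounds must satisfy -90 <= lat_min < lat_max <= 90", call. = FALSE)
  if (lon_min >= lon_max || lon_min < -180 || lon_max > 180)
    stop("longitude bounds must satisfy -180 <= lon_min < lon_max <= 180", call. = FALSE)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      lat_min = lat_min, lat_max = lat_max,
      lon_min = lon_min, lon_max = lon_max,
      cell_lat = (lat_max - lat_min) / n_rows,
      cell_lon = (lon_max - lon_min) / n_cols,
      n_pixels = as.integer(n_rows) * as.integer(n_cols)
    ),
    class = "oceandark_grid"
  )
}

#' @export
print.oceandark_grid <- function(x, ...) {
  cat(sprintf(
    "<oceandark_grid> %d x %d cells, lat [%g, %g], lon [%g, %g], cell %g x %g deg\n",
    x$n_rows, x$n_cols, x$lat_min, x$lat_max, x$lon_min, x$lon_max,
    x$cell_lat, x$cell_lon
  ))
  invisible(x)
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid An [grid_spec()] object.
#' @return A tibble with one row per pixel: `pixel` (row-major index), `row`,
#'   `col`, `lat`, `lon` (cell centres, degrees).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "oceandark_grid"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    pixel = seq_len(grid$n_pixels),
    row = row,
    col = col,
    lat = grid_row_lat(grid, row),
    lon = grid_col_lon(grid, col)
  )
}

# centre latitude of a row (row 1 = northernmost)
grid_row_lat <- function(grid, row) {
  grid$lat_max - (row - 0.5) * grid$cell_lat
}

grid_col_lon <- function(grid, col) {
  grid$lon_min + (col - 0.5) * grid$cell_lon
}

grid_as_list <- function(grid) unclass(grid)[c("n_rows", "n_cols", "lat_min",
                                               "lat_max", "lon_min", "lon_max")]

grid_from_list <- function(x) {
  grid_spec(x$n_rows, x$n_cols, x$lat_min, x$lat_max, x$lon_min, x$lon_max)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
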