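# Valid range of the MODIS Kd(490) product, m^-1
KD_MIN <- 0.01
KD_MAX <- 6.4

#' Simulate an annual series with a linear trend and AR(1) noise
#'
#' Generates `mean + slope * t + e_t` for `t = 0, ..., n_years - 1`, where
#' `e_t` is a stationary AR(1) process with autoregressive coefficient `phi`
#' and innovation standard deviation `sigma` (so the marginal variance is
#' `sigma^2 / (1 - phi^2)`). The first noise value is drawn from the
#' stationary distribution, making the whole noise process stationary.
#'
#' @param n_years Length of the series (>= 3).
#' @param mean Level of the series at `t = 0`, m^-1.
#' @param slope Linear trend, m^-1 per year.
#' @param phi AR(1) coefficient, in `[0, 1)`.
#' @param sigma Innovation standard deviation, m^-1 (>= 0).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Numeric vector of length `n_years`.
#' @examples
#' ar1_series(20, mean = 0.1, slope = 0.002, phi = 0.5, sigma = 0.01, seed = 1)
#' @export
ar1_series <- function(n_years, mean = 0.1, slope = 0, phi = 0.5,
                       sigma = 0.01, seed = NULL) {
  if (n_years < 3) stop("n_years must be at least 3", call. = FALSE)
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1) for stationarity", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  t <- seq_len(n_years) - 1
  noise <- with_seed(seed, ar1_noise(n_years, phi, sigma))
  mean + slope * t + noise
}

# stationary AR(1) noise; vectorised over n draws of length n_years when
# n_series > 1 (returns a matrix n_years x n_series)
ar1_noise <- function(n_years, phi, sigma, n_series = 1) {
  if (sigma == 0) {
    out <- matrix(0, n_years, n_series)
  } else {
    innov <- matrix(stats::rnorm(n_years * n_series, 0, sigma), n_years, n_series)
    out <- innov
    out[1, ] <- innov[1, ] / sqrt(1 - phi^2)
    if (n_years > 1) for (i in 2:n_years) out[i, ] <- phi * out[i - 1, ] + innov[i, ]
  }
  if (n_series == 1) drop(out) else out
}

#' Simulate a stack of annual Kd(490) rasters with planted trends
#'
#' Builds one Kd(490) field per year on a regular grid. Each pixel follows a
#' linear trend plus stationary AR(1) noise (see [ar1_series()]), clamped to
#' the valid Kd(490) range (0.01, 6.4] m^-1. A fraction of pixel-years is
#' dropped to emulate satellite coverage gaps. The planted per-pixel slope
#' and its sign classification are attached as a truth table so parameter
#' recovery can be measured downstream.
#'
#' @param grid A [grid_spec()].
#' @param years Integer vector of consecutive years (default 2003:2022).
#' @param baseline Baseline Kd(490) at the first year, m^-1: a scalar or an
#'   `n_rows x n_cols` matrix.
#' @param slope Trend, m^-1 per year: scalar or `n_rows x n_cols` matrix.
#' @param phi,sigma AR(1) noise parameters (see [ar1_series()]).
#' @param dropout Independent per-pixel-per-year probability of a missing
#'   value (default 0.05).
#' @param dropout_mode `"random"` (independent dropout everywhere) or
#'   `"polar"` (dropout rate tripled poleward of 66.5 degrees, emulating
#'   polar-night data loss; capped at 1).
#' @param seed Integer seed governing all randomness.
#' @return A tibble of class `kd_stack` with columns `pixel`, `row`, `col`,
#'   `lat`, `lon`, `year`, `kd` (NA when missing), carrying attributes
#'   `grid`, `years` and `truth` (tibble: `pixel`, `true_slope`,
#'   `true_class`).
#' @examples
#' g <- grid_spec(8, 8, 40, 48, -20, -12)
#' stk <- simulate_kd_stack(g, years = 2003:2022, baseline = 0.1,
#'                          slope = 0.002, sigma = 0.005, seed = 42)
#' @export
simulate_kd_stack <- function(grid, years = 2003:2022, baseline = 0.1,
                              slope = 0, phi = 0.5, sigma = 0.01,
                              dropout = 0.05, dropout_mode = c("random", "polar"),
                              seed = NULL) {
  stopifnot(inherits(grid, "oceandark_grid"))
  dropout_mode <- match.arg(dropout_mode)
  n_years <- length(years)
  if (n_years < 3) stop("need at least 3 years", call. = FALSE)
  if (any(diff(years) != 1)) stop("years must be consecutive", call. = FALSE)
  np <- grid$n_pixels
  baseline <- expand_field(baseline, grid, "baseline")
  slope <- expand_field(slope, grid, "slope")
  if (any(baseline <= KD_MIN | baseline > KD_MAX))
    stop("baseline Kd must lie in (0.01, 6.4] m^-1", call. = FALSE)

  pts <- grid_points(grid)
  tgrid <- outer(0:(n_years - 1), rep(1, np))            # n_years x np
  expected <- matrix(baseline, n_years, np, byrow = TRUE) +
    tgrid * matrix(slope, n_years, np, byrow = TRUE)
  vals <- with_seed(seed, {
    noise <- ar1_noise(n_years, phi, sigma, n_series = np)
    v <- expected + noise
    p_drop <- rep(dropout, np)
    if (dropout_mode == "polar")
      p_drop <- pmin(1, ifelse(abs(pts$lat) > 66.5, 3 * dropout, dropout))
    miss <- matrix(stats::runif(n_years * np), n_years, np) <
      matrix(p_drop, n_years, np, byrow = TRUE)
    v[miss] <- NA_real_
    v
  })
  vals <- pmin(pmax(vals, KD_MIN), KD_MAX)

  out <- tidyr::crossing(pts, year = years) |>
    dplyr::arrange(.data$pixel, .data$year)
  # vals is n_years x np; column-major flattening yields pixel-major order
  # (pixel 1 all years, then pixel 2, ...), matching the arranged table
  out$kd <- as.vector(vals)
  truth <- tibble::tibble(
    pixel = pts$pixel,
    true_slope = slope,
    true_class = dplyr::case_when(
      slope > 0 ~ "increasing",
      slope < 0 ~ "decreasing",
      TRUE ~ "no_change"
    )
  )
  new_kd_stack(out, grid, years, truth)
}

new_kd_stack <- function(data, grid, years, truth = NULL) {
  out <- tibble::new_tibble(data, class = "kd_stack")
  attr(out, "grid") <- grid
  attr(out, "years") <- as.integer(years)
  attr(out, "truth") <- truth
  out
}

expand_field <- function(x, grid, what) {
  if (length(x) == 1) return(rep(as.numeric(x), grid$n_pixels))
  if (is.matrix(x)) {
    if (nrow(x) != grid$n_rows || ncol(x) != grid$n_cols)
      stop(sprintf("%s matrix must be %d x %d", what, grid$n_rows, grid$n_cols),
           call. = FALSE)
    # row-major pixel order: row 1 across columns first
    return(as.numeric(t(x)))
  }
  if (length(x) == grid$n_pixels) return(as.numeric(x))
  stop(sprintf("%s must be a scalar, a full matrix, or a per-pixel vector", what),
       call. = FALSE)
}

#' Simulate a smooth shelf-and-abyss bathymetry field
#'
#' Depth (positive down, metres) ramps smoothly from `shelf_depth` in a
#' coastal band along the grid edge to `abyss_depth` in the interior, with a
#' gentle random large-scale undulation. All ocean pixels have depth > 0.
#'
#' @param grid A [grid_spec()].
#' @param shelf_depth,abyss_depth Shelf and abyssal depths in metres,
#'   `0 < shelf_depth < abyss_depth`.
#' @param shelf_width Width of the shelf-to-abyss ramp, in cells (default
#'   one quarter of the smaller grid dimension).
#' @param seed Integer seed.
#' @return Tibble: `pixel`, `row`, `col`, `lat`, `lon`, `depth` (m).
#' @export
simulate_bathymetry <- function(grid, shelf_depth = 50, abyss_depth = 4000,
                                shelf_width = NULL, seed = NULL) {
  stopifnot(inherits(grid, "oceandark_grid"))
  if (shelf_depth <= 0 || shelf_depth >= abyss_depth)
    stop("require 0 < shelf_depth < abyss_depth", call. = FALSE)
  if (is.null(shelf_width)) shelf_width <- max(2, min(grid$n_rows, grid$n_cols) / 4)
  pts <- grid_points(grid)
  # distance (in cells) from the nearest grid edge: the "coast"
  d_edge <- pmin(pts$row - 0.5, grid$n_rows - pts$row + 0.5,
                 pts$col - 0.5, grid$n_cols - pts$col + 0.5)
  ramp <- pmin(1, d_edge / shelf_width)^2 * (3 - 2 * pmin(1, d_edge / shelf_width))
  base <- shelf_depth + (abyss_depth - shelf_depth) * ramp
  # smooth undulation: a few low-frequency sinusoids, +/-5% of local depth
  wob <- with_seed(seed, {
    k <- 3
    a <- stats::runif(k, 0, 1); ph <- stats::runif(2 * k, 0, 2 * pi)
    fr <- stats::runif(2 * k, 0.5, 1.5)
    w <- rep(0, nrow(pts))
    for (i in seq_len(k)) {
      w <- w + a[i] * sin(2 * pi * fr[i] * pts$row / grid$n_rows + ph[i]) *
        sin(2 * pi * fr[k + i] * pts$col / grid$n_cols + ph[k + i])
    }
    w / max(1e-12, max(abs(w)))
  })
  depth <- pmin(abyss_depth, pmax(shelf_depth * 0.95, base * (1 + 0.05 * wob)))
  dplyr::mutate(pts, depth = depth)
}

#' Partition a grid into contiguous labelled regions
#'
#' Assigns every pixel to the nearest of `n_regions` randomly placed seed
#' points (a Voronoi tessellation in grid coordinates), which guarantees
#' contiguous, convex-ish regions that exactly partition the grid. Stands in
#' for named sea-region polygons in the synthetic pipeline.
#'
#' @param grid A [grid_spec()].
#' @param n_regions Number of regions, between 1 and the pixel count.
#' @param seed Integer seed.
#' @return Tibble: `pixel`, `row`, `col`, `lat`, `lon`, `region_id` (int),
#'   `region` (label).
#' @export
simulate_regions <- function(grid, n_regions = 4, seed = NULL) {
  stopifnot(inherits(grid, "oceandark_grid"))
  if (n_regions < 1 || n_regions > grid$n_pixels)
    stop("n_regions must be between 1 and the number of pixels", call. = FALSE)
  pts <- grid_points(grid)
  centers <- with_seed(seed, {
    data.frame(r = stats::runif(n_regions, 0.5, grid$n_rows + 0.5),
               c = stats::runif(n_regions, 0.5, grid$n_cols + 0.5))
  })
  d2 <- outer(pts$row, centers$r, "-")^2 + outer(pts$col, centers$c, "-")^2
  id <- max.col(-d2, ties.method = "first")
  dplyr::mutate(pts, region_id = as.integer(id),
                region = sprintf("Region %02d", id))
}
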