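test_that("pixel areas match spherical geometry and the Mercator convention", {
  # 1 x 1 degree cell on the equator
  expect_equal(pixel_area(0, cell_lat = 1, cell_lon = 1), 12364, tolerance = 1e-3)
  # whole 1-degree globe sums to the sphere's surface
  lats <- seq(-89.5, 89.5, by = 1)
  total <- sum(pixel_area(lats, 1, 1)) * 360
  expect_equal(total, 4 * pi * 6371.0088^2, tolerance = 1e-3)
  # Mercator-spaced 9 km point at 60 degrees: (9 * cos 60)^2
  expect_equal(pixel_area(60, spacing_m = 9000, mode = "mercator_grid"), 20.25,
               tolerance = 1e-9)
  # the two conventions agree at low latitude for matched grids: a Mercator
  # point grid at spacing s has ground spacing s (lon) and s cos(lat) (lat),
  # so the matching spherical cell is s/R wide and s cos(lat)/R tall
  for (lat in c(0, 10, 14)) {
    s <- 9000
    dlon <- s / 6371008.8 * 180 / pi
    sph <- pixel_area(lat, cell_lat = dlon * cos(lat * pi / 180),
                      cell_lon = dlon)
    mer <- pixel_area(lat, spacing_m = s, mode = "mercator_grid")
    expect_equal(sph, mer, tolerance = 0.01)
  }
})

test_that("region summaries rank by increasing fraction and conserve area", {
  g <- small_grid(8)
  pts <- grid_points(g)
  # construct a trend table directly: left half increasing, right half not
  trends <- dplyr::mutate(
    pts,
    classification = ifelse(col <= 4, "increasing", "no_change"),
    slope = ifelse(col <= 4, 0.002, 0))
  attr(trends, "grid") <- g
  regions <- dplyr::mutate(
    pts, region_id = ifelse(col <= 4, 1L, 2L),
    region = ifelse(col <= 4, "West", "East"))
  rs <- region_summary(trends, regions)
  expect_equal(rs$pct_increasing[rs$region == "West"], 100)
  expect_equal(rs$pct_increasing[rs$region == "East"], 0)
  expect_equal(rs$region[rs$rank == 1], "West")
  # partition conserves area
  all_area <- sum(pixel_area(pts$lat, g$cell_lat, g$cell_lon))
  expect_equal(sum(rs$total_area), all_area, tolerance = 1e-12)
  expect_equal(rs$total_area,
               rs$area_increasing + rs$area_decreasing + rs$area_no_change +
                 rs$area_insufficient, tolerance = 1e-12)
})

test_that("insufficient pixels leave the percentage denominator", {
  g <- small_grid(4)
  pts <- grid_points(g)
  trends <- dplyr::mutate(
    pts, classification = rep(c("increasing", "insufficient_data"), 8))
  attr(trends, "grid") <- g
  regions <- dplyr::mutate(pts, region_id = 1L, region = "All")
  rs <- region_summary(trends, regions)
  expect_equal(rs$pct_increasing, 100)
  expect_gt(rs$area_insufficient, 0)
})

test_that("threshold areas use strict comparisons and nest", {
  ch <- tibble::tibble(
    pixel = 1:3, lat = 0, lon = 1:3, luminary = "sun",
    z_start = 300, z_end = 300 + c(-5, -15, -55),
    delta_z = c(-5, -15, -55), pct_change = 100 * c(-5, -15, -55) / 300,
    clipped_frac = 0, zero_start = FALSE)
  g <- grid_spec(1, 3, -0.5, 0.5, 0, 3)
  ta <- threshold_areas(ch, g, thresholds_m = c(10, 50, 100))
  a <- pixel_area(0, g$cell_lat, g$cell_lon)
  got <- ta$area_km2[ta$kind == "depth_m"]
  expect_equal(got, c(2 * a, a, 0), tolerance = 1e-12)
  # nesting holds for any field
  expect_true(all(diff(got) <= 0))
  # all-zero change: all areas zero
  ch0 <- dplyr::mutate(ch, delta_z = 0, pct_change = 0)
  expect_true(all(threshold_areas(ch0, g)$area_km2 == 0))
})

test_that("the change histogram bins left-open and conserves area", {
  g <- grid_spec(1, 3, -0.5, 0.5, 0, 3)
  a <- pixel_area(0, g$cell_lat, g$cell_lon)
  ch <- tibble::tibble(
    pixel = 1:3, lat = 0, lon = 1:3, luminary = "sun",
    z_start = 300, z_end = 300 + c(-15, 8, 0),
    delta_z = c(-15, 8, 0), pct_change = 0, clipped_frac = 0,
    zero_start = FALSE)
  h <- delta_histogram(ch, bin_width = 10, grid = g)
  red <- h[h$direction == "reduction", ]
  expect_equal(red$bin_lo, 10)
  expect_equal(red$bin_hi, 20)
  expect_equal(red$area_km2, a, tolerance = 1e-12)
  inc <- h[h$direction == "increase", ]
  expect_equal(inc$bin_lo, 0)
  # conservation: histogram total equals the area with nonzero change,
  # and the reduction side equals the area beyond a zero threshold
  expect_equal(sum(h$area_km2), 2 * a, tolerance = 1e-12)
  t0 <- threshold_areas(ch, g, thresholds_m = 0, thresholds_pct = numeric(0))
  expect_equal(sum(red$area_km2), t0$area_km2[t0$kind == "depth_m"],
               tolerance = 1e-12)
  # empty input: empty histogram
  expect_equal(nrow(delta_histogram(dplyr::mutate(ch, delta_z = 0), grid = g)),
               0)
})
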