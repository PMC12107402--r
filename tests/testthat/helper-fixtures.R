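# Small grids and scenario builders shared across the suite. All fixtures
# are generated in code; nothing is read from disk except packaged tables.

small_grid <- function(n = 8, lat0 = 40, lon0 = -40) {
  grid_spec(n, n, lat0, lat0 + n, lon0, lon0 + n)
}

# a 12-month irradiance field with constant band irradiance, for tests that
# need the photic machinery without the atmosphere/ephemeris stack
flat_irradiance <- function(latitudes, i0_sun = 0.5, i0_moon = 2e-5) {
  tidyr::crossing(latitude = latitudes, month = 1:12) |>
    dplyr::mutate(sun_band = i0_sun, moon_band = i0_moon,
                  sun_zenith = 0, moon_zenith = 0, phase_angle = 5)
}

# deep-water bathymetry table for a set of pixels
flat_bathymetry <- function(pixels, depth = 6000) {
  tibble::tibble(pixel = pixels, depth = depth)
}

# brute-force L1 objective for checking the median regression line
l1_objective <- function(par, x, y) sum(abs(y - par[1] - par[2] * x))
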