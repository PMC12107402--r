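# Spectral solar and lunar irradiance just above the sea surface, 1 nm
# resolution over 350-700 nm, band-integrated 485-495 nm downstream.

.spectra_cache <- new.env(parent = emptyenv())

load_spectral_table <- function(file) {
  if (!is.null(.spectra_cache[[file]])) return(.spectra_cache[[file]])
  path <- system.file("extdata", file, package = "oceandark")
  if (path == "") stop("packaged table not found: ", file, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#")
  .spectra_cache[[file]] <- tab
  tab
}

# interpolate a packaged table column to the 1 nm working grid
.interp_spectrum <- function(file, column, wavelengths = 350:700) {
  tab <- load_spectral_table(file)
  stats::approx(tab$wavelength_nm, tab[[column]], xout = wavelengths,
                rule = 2)$y
}

#' Packaged top-of-atmosphere solar spectrum
#'
#' @param wavelengths Wavelength grid in nm (default 350:700 at 1 nm).
#' @return Numeric vector of spectral irradiance, W m^-2 nm^-1.
#' @export
solar_spectrum <- function(wavelengths = 350:700) {
  .interp_spectrum("solar_spectrum.csv", "irradiance", wavelengths)
}

#' Packaged spectral lunar albedo
#'
#' @param wavelengths Wavelength grid in nm.
#' @return Unitless albedo per wavelength.
#' @export
lunar_albedo <- function(wavelengths = 350:700) {
  .interp_spectrum("lunar_albedo.csv", "albedo", wavelengths)
}

new_spectral_irradiance <- function(wavelengths, direct, diffuse) {
  tibble::new_tibble(
    tibble::tibble(wavelength = wavelengths, direct = direct,
                   diffuse = diffuse),
    class = "spectral_irradiance"
  )
}

#' Top-of-atmosphere solar spectral irradiance for a day of year
#'
#' Scales the packaged solar spectrum by the Earth-orbit eccentricity
#' factor `(1 + e * cos(2 * pi * (D - 3) / 365))^2`, which peaks at
#' perihelion (D = 3) and equals 1 where the cosine vanishes.
#'
#' @param day_of_year Day of year D, 1-366.
#' @param eccentricity Orbital eccentricity (default 0.0167).
#' @param wavelengths Wavelength grid, nm.
#' @return A `spectral_irradiance` tibble (`wavelength`, `direct`,
#'   `diffuse`); at the top of the atmosphere the diffuse component is zero.
#' @examples
#' toa_solar(172)
#' @export
toa_solar <- function(day_of_year, eccentricity = 0.0167,
                      wavelengths = 350:700) {
  if (day_of_year < 1 || day_of_year > 366)
    stop("day_of_year must be in 1..366", call. = FALSE)
  if (eccentricity < 0 || eccentricity >= 0.1)
    stop("eccentricity must be in [0, 0.1)", call. = FALSE)
  fac <- eccentricity_factor(day_of_year, eccentricity)
  new_spectral_irradiance(wavelengths, solar_spectrum(wavelengths) * fac,
                          rep(0, length(wavelengths)))
}

#' Earth-orbit eccentricity correction factor
#'
#' @inheritParams toa_solar
#' @return `(1 + e cos(2 pi (D - 3) / 365))^2`, unitless.
#' @export
eccentricity_factor <- function(day_of_year, eccentricity = 0.0167) {
  (1 + eccentricity * cos(2 * pi * (day_of_year - 3) / 365))^2
}

#' Clear-sky marine atmosphere parameters
#'
#' Canonical clear-sky marine defaults; all overridable. Units: pressure
#' hPa, precipitable water vapour cm, ozone Dobson units, relative humidity
#' percent, wind speed m s^-1, visibility km.
#'
#' @param pressure,water_vapor,ozone_du,rh,wind,visibility,air_mass_type
#'   Atmosphere settings.
#' @param angstrom_alpha Angstrom wavelength exponent of the marine aerosol.
#' @param aerosol_ssa Aerosol single-scattering albedo.
#' @param aerosol_asymmetry Aerosol asymmetry parameter.
#' @return List of class `marine_atmosphere`.
#' @export
marine_atmosphere <- function(pressure = 1013.25, water_vapor = 2.5,
                              ozone_du = 350, rh = 80, wind = 5,
                              visibility = 23, air_mass_type = "marine",
                              angstrom_alpha = 0.5, aerosol_ssa = 0.985,
                              aerosol_asymmetry = 0.75) {
  if (pressure <= 0 || water_vapor < 0 || ozone_du <= 0 || visibility <= 0 ||
      wind < 0 || rh < 0 || rh > 100)
    stop("unphysical atmosphere parameters", call. = FALSE)
  structure(
    list(pressure = pressure, water_vapor = water_vapor, ozone_du = ozone_du,
         rh = rh, wind = wind, visibility = visibility,
         air_mass_type = air_mass_type, angstrom_alpha = angstrom_alpha,
         aerosol_ssa = aerosol_ssa, aerosol_asymmetry = aerosol_asymmetry),
    class = "marine_atmosphere"
  )
}

#' Above-surface spectral irradiance through a clear marine atmosphere
#'
#' Propagates a top-of-atmosphere spectrum to just above the sea surface
#' (0+) with the classical clear-sky decomposition: Rayleigh, aerosol,
#' ozone, oxygen and water-vapour transmittances for the direct beam, and
#' single-scattering Rayleigh and aerosol terms for the diffuse sky
#' component. Aerosol turbidity follows the marine visibility
#' parameterisation; air masses use the Kasten-Young formula.
#'
#' @param toa A `spectral_irradiance` tibble of TOA irradiance (see
#'   [toa_solar()] or [lunar_toa()]).
#' @param zenith Zenith angle of the luminary, degrees; 90 or more returns
#'   an all-zero spectrum.
#' @param atmosphere A [marine_atmosphere()].
#' @return A `spectral_irradiance` tibble with `direct` and `diffuse`
#'   components, W m^-2 nm^-1.
#' @export
surface_irradiance <- function(toa, zenith, atmosphere = marine_atmosphere()) {
  stopifnot(inherits(atmosphere, "marine_atmosphere"))
  wl <- toa$wavelength
  toa_total <- toa$direct + toa$diffuse
  if (zenith >= 90)
    return(new_spectral_irradiance(wl, rep(0, length(wl)), rep(0, length(wl))))
  mu <- cos(zenith * DEG)
  # Kasten-Young relative air mass, pressure-corrected for scattering paths
  M <- 1 / (mu + 0.50572 * (96.07995 - zenith)^-1.6364)
  Mp <- M * atmosphere$pressure / 1013.25
  Moz <- 1.0035 / sqrt(mu^2 + 0.007)
  lam_um <- wl / 1000
  tau_r <- 1 / (115.6406 * lam_um^4 - 1.335 * lam_um^2)
  Tr <- exp(-Mp * tau_r)
  a_oz <- .interp_spectrum("gas_absorption.csv", "a_ozone", wl)
  a_o2 <- .interp_spectrum("gas_absorption.csv", "a_oxygen", wl)
  a_w <- .interp_spectrum("gas_absorption.csv", "a_water", wl)
  Toz <- exp(-a_oz * (atmosphere$ozone_du / 1000) * Moz)
  To2 <- exp(-1.41 * a_o2 * Mp / (1 + 118.3 * a_o2 * Mp)^0.45)
  Tw <- exp(-0.2385 * a_w * atmosphere$water_vapor * M /
              (1 + 20.07 * a_w * atmosphere$water_vapor * M)^0.45)
  # marine aerosol optical depth at 550 nm from visibility (Koschmieder,
  # minus the molecular contribution), Angstrom spectral slope
  tau_a550 <- max(0, 3.912 / atmosphere$visibility - 0.0973)
  tau_a <- tau_a550 * (lam_um / 0.55)^(-atmosphere$angstrom_alpha)
  Ta <- exp(-tau_a * M)
  wa <- atmosphere$aerosol_ssa
  Taa <- exp(-(1 - wa) * tau_a * M)
  Tas <- exp(-wa * tau_a * M)
  g <- atmosphere$aerosol_asymmetry
  alg <- log(1 - g)
  afs <- alg * (1.459 + alg * (0.1595 + 0.4129 * alg))
  bfs <- alg * (0.0783 + alg * (-0.3824 - 0.5874 * alg))
  Fs <- 1 - 0.5 * exp((afs + bfs * mu) * mu)
  direct <- toa_total * mu * Tr * Ta * Toz * To2 * Tw
  diff_r <- toa_total * mu * Toz * To2 * Tw * Taa * 0.5 * (1 - Tr^0.95)
  diff_a <- toa_total * mu * Toz * To2 * Tw * Taa * Tr^1.5 * (1 - Tas) * Fs
  new_spectral_irradiance(wl, direct, diff_r + diff_a)
}

#' Phase-curve brightening factor for the full moon
#'
#' Two-component phase function in the H,G standardisation of the
#' Lumme-Bowell photometric theory:
#' `phi(alpha) = (1 - G) exp(-3.33 tan(a/2)^0.63) + G exp(-1.87 tan(a/2)^1.22)`,
#' normalised so `phi(0) = 1` (opposition). Monotonically non-increasing.
#'
#' @param phase_angle Sun-Moon-observer angle, degrees, in `[0, 180]`.
#' @param slope_parameter Photometric slope parameter G (default 0.15).
#' @return Unitless factor in `[0, 1]`.
#' @export
phase_curve <- function(phase_angle, slope_parameter = 0.15) {
  if (any(phase_angle < 0 | phase_angle > 180))
    stop("phase_angle must be in [0, 180]", call. = FALSE)
  ta <- tan(pmin(phase_angle, 179.99) * DEG / 2)
  G <- slope_parameter
  (1 - G) * exp(-3.33 * ta^0.63) + G * exp(-1.87 * ta^1.22)
}

#' Top-of-atmosphere lunar spectral irradiance
#'
#' Lambertian-disk composition of the named ingredients: the solar TOA
#' spectrum, the spectral lunar albedo, the phase-curve factor and the
#' solid angle of the lunar disk,
#' `E_moon(lambda) = E_sun(lambda) * A(lambda) * f(alpha) * theta_s^2`
#' with `theta_s` the semi-diameter in radians (disk radiance
#' `L = A E_sun / pi` over solid angle `pi theta_s^2`).
#'
#' @param toa_sun Solar TOA `spectral_irradiance` (see [toa_solar()]).
#' @param phase_angle Lunar phase angle, degrees.
#' @param albedo Spectral albedo on the same wavelength grid (default the
#'   packaged table), or a scalar.
#' @param semi_diameter Lunar semi-diameter view angle, degrees
#'   (default 0.26, the mean value).
#' @param slope_parameter Phase-curve G (see [phase_curve()]).
#' @return A `spectral_irradiance` tibble (all direct, diffuse zero).
#' @export
lunar_toa <- function(toa_sun, phase_angle, albedo = NULL,
                      semi_diameter = 0.26, slope_parameter = 0.15) {
  if (semi_diameter <= 0) stop("semi_diameter must be positive", call. = FALSE)
  wl <- toa_sun$wavelength
  if (is.null(albedo)) albedo <- lunar_albedo(wl)
  if (any(albedo < 0 | albedo >= 1))
    stop("albedo must lie in [0, 1)", call. = FALSE)
  theta <- semi_diameter * DEG
  f <- phase_curve(phase_angle, slope_parameter)
  e <- (toa_sun$direct + toa_sun$diffuse) * albedo * f * theta^2
  new_spectral_irradiance(wl, e, rep(0, length(wl)))
}

#' Band-integrated irradiance
#'
#' Trapezoidal integral of the global (direct + diffuse) spectral
#' irradiance over `[lo, hi]` nm.
#'
#' @param spectrum A `spectral_irradiance` tibble.
#' @param lo,hi Band edges in nm (default 485-495, the Kd(490) band).
#' @return Irradiance in W m^-2.
#' @export
band_integrate <- function(spectrum, lo = 485, hi = 495) {
  wl <- spectrum$wavelength
  if (lo < min(wl) || hi > max(wl) || lo >= hi)
    stop("band [lo, hi] must lie within the spectrum support", call. = FALSE)
  keep <- wl >= lo & wl <= hi
  w <- wl[keep]
  v <- spectrum$direct[keep] + spectrum$diffuse[keep]
  # include fractional end-cells if band edges fall between grid points
  if (!(lo %in% w)) {
    v <- c(stats::approx(wl, spectrum$direct + spectrum$diffuse, lo)$y, v)
    w <- c(lo, w)
  }
  if (!(hi %in% w)) {
    v <- c(v, stats::approx(wl, spectrum$direct + spectrum$diffuse, hi)$y)
    w <- c(w, hi)
  }
  sum(diff(w) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Monthly sun and full-moon band irradiance per latitude
#'
#' For each latitude and calendar month computes the 485-495 nm
#' band-integrated irradiance just above the sea surface for (a) the sun at
#' solar noon on the 15th of the month and (b) the full moon at its
#' culmination in that month, both through the clear-sky marine atmosphere.
#' A luminary below the horizon contributes exactly zero. Lunar geometry is
#' evaluated at the reference longitude (default 0): the culmination
#' instant is the lunar transit there, and each latitude sees the moon at
#' its own zenith angle at that instant.
#'
#' @param latitudes Numeric vector of latitudes, degrees.
#' @param year Calendar year whose geometry is used (default 2022).
#' @param atmosphere A [marine_atmosphere()].
#' @param eccentricity Orbital eccentricity for [toa_solar()].
#' @param semi_diameter,slope_parameter Lunar disk and phase settings.
#' @param longitude Reference longitude for the lunar path (default 0).
#' @return A tibble of class `irradiance_field`: `latitude`, `month`,
#'   `sun_band`, `moon_band` (W m^-2), `sun_zenith`, `moon_zenith`,
#'   `phase_angle` (deg).
#' @examples
#' \donttest{
#' surface_irradiance_field(seq(-60, 60, by = 30))
#' }
#' @export
surface_irradiance_field <- function(latitudes, year = 2022,
                                     atmosphere = marine_atmosphere(),
                                     eccentricity = 0.0167,
                                     semi_diameter = 0.26,
                                     slope_parameter = 0.15,
                                     longitude = 0) {
  months <- 1:12
  month_day15 <- function(m) {
    as.integer(strftime(as.Date(sprintf("%d-%02d-15", year, m)), "%j"))
  }
  rows <- purrr::map(months, function(m) {
    doy <- month_day15(m)
    toa <- toa_solar(doy, eccentricity)
    cul <- monthly_culmination(0, longitude, m, year)
    doy_fm <- as.integer(strftime(as.Date(cul$culmination, tz = "UTC"), "%j"))
    toa_fm <- toa_solar(doy_fm, eccentricity)
    alpha <- cul$phase_angle
    moon_toa <- lunar_toa(toa_fm, alpha, semi_diameter = semi_diameter,
                          slope_parameter = slope_parameter)
    sun_z <- solar_noon_zenith(latitudes, doy, year)
    lat_rows <- purrr::map(seq_along(latitudes), function(i) {
      sb <- if (sun_z[i] >= 90) 0 else
        band_integrate(surface_irradiance(toa, sun_z[i], atmosphere))
      mz <- moon_altaz(latitudes[i], longitude, cul$culmination)$zenith
      mb <- if (mz >= 90) 0 else
        band_integrate(surface_irradiance(moon_toa, mz, atmosphere))
      tibble::tibble(latitude = latitudes[i], month = m, sun_band = sb,
                     moon_band = mb, sun_zenith = sun_z[i], moon_zenith = mz,
                     phase_angle = alpha)
    })
    dplyr::bind_rows(lat_rows)
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "irradiance_field")
}
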