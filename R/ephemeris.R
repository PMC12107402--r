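# Low-precision solar and lunar ephemeris, built from the standard almanac
# truncated series. Accuracy: ~0.01 deg for the Sun, ~0.3 deg for the Moon's
# ecliptic position -- comfortably inside the package's 1 deg contract for
# lunar zenith and phase angles.

DEG <- pi / 180

#' Julian day number of a UTC instant
#'
#' @param time A `POSIXct` instant (UTC).
#' @return Julian day (numeric, continuous).
#' @export
julian_day <- function(time) {
  as.numeric(time, tz = "UTC") / 86400 + 2440587.5
}

# Julian centuries since J2000.0
.jcent <- function(jd) (jd - 2451545) / 36525

# wrap angle to [0, 360)
.wrap360 <- function(x) x %% 360

#' Geocentric solar position
#'
#' Standard low-precision solar ephemeris: mean longitude and anomaly plus
#' the equation of centre, converted to apparent ecliptic longitude, right
#' ascension and declination.
#'
#' @param jd Julian day.
#' @return List: `lon` (ecliptic longitude, deg), `ra`, `dec` (deg).
#' @export
sun_position <- function(jd) {
  n <- jd - 2451545
  L <- .wrap360(280.460 + 0.9856474 * n)
  g <- .wrap360(357.528 + 0.9856003 * n) * DEG
  lambda <- .wrap360(L + 1.915 * sin(g) + 0.020 * sin(2 * g))
  eps <- (23.439 - 0.0000004 * n) * DEG
  lam <- lambda * DEG
  ra <- atan2(cos(eps) * sin(lam), cos(lam)) / DEG
  dec <- asin(sin(eps) * sin(lam)) / DEG
  list(lon = lambda, ra = .wrap360(ra), dec = dec)
}

#' Geocentric lunar position
#'
#' Truncated lunar series (the almanac low-precision formulation): ecliptic
#' longitude and latitude to ~0.3 deg and horizontal parallax to ~0.005 deg.
#'
#' @param jd Julian day.
#' @return List: `lon`, `lat` (ecliptic, deg), `ra`, `dec` (deg),
#'   `parallax` (deg), `distance_er` (Earth radii).
#' @export
moon_position <- function(jd) {
  T_ <- .jcent(jd)
  s <- function(a, b) sin((a + b * T_) * DEG)
  cc <- function(a, b) cos((a + b * T_) * DEG)
  lon <- .wrap360(
    218.32 + 481267.881 * T_ +
      6.29 * s(135.0, 477198.87) - 1.27 * s(259.3, -413335.36) +
      0.66 * s(235.7, 890534.22) + 0.21 * s(269.9, 954397.74) -
      0.19 * s(357.5, 35999.05) - 0.11 * s(186.5, 966404.03)
  )
  lat <- 5.13 * s(93.3, 483202.02) + 0.28 * s(228.2, 960400.89) -
    0.28 * s(318.3, 6003.15) - 0.17 * s(217.6, -407332.21)
  par <- 0.9508 +
    0.0518 * cc(135.0, 477198.87) + 0.0095 * cc(259.3, -413335.36) +
    0.0078 * cc(235.7, 890534.22) + 0.0028 * cc(269.9, 954397.74)
  eps <- (23.439 - 0.0000004 * (jd - 2451545)) * DEG
  lam <- lon * DEG; bet <- lat * DEG
  sl <- sin(lam); cl <- cos(lam); sb <- sin(bet); cb <- cos(bet)
  ra <- atan2(sl * cb * cos(eps) - sb * sin(eps), cl * cb) / DEG
  dec <- asin(sb * cos(eps) + cb * sin(eps) * sl) / DEG
  list(lon = lon, lat = lat, ra = .wrap360(ra), dec = dec,
       parallax = par, distance_er = 1 / sin(par * DEG))
}

# Greenwich mean sidereal time, degrees
.gmst <- function(jd) .wrap360(280.46061837 + 360.98564736629 * (jd - 2451545))

#' Topocentric lunar altitude and azimuth
#'
#' @param latitude,longitude Observer coordinates, degrees (east positive).
#' @param time `POSIXct` UTC instant.
#' @return List: `altitude` (topocentric, parallax-corrected, deg),
#'   `azimuth` (deg from north), `zenith` (deg), `dec` (deg).
#' @export
moon_altaz <- function(latitude, longitude, time) {
  jd <- julian_day(time)
  m <- moon_position(jd)
  H <- (.gmst(jd) + longitude - m$ra) * DEG
  phi <- latitude * DEG; dec <- m$dec * DEG
  sina <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)
  alt <- asin(pmin(1, pmax(-1, sina))) / DEG
  az <- atan2(-cos(dec) * sin(H),
              sin(dec) * cos(phi) - cos(dec) * sin(phi) * cos(H)) / DEG
  alt_topo <- alt - m$parallax * cos(alt * DEG)   # geocentric -> topocentric
  list(altitude = alt_topo, azimuth = .wrap360(az), zenith = 90 - alt_topo,
       dec = m$dec)
}

#' Lunar phase angle (Sun-Moon-observer), degrees
#'
#' Computed from the geocentric elongation of the Moon from the Sun;
#' 0 deg = opposition surge (full moon), 180 deg = new moon.
#'
#' @param time `POSIXct` UTC instant.
#' @return Phase angle in degrees, in `[0, 180]`.
#' @export
moon_phase_angle <- function(time) {
  jd <- julian_day(time)
  m <- moon_position(jd)
  s <- sun_position(jd)
  cospsi <- cos(m$lat * DEG) * cos((m$lon - s$lon) * DEG)
  psi <- acos(pmin(1, pmax(-1, cospsi))) / DEG    # elongation
  180 - psi
}

#' Lunar observation geometry for a site and instant
#'
#' @param latitude,longitude Observer coordinates, degrees.
#' @param time `POSIXct` UTC instant.
#' @return List of class `lunar_geometry`: `zenith`, `altitude`,
#'   `phase_angle` (deg), `instant`.
#' @export
lunar_geometry <- function(latitude, longitude, time) {
  if (abs(latitude) > 90) stop("latitude out of range", call. = FALSE)
  aa <- moon_altaz(latitude, longitude, time)
  structure(
    list(zenith = aa$zenith, altitude = aa$altitude,
         phase_angle = moon_phase_angle(time), instant = time),
    class = "lunar_geometry"
  )
}

#' Full-moon instants of a calendar year
#'
#' Seeds each lunation from the mean synodic cycle and refines the instant
#' of minimum phase angle by golden-section search over +/- 1.5 days.
#'
#' @param year Calendar year.
#' @return Tibble: `instant` (POSIXct UTC), `phase_angle` (deg at minimum).
#' @export
full_moon_instants <- function(year) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:59:59", year), tz = "UTC")
  jd0 <- julian_day(t0); jd1 <- julian_day(t1)
  # mean full moons: new-moon epoch + (k + 0.5) synodic months
  k0 <- floor((jd0 - 2451550.09766) / 29.530588861) - 1
  k1 <- ceiling((jd1 - 2451550.09766) / 29.530588861) + 1
  cand <- 2451550.09766 + (seq(k0, k1) + 0.5) * 29.530588861
  refine <- function(jdc) {
    f <- function(jd) {
      tm <- as.POSIXct((jd - 2440587.5) * 86400, origin = "1970-01-01", tz = "UTC")
      moon_phase_angle(tm)
    }
    opt <- stats::optimize(f, c(jdc - 1.5, jdc + 1.5), tol = 1e-5)
    c(opt$minimum, opt$objective)
  }
  ref <- t(vapply(cand, refine, numeric(2)))
  keep <- ref[, 1] >= jd0 & ref[, 1] <= jd1
  ref <- ref[keep, , drop = FALSE]
  ref <- ref[!duplicated(round(ref[, 1], 1)), , drop = FALSE]
  tibble::tibble(
    instant = as.POSIXct((ref[, 1] - 2440587.5) * 86400,
                         origin = "1970-01-01", tz = "UTC"),
    phase_angle = ref[, 2]
  )
}

#' Full-moon culmination instant for one calendar month
#'
#' Finds the full moon of the month (minimum phase angle within the month;
#' when a month contains no full-moon minimum, the instant of minimum phase
#' angle within the month is used, which lies at a month boundary) and then
#' the instant of maximum lunar altitude at the site within half a lunar
#' transit period (13 h) of the full moon.
#'
#' @param latitude,longitude Site coordinates, degrees.
#' @param month Month 1-12.
#' @param year Calendar year.
#' @return List: `full_moon` (POSIXct), `culmination` (POSIXct),
#'   `altitude` (deg at culmination), `phase_angle` (deg at culmination).
#' @export
monthly_culmination <- function(latitude, longitude, month, year) {
  stopifnot(month %in% 1:12)
  fm_all <- full_moon_instants(year)
  mo <- as.integer(format(fm_all$instant, "%m", tz = "UTC"))
  if (any(mo == month)) {
    fm <- fm_all$instant[mo == month][which.min(fm_all$phase_angle[mo == month])]
  } else {
    # no full-moon minimum inside the month: take the month's best instant
    t0 <- as.POSIXct(sprintf("%d-%02d-01 00:00:00", year, month), tz = "UTC")
    t1 <- t0 + 86400 * (c(31, 28 + (year %% 4 == 0), 31, 30, 31, 30,
                          31, 31, 30, 31, 30, 31)[month])
    fm <- if (moon_phase_angle(t0) < moon_phase_angle(t1)) t0 else t1 - 1
  }
  # the transit nearest the full-moon instant: successive lunar transits are
  # ~24.8 h apart, so a +/- 13 h window always contains exactly one interior
  # altitude maximum
  altf <- function(h) moon_altaz(latitude, longitude, fm + h * 3600)$altitude
  hours <- seq(-13, 13, by = 1 / 3)
  alts <- vapply(hours, altf, numeric(1))
  hbest <- hours[which.max(alts)]
  opt <- stats::optimize(altf, c(hbest - 2 / 3, hbest + 2 / 3),
                         maximum = TRUE, tol = 1e-6)
  tcul <- fm + opt$maximum * 3600
  list(full_moon = fm, culmination = tcul, altitude = opt$objective,
       phase_angle = moon_phase_angle(tcul))
}

#' Solar declination, degrees
#'
#' @param day_of_year Day of year, 1-366.
#' @param year Calendar year used to anchor the date (default 2022).
#' @return Declination in degrees.
#' @export
solar_declination <- function(day_of_year, year = 2022) {
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("day_of_year must be in 1..366", call. = FALSE)
  t0 <- as.POSIXct(sprintf("%d-01-01 12:00:00", year), tz = "UTC")
  jd <- julian_day(t0) + (day_of_year - 1)
  vapply(jd, function(j) sun_position(j)$dec, numeric(1))
}

#' Solar zenith angle at local solar noon
#'
#' At solar noon the zenith angle is the absolute difference between the
#' site latitude and the solar declination. Values of 90 deg or more mean
#' the sun does not rise above the horizon at noon (polar night).
#'
#' @param latitude Degrees, in `[-90, 90]`.
#' @param day_of_year Day of year, 1-366.
#' @param year Calendar year (default 2022).
#' @return Zenith angle in degrees.
#' @export
solar_noon_zenith <- function(latitude, day_of_year, year = 2022) {
  if (any(abs(latitude) > 90)) stop("latitude out of range", call. = FALSE)
  abs(latitude - solar_declination(day_of_year, year))
}
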