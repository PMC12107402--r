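test_that("eccentricity factor hits its limiting values", {
  # cosine zero: D = 3 + 365/4
  expect_equal(eccentricity_factor(3 + 365 / 4, 0.0167), 1, tolerance = 1e-12)
  # perihelion (D = 3): annual maximum (1 + e)^2
  expect_equal(eccentricity_factor(3, 0.0167), 1.0167^2, tolerance = 1e-12)
  expect_equal(eccentricity_factor(3, 0.0167), 1.033679, tolerance = 1e-6)
  # aphelion half a year later: (1 - e)^2
  expect_equal(eccentricity_factor(3 + 365 / 2, 0.0167), (1 - 0.0167)^2,
               tolerance = 1e-12)
  fac <- eccentricity_factor(1:365)
  expect_true(all(fac >= (1 - 0.0167)^2 - 1e-12 & fac <= (1 + 0.0167)^2 + 1e-12))
  expect_error(toa_solar(0), "day_of_year")
})

test_that("solar noon zenith follows latitude minus declination", {
  # equator at the March equinox
  expect_lt(solar_noon_zenith(0, 79), 0.5)
  # 50 N at the June solstice: |50 - 23.44|
  expect_equal(solar_noon_zenith(50, 172), 26.56, tolerance = 0.5)
  # 80 N in December: polar night
  expect_gt(solar_noon_zenith(80, 355), 90)
})

test_that("the clear-sky model respects transmission physics", {
  toa <- toa_solar(172)
  # below the horizon: exactly zero
  dark <- surface_irradiance(toa, 90)
  expect_true(all(dark$direct == 0 & dark$diffuse == 0))
  # transmittance bound: direct never exceeds TOA * cos(zenith)
  for (z in c(0, 15, 40, 70, 85)) {
    surf <- surface_irradiance(toa, z)
    expect_true(all(surf$direct <= toa$direct * cos(z * pi / 180) + 1e-12))
    expect_true(all(surf$direct >= 0 & surf$diffuse >= 0))
  }
  # air-mass monotonicity of the band integral over zenith 0 -> 80
  bands <- vapply(seq(0, 80, by = 20),
                  function(z) band_integrate(surface_irradiance(toa, z)),
                  numeric(1))
  expect_true(all(diff(bands) < 0))
  expect_error(marine_atmosphere(pressure = -1), "unphysical")
})

test_that("band integration is a trapezoidal integral with additivity", {
  wl <- 480:500
  flat <- oceandark:::new_spectral_irradiance(wl, rep(1, 21), rep(0, 21))
  expect_equal(band_integrate(flat, 485, 495), 10)
  tri <- oceandark:::new_spectral_irradiance(
    wl, pmax(0, (wl - 485) / 10), rep(0, 21))
  expect_equal(band_integrate(tri, 485, 495), 5)
  set.seed(3)
  ran <- oceandark:::new_spectral_irradiance(wl, runif(21), runif(21))
  expect_equal(band_integrate(ran, 485, 490) + band_integrate(ran, 490, 495),
               band_integrate(ran, 485, 495), tolerance = 1e-12)
  expect_error(band_integrate(flat, 400, 495), "support")
})

test_that("the lunar phase curve is normalised at opposition and monotone", {
  expect_equal(phase_curve(0), 1)
  f <- phase_curve(c(5, 20, 60))
  expect_true(all(diff(f) < 0))
  expect_true(f[1] < 1 && f[1] > 0)
  expect_error(phase_curve(200), "\\[0, 180\\]")
})

test_that("lunar TOA irradiance follows the Lambertian disk formula", {
  sun <- toa_solar(100)
  moon <- lunar_toa(sun, phase_angle = 0, albedo = 0.10, semi_diameter = 0.26)
  ratio <- moon$direct / sun$direct
  # A * theta_s^2 with theta_s = 0.26 deg = 4.5379e-3 rad
  expect_equal(ratio, rep(0.10 * (0.26 * pi / 180)^2, length(ratio)),
               tolerance = 1e-9)
  expect_equal(ratio[1], 2.0593e-6, tolerance = 1e-4)
  # zero albedo -> zero spectrum
  expect_true(all(lunar_toa(sun, 0, albedo = 0)$direct == 0))
  # doubling the semi-diameter quadruples the irradiance
  m2 <- lunar_toa(sun, 0, albedo = 0.10, semi_diameter = 0.52)
  expect_equal(m2$direct, 4 * moon$direct, tolerance = 1e-12)
})

test_that("the latitude-month field obeys horizon, symmetry and magnitude checks", {
  irr <- surface_irradiance_field(c(-85, -45, 0, 45, 85))
  expect_true(all(is.finite(irr$sun_band)) && all(is.finite(irr$moon_band)))
  expect_true(all(irr$sun_band >= 0 & irr$moon_band >= 0))
  # polar night: no June sun at 85 S
  expect_equal(irr$sun_band[irr$latitude == -85 & irr$month == 6], 0)
  # and the sun dominates the moon wherever it is properly up
  lit <- irr[irr$sun_zenith < 70, ]
  expect_true(all(lit$moon_band <= 1e-5 * lit$sun_band))
  # June/December mirror symmetry of the solar band across the equator,
  # once the Earth-orbit distance factor (about 6.7% June vs December) is
  # divided out; what remains is the near-mirror of the declination
  jun <- irr$sun_band[irr$month == 6 & irr$latitude == 45] /
    eccentricity_factor(166)
  dec <- irr$sun_band[irr$month == 12 & irr$latitude == -45] /
    eccentricity_factor(349)
  expect_equal(jun, dec, tolerance = 0.05)
  # moonlight reaching the surface is within the disk-formula decades
  both <- irr[irr$sun_zenith < 70 & irr$moon_zenith < 80, ]
  expect_true(all(both$moon_band / both$sun_band > 1e-7))
})
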