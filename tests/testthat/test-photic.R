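test_that("Beer-Lambert inversion matches direct evaluation and floors at zero", {
  # surface irradiance at the sensitivity threshold: depth zero
  expect_equal(photic_depth(0.1, 2.7e-8), 0)
  # worked value: kd 0.05 m^-1, i0 0.5 W m^-2, Calanus threshold
  expect_equal(photic_depth(0.05, 0.5), log(0.5 / 2.7e-8) / 0.05,
               tolerance = 1e-12)
  expect_equal(photic_depth(0.05, 0.5), 334.7, tolerance = 1e-4)
  # polar night (zero irradiance) floors at zero rather than -Inf
  expect_equal(photic_depth(0.05, 0), 0)
  expect_error(photic_depth(0, 1), "positive")
  expect_error(photic_depth(0.1, -1), "non-negative")
})

test_that("the one-percent definition is irradiance-free", {
  expect_equal(photic_depth_one_percent(log(100) / 100), 100, tolerance = 1e-9)
  expect_equal(photic_depth_one_percent(0.1), 46.0517, tolerance = 1e-4)
  # equals the threshold definition when i_sens is exactly 1% of i0
  kd <- c(0.02, 0.1, 0.7)
  i0 <- c(0.3, 1.2, 8)
  expect_equal(photic_depth(kd, i0, i_sens = 0.01 * i0),
               photic_depth_one_percent(kd), tolerance = 1e-12)
  expect_error(photic_depth_one_percent(-0.1), "positive")
})

test_that("bathymetric clipping takes the minimum and flags ties as clipped", {
  r <- clip_to_bathymetry(c(334.7, 50, 100), c(100, 4000, 100))
  expect_equal(r$z, c(100, 50, 100))
  expect_identical(r$clipped, c(TRUE, FALSE, TRUE))
  expect_error(clip_to_bathymetry(10, -5), "positive")
})

test_that("photic depth is monotone in kd and in surface irradiance", {
  set.seed(21)
  kd <- sort(runif(50, 0.02, 2))
  z <- photic_depth(kd, 0.5)
  expect_true(all(diff(z) < 0))
  i0 <- sort(runif(50, 1e-6, 10))
  z2 <- photic_depth(0.1, i0)
  expect_true(all(diff(z2) > 0))
})

test_that("proportional loss is invariant to the photosensitivity threshold", {
  # the photic-niche claim: for unclipped pixels z_end/z_start depends only
  # on the kd ratio, identically across 4 decades of i_sens
  set.seed(22)
  for (k in 1:200) {
    kd1 <- runif(1, 0.02, 1); kd2 <- runif(1, 0.02, 1)
    i0 <- runif(1, 0.1, 10)
    is_ <- 10^runif(1, -9, -5)
    r <- photic_depth(kd2, i0, is_) / photic_depth(kd1, i0, is_)
    expect_equal(r, kd1 / kd2, tolerance = 1e-12)
  }
})

test_that("the change field reproduces scalar evaluation and clipping rules", {
  px <- tibble::tibble(pixel = 1:2, lat = c(50.5, 50.5),
                       kd_start = c(0.05, 0.05), kd_end = c(0.06, 0.06))
  irr <- flat_irradiance(50.5, i0_sun = 0.5, i0_moon = 0.5)
  deep <- flat_bathymetry(1:2, 6000)
  ch <- photic_change(px, deep, irr)
  # kd 0.05 -> 0.06 under i0 = 0.5: ln(0.5/2.7e-8) * (1/0.06 - 1/0.05)
  want <- log(0.5 / 2.7e-8) * (1 / 0.06 - 1 / 0.05)
  expect_equal(ch$delta_z, rep(want, 4), tolerance = 1e-9)
  expect_equal(want, -55.78, tolerance = 1e-3)
  # both years clip to a 100 m shelf: change is absorbed
  shal <- flat_bathymetry(1:2, 100)
  ch2 <- photic_change(px, shal, irr)
  expect_true(all(ch2$delta_z == 0))
  expect_true(all(ch2$clipped_frac == 1))
  # no change in kd -> no change in depth
  px0 <- dplyr::mutate(px, kd_end = kd_start)
  expect_true(all(photic_change(px0, deep, irr)$delta_z == 0))
})

test_that("zero surface irradiance months enter the annual mean as zero depth", {
  px <- tibble::tibble(pixel = 1, lat = 80.5, kd_start = 0.05, kd_end = 0.05)
  irr <- flat_irradiance(80.5, i0_sun = 0.5, i0_moon = 0) |>
    dplyr::mutate(sun_band = ifelse(month %in% c(11, 12, 1, 2), 0, sun_band))
  ch <- photic_change(px, flat_bathymetry(1), irr)
  sun <- ch[ch$luminary == "sun", ]
  expect_equal(sun$z_start, (8 / 12) * photic_depth(0.05, 0.5),
               tolerance = 1e-9)
  # all-dark moon: z_start 0, pct_change defined as 0 and flagged
  moon <- ch[ch$luminary == "moon", ]
  expect_equal(moon$z_start, 0)
  expect_true(moon$zero_start)
  expect_equal(moon$pct_change, 0)
})

test_that("the one-percent definition yields identical sun and moon fields", {
  px <- tibble::tibble(pixel = 1:3, lat = c(40.5, 42.5, 44.5),
                       kd_start = c(0.05, 0.1, 0.2),
                       kd_end = c(0.06, 0.1, 0.15))
  ch <- photic_change(px, flat_bathymetry(1:3),
                      config = photic_config(definition = "one_percent"))
  wide <- tidyr::pivot_wider(ch[, c("pixel", "luminary", "delta_z")],
                             names_from = "luminary", values_from = "delta_z")
  expect_equal(wide$sun, wide$moon)
  expect_equal(ch$z_start[ch$pixel == 2][1], log(100) / 0.1, tolerance = 1e-9)
})
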