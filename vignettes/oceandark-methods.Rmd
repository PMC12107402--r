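---
title: "Methods: from Kd(490) trends to photic-zone loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Kd(490) trends to photic-zone loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceandark)
```

## The problem

The diffuse attenuation coefficient of downwelling irradiance at 490 nm,
$K_d(490)$ (m$^{-1}$), measures how quickly blue-green light is extinguished
with depth in seawater. Where $K_d(490)$ rises over time, the ocean darkens:
the depth to which enough light penetrates for photobiology — the *photic
zone* — shoals. `oceandark` implements a complete analysis chain for
quantifying this from a stack of annual $K_d(490)$ rasters:

1. per-pixel trend detection on the annual series,
2. a clear-sky model of 485–495 nm solar and full-moon irradiance at the sea
   surface,
3. inversion of the Beer–Lambert law to photic-zone depths under a species
   photosensitivity threshold, clipped to bathymetry,
4. aggregation of the resulting depth changes into area-based summaries.

A synthetic-data generator with planted truth makes the whole chain testable
at desk scale without any satellite download.

## Trend detection

For each pixel the annual series $y_t$ is filtered through an
ARIMA$(p,1,q)$ model and the *median* ($\tau = 0.5$) regression line of the
fitted values on calendar year supplies the rate of change. Median
regression is insensitive to outlying years and makes no distributional
assumption; the ARIMA prefilter absorbs serial autocorrelation between
years.

Choices that the procedure leaves open, and how this package resolves them:

* **Order search.** $p, q \in \{0, 1, 2\}$ with $d = 1$ fixed, selected by
  AIC from maximum-likelihood fits; 20 annual values cannot support larger
  orders. Fit failures fall back to $(0,1,0)$, then to
  `insufficient_data`.
* **Drift.** A linear drift term (a regression on time alongside the ARIMA
  errors) is always included. Without it the fitted values of a trending
  series revert to a driftless random walk and the trend never reaches the
  quantile regression.
* **Fitted values.** In-sample one-step predictions on the original scale;
  the first fitted value is the first observation, since nothing precedes
  it after differencing. A series whose non-missing values are exactly
  collinear in time is handled analytically (the ML variance degenerates),
  and responses that are constant to within $10^{-12}$ relative are
  declared trendless outright — the rank test below is scale-free, so
  machine-precision wiggle must never register as a trend.
* **Completeness.** At least 10 of 20 years must be non-missing
  (`min_valid_years`), otherwise the pixel is classified
  `insufficient_data` and excluded from percentage denominators downstream.

The 95% confidence interval for the slope inverts the
Gutenbrunner–Jurečková regression rank-score test (iid-error variant,
Student-$t$ critical value with $n-2$ df). The test statistic is piecewise
constant in the hypothesised slope with breakpoints at the pairwise slopes
of the data, so the inversion is exact rather than iterative. The L1
regression itself is solved exactly by enumerating candidate lines through
pairs of points — an optimal L1 simple-regression line always interpolates
two observations, and with 20 points per pixel the enumeration is cheap.

A pixel is classified *increasing* when the CI lies above zero,
*decreasing* when below, *no change* when it straddles zero. For
significant pixels the regression line evaluated at the first and last
years gives the endpoint predictions $K_d^{2003}$ and $K_d^{2022}$ (the
line is the only fitted object with a stated slope and intercept);
otherwise both endpoints are the median of the observed series. Endpoints
are floored at the product validity minimum of 0.01 m$^{-1}$.

### A caution on the false-positive rate

The rank-score interval assumes exchangeable deviations around the median
line. One-step ARIMA fitted values are serially *smoothed*, so their
deviations are strongly autocorrelated, and on synthetic null AR(1) series
($\phi = 0.5$, $n = 20$) the package's own acceptance measurements put the
fraction classified significant near 0.4 rather than the nominal 0.05.
This is a property of the procedure itself — it persists (at ~0.3) if the
drift is dropped, and (at ~0.15) if the interval is computed from the raw
series instead — while the same interval is well calibrated (~0.04) on
independent noise. Power is good: a trend of three (marginal) noise
standard deviations over the 20-year span is detected with the correct
sign in ~85% of series. Maps produced by this chain should therefore be
read as sensitive but permissive: regional aggregates are informative,
individual-pixel significance is overstated wherever the annual noise is
autocorrelated.

## Surface irradiance

Top-of-atmosphere spectral solar irradiance comes from a packaged reference
spectrum scaled by the Earth-orbit eccentricity factor
$\left(1 + \varepsilon \cos \tfrac{2\pi (D - 3)}{365}\right)^2$ with
$\varepsilon = 0.0167$ and $D$ the day of year (365 is used for leap years
too). The clear-sky marine atmosphere transmits it to just above the sea
surface ($0^+$) with the classical decomposition: Kasten–Young air mass;
Rayleigh, aerosol, ozone, oxygen and water-vapour transmittances for the
direct beam; single-scattering Rayleigh and aerosol terms for the diffuse
sky component; global = direct + diffuse. Aerosol turbidity follows the
marine visibility parameterisation (Ångström exponent 0.5,
single-scattering albedo 0.985, asymmetry 0.75). Defaults — 1013.25 hPa,
2.5 cm precipitable water, 350 DU ozone, 80% RH, 5 m s$^{-1}$ wind, 23 km
visibility — are canonical clear-sky marine values and all sit in
`marine_atmosphere()` rather than being hard-coded, since the original
analysis settings are not fully specified anywhere recoverable. Gaseous
absorption and the two packaged spectra are coarse tabulations interpolated
to the 1 nm working grid (350–700 nm); only the 485–495 nm band is consumed
downstream, where ozone absorption is weak and oxygen/water-vapour bands
are absent, so coarse tables cost little accuracy. A zenith angle of 90° or
more yields an exactly zero spectrum.

Full-moon irradiance is assembled as a Lambertian disk:
$E_{moon}(\lambda) = E_{sun}(\lambda)\, A(\lambda)\, f(\alpha)\,
\theta_s^2$, with spectral albedo $A$ from a packaged table, phase factor
$f$ normalised to 1 at opposition (the two-exponential $H,G$
standardisation of the Lumme–Bowell photometric theory, $G = 0.15$), and
the mean semi-diameter $\theta_s = 0.26^\circ$ in radians (disk radiance
$A E_{sun}/\pi$ over solid angle $\pi \theta_s^2$); the Earth–Moon distance
is held fixed. The moon-to-sun band ratio at the top of the atmosphere is
then $\sim 2\times10^{-6}$, and stays within $10^{-7}$–$10^{-5}$ for any
albedo in 0.05–0.2.

The monthly field `surface_irradiance_field()` evaluates, per latitude:
the sun at solar noon on the 15th of each month (noon zenith =
|latitude − declination|, which is longitude-free), and the full moon at
its culmination — the altitude maximum within half a transit period
(±13 h) of the month's full-moon instant, computed at the reference
longitude 0°. Lunar positions come from the package's own low-precision
almanac series (~0.3° for the Moon, topocentric parallax corrected), well
inside the 1° accuracy the pipeline needs; full-moon instants land within
an hour of standard almanac tabulations (a packaged 2022 reference table
is used in the tests). Note one physical asymmetry worth knowing: during
polar night the *moon* can be high while the sun never rises, so monthly
moonlight irradiance legitimately exceeds sunlight there; and at grazing
solar zenith the moon/sun surface ratio can marginally exceed the
$10^{-5}$ top-of-atmosphere bound because of the differential air mass.

## Photic-zone depths and their change

Under the threshold definition, the photic depth for a pixel, month and
luminary is the Beer–Lambert inversion

$$Z_{photic} = -\frac{1}{K_d(490)} \ln \frac{I_{sens}}{I_0},$$

floored at 0 when the surface irradiance $I_0$ is at or below the
threshold (polar night included). The default threshold
$I_{sens} = 2.7\times10^{-8}$ W m$^{-2}$ (0.027 µW m$^{-2}$) is the
minimum 490 nm irradiance that elicits diel vertical migration in
*Calanus* copepods — a deliberately photosensitive benchmark; the
classical 1%-of-surface criterion ($Z = \ln(100)/K_d$, identical for sun
and moon) is available as `definition = "one_percent"`. The unit
conversion happens once, at `photic_config()`; everything internal is in
W m$^{-2}$.

Depths are clipped to bathymetry (a tie counts as clipped), *then*
differenced between the endpoint years, month by month, and the twelve
monthly differences are averaged; months with a dark luminary contribute
zero depth. Percent change is taken relative to the annual-mean start
depth and defined as 0 (with a flag) when that depth is 0. Because
$I_{sens}$ enters only through $\ln(I_0/I_{sens})$, the *ratio*
$Z_{end}/Z_{start}$ for unclipped pixels equals
$K_d^{start}/K_d^{end}$ for every threshold — the proportional loss is
species-independent, and the test suite asserts this across four decades
of $I_{sens}$ at $10^{-12}$ relative tolerance.

## Areas and aggregation

Two area conventions are provided. `spherical` (default) is exact on the
sphere ($R = 6371.0088$ km). `mercator_grid` reproduces the footprint of a
point grid spaced $s$ metres apart in a World Mercator projection,
$(s \cos\varphi)^2$ — the convention of analyses that count
Mercator-spaced points. Mercator is not equal-area; both modes are exposed
so the discrepancy is visible rather than hidden. Threshold areas use
strict "more than" comparisons; the change histogram uses left-open 10 m
bins with increases binned separately; `insufficient_data` pixels leave
every percentage denominator. Conservation (regions, classifications,
bins) is exact by construction and asserted exactly in the tests.

## The synthetic generator

`simulate_kd_stack()` emulates what the analysis assumes about the real
archive: per-pixel linear trends plus *stationary* AR(1) noise
(autocorrelation for the ARIMA stage to absorb; $\phi = 0.5$ by default),
values clamped to the product validity range (0.01, 6.4] m$^{-1}$, and
independent 5% per-pixel-per-year dropout (with a polar-night-like option
that triples dropout poleward of 66.5°). Noise magnitudes for real annual
$K_d(490)$ series are not documented anywhere usable, so the default
innovation sd of 0.01 m$^{-1}$ against baselines of ~0.1 m$^{-1}$ is a
plausible placeholder for sensitivity sweeps, not a calibrated value.
Bathymetry is a smooth shelf-to-abyss ramp; regions are a seeded Voronoi
partition (contiguous by construction). Grids are regular lat/lon so the
planted truth maps stay exact; Mercator-grid fidelity is covered
separately by `resample_to_point_grid()`. One integer seed drives
everything, and every generator is pure given (inputs, seed).

What the generator does *not* emulate: satellite radiometry and retrieval
error, cloud masking, spatially correlated noise, seasonal structure
(annual composites by design), or coastline geometry. Passing tests
therefore demonstrate that the *chain* recovers what it assumes, not that
the real archive satisfies those assumptions.

## Problem sizes and I/O

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path: 10,000 random pixels for the Beer-law oracle, 2,000 null and
500 trended series for the error-rate measurements, and a 64×64, 20-year
stack with a planted darkening region for the end-to-end recovery — small
enough to run anywhere, large enough for stable Monte-Carlo fractions.
Raster interchange is a long-format CSV plus a JSON sidecar (grid, years,
nodata −999, WGS84, cell-centre registration, row 1 northernmost), which
round-trips losslessly including the missingness mask; trend maps export
with the colour/code convention 1 = increasing (red), −1 = decreasing
(blue), 0 = no change (white), −9 = insufficient data.

## Known limitations

* Pixel-level significance is permissive under autocorrelated noise (see
  the trend caution above); no multiple-testing correction is applied
  across pixels, deliberately.
* $K_d(490)$ is treated as vertically invariant — no mixed layer, deep
  chlorophyll maximum, or depth-varying attenuation.
* Clear sky only; no cloud climatology, and no air–sea interface
  transmission (depths are driven by the $0^+$ irradiance).
* The ephemeris is a truncated almanac series (~0.3°); adequate here, not
  for astrometry. The Earth–Moon distance, and hence the lunar
  semi-diameter, is fixed at its mean.
* The packaged spectra are smoothed coarse tables: band-integrated results
  outside 485–495 nm should not be quoted at better than a few percent.
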