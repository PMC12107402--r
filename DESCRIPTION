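Package: oceandark
Title: Detecting Ocean Darkening and Photic-Zone Loss from Kd(490) Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying darkening of the
    surface ocean from annual composites of the diffuse attenuation
    coefficient of downwelling irradiance at 490 nm, Kd(490). Per-pixel
    rates of change are estimated by median quantile regression on the
    fitted values of an ARIMA(p,1,q) model, with 95% confidence intervals
    from rank-score test inversion. Clear-sky spectral solar and full-moon
    irradiance just above the sea surface is modelled at 1 nm resolution
    and band-integrated over 485-495 nm. Photic-zone depths are obtained
    by inverting the Beer-Lambert law under a species photosensitivity
    threshold (default: the diel-vertical-migration threshold of Calanus
    copepods) or the classical 1%-of-surface criterion, clipped to
    bathymetry, and changes are aggregated into area-based regional
    summaries. A synthetic-data generator provides Kd stacks with planted
    trends, bathymetry and region masks so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
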