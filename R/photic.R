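# Photic-zone depths by Beer-Lambert inversion under a photosensitivity
# threshold, bathymetric clipping, and 2003 -> 2022 change fields.

#' Photic-zone configuration
#'
#' The photic zone is defined either by an absolute irradiance threshold
#' (`definition = "threshold"`; the default threshold is the minimum 490 nm
#' irradiance that elicits diel vertical migration in Calanus copepods,
#' 0.027 uW m^-2 = 2.7e-8 W m^-2) or by the classical criterion of 1% of
#' surface irradiance (`definition = "one_percent"`).
#'
#' @param i_sens Photosensitivity threshold, W m^-2 (> 0).
#' @param definition `"threshold"` or `"one_percent"`.
#' @return List of class `photic_config`.
#' @export
photic_config <- function(i_sens = 2.7e-8,
                          definition = c("threshold", "one_percent")) {
  definition <- match.arg(definition)
  if (i_sens <= 0) stop("i_sens must be positive", call. = FALSE)
  structure(list(i_sens = i_sens, definition = definition),
            class = "photic_config")
}

#' Photic-zone depth under an irradiance threshold
#'
#' Inverts the Beer-Lambert law: the depth where downwelling 490 nm
#' irradiance falls to the photosensitivity threshold,
#' `Z = -(1 / Kd) * ln(i_sens / i0)`, floored at zero when the surface
#' irradiance is already at or below the threshold (including `i0 = 0`,
#' e.g. polar night).
#'
#' @param kd Diffuse attenuation coefficient Kd(490), m^-1 (> 0);
#'   vectorised.
#' @param i0 Band-integrated surface irradiance, W m^-2 (>= 0); vectorised.
#' @param i_sens Photosensitivity threshold, W m^-2.
#' @return Depth in metres (>= 0).
#' @examples
#' photic_depth(0.05, 0.5)           # ~334.7 m for Calanus
#' @export
photic_depth <- function(kd, i0, i_sens = 2.7e-8) {
  if (any(kd <= 0, na.rm = TRUE)) stop("kd must be positive", call. = FALSE)
  if (any(i0 < 0, na.rm = TRUE)) stop("i0 must be non-negative", call. = FALSE)
  z <- ifelse(i0 <= i_sens, 0, log(i0 / i_sens) / kd)
  pmax(0, z)
}

#' Photic-zone depth under the 1%-of-surface criterion
#'
#' `Z = ln(100) / Kd`: independent of the absolute surface irradiance and
#' therefore identical for sunlight and moonlight.
#'
#' @param kd Kd(490), m^-1 (> 0); vectorised.
#' @return Depth in metres.
#' @export
photic_depth_one_percent <- function(kd) {
  if (any(kd <= 0, na.rm = TRUE)) stop("kd must be positive", call. = FALSE)
  log(100) / kd
}

#' Clip photic depth to the sea floor
#'
#' Where the photic depth reaches or exceeds the bathymetric depth, the
#' bathymetric depth is used and the pixel is flagged as clipped (a tie
#' counts as clipped).
#'
#' @param z Photic depth, m (>= 0); vectorised.
#' @param depth Bathymetric depth, m, positive down (> 0); vectorised.
#' @return Tibble: `z` (clipped depth) and `clipped` (logical).
#' @export
clip_to_bathymetry <- function(z, depth) {
  if (any(depth <= 0, na.rm = TRUE))
    stop("bathymetric depth must be positive", call. = FALSE)
  if (any(z < 0, na.rm = TRUE)) stop("z must be non-negative", call. = FALSE)
  tibble::tibble(z = pmin(z, depth), clipped = z >= depth)
}

#' Per-pixel photic-zone change between the endpoint years
#'
#' For every pixel, month and luminary (sun, moon), computes the photic
#' depth for the start-year and end-year Kd(490) predictions using that
#' month's band irradiance, clips each to bathymetry, differences them, and
#' averages the monthly differences over the 12 months. Percent change is
#' relative to the annual-mean start depth (defined as 0, and flagged, when
#' that depth is 0). Months in which the luminary never rises contribute a
#' depth of 0 to the annual mean.
#'
#' @param trends A `kd_trends` tibble (or any data frame with `pixel`,
#'   `lat`, `kd_start`, `kd_end`; pixels with missing endpoints are
#'   dropped).
#' @param bathymetry Data frame with `pixel` and `depth` (m, positive
#'   down), as from [simulate_bathymetry()].
#' @param irradiance An `irradiance_field` tibble
#'   ([surface_irradiance_field()]); each pixel uses the nearest latitude
#'   row. Ignored (and optional) under the one-percent definition.
#' @param config A [photic_config()].
#' @return A tibble of class `photic_change`, one row per pixel x luminary:
#'   `z_start`, `z_end` (annual means, m), `delta_z` (m), `pct_change`
#'   (%), `clipped_frac` (fraction of the 24 pixel-months clipped),
#'   `zero_start` (flag for the degenerate percent rule).
#' @export
photic_change <- function(trends, bathymetry, irradiance = NULL,
                          config = photic_config()) {
  stopifnot(inherits(config, "photic_config"))
  need <- c("pixel", "kd_start", "kd_end")
  if (!all(need %in% names(trends)))
    stop("trends must contain pixel, kd_start, kd_end", call. = FALSE)
  px <- trends |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$kd_start), !is.na(.data$kd_end)) |>
    dplyr::select(dplyr::any_of(c("pixel", "row", "col", "lat", "lon",
                                  "kd_start", "kd_end")))
  px <- dplyr::inner_join(
    px, dplyr::select(tibble::as_tibble(bathymetry), "pixel", "depth"),
    by = "pixel"
  )
  if (nrow(px) == 0) stop("no pixels with endpoint Kd and depth", call. = FALSE)

  if (config$definition == "one_percent") {
    # irradiance-free: identical for both luminaries, no monthly structure
    long <- tidyr::crossing(px, luminary = c("sun", "moon")) |>
      dplyr::mutate(
        zs = photic_depth_one_percent(.data$kd_start),
        ze = photic_depth_one_percent(.data$kd_end)
      )
    months_n <- 1
  } else {
    if (is.null(irradiance))
      stop("the threshold definition needs an irradiance field", call. = FALSE)
    if (!("lat" %in% names(px)))
      stop("trends must carry a lat column to look up irradiance", call. = FALSE)
    irr_long <- irradiance |>
      tibble::as_tibble() |>
      tidyr::pivot_longer(c("sun_band", "moon_band"), names_to = "luminary",
                          values_to = "i0") |>
      dplyr::mutate(luminary = sub("_band$", "", .data$luminary))
    irr_lats <- sort(unique(irr_long$latitude))
    px$irr_lat <- irr_lats[pmax(1, pmin(length(irr_lats),
      findInterval(px$lat, c(-Inf, irr_lats[-1] - diff(irr_lats) / 2))))]
    long <- tidyr::crossing(px, month = 1:12, luminary = c("sun", "moon")) |>
      dplyr::left_join(irr_long, by = c(irr_lat = "latitude", "month",
                                        "luminary")) |>
      dplyr::mutate(
        zs = photic_depth(.data$kd_start, .data$i0, config$i_sens),
        ze = photic_depth(.data$kd_end, .data$i0, config$i_sens)
      )
    months_n <- 12
  }
  long <- long |>
    dplyr::mutate(
      zs_c = pmin(.data$zs, .data$depth),
      ze_c = pmin(.data$ze, .data$depth),
      clip = .data$zs >= .data$depth | .data$ze >= .data$depth
    )
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("pixel", "row", "col", "lat", "lon", "luminary")))) |>
    dplyr::summarise(
      z_start = mean(.data$zs_c), z_end = mean(.data$ze_c),
      delta_z = mean(.data$ze_c - .data$zs_c),
      clipped_frac = mean(.data$clip), .groups = "drop"
    ) |>
    dplyr::mutate(
      zero_start = .data$z_start == 0,
      pct_change = dplyr::if_else(.data$zero_start, 0,
                                  100 * .data$delta_z / .data$z_start)
    )
  out <- tibble::new_tibble(out, class = "photic_change")
  attr(out, "definition") <- config$definition
  attr(out, "months") <- months_n
  out
}
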