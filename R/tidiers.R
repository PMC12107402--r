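# broom-style accessors for fitted trend objects.

#' Tidy a per-pixel trend fit
#'
#' @param x A `kd_trend_fit` from [fit_kd_trend()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`slope`, `intercept`),
#'   the rank-inversion confidence bounds attached to the slope row.
#' @method tidy kd_trend_fit
#' @export
tidy.kd_trend_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$ci_low, NA_real_),
    conf.high = c(x$ci_high, NA_real_)
  )
}

#' One-row summary of a per-pixel trend fit
#'
#' @param x A `kd_trend_fit` from [fit_kd_trend()].
#' @param ... Unused.
#' @return A one-row tibble: ARIMA order, AIC, valid-year count,
#'   classification and endpoint Kd predictions.
#' @method glance kd_trend_fit
#' @export
glance.kd_trend_fit <- function(x, ...) {
  tibble::tibble(
    arima_p = x$order[1], arima_d = x$order[2], arima_q = x$order[3],
    aic = x$aic, n_valid = x$n_valid, classification = x$classification,
    kd_start = x$kd_start, kd_end = x$kd_end
  )
}

#' Summarise a pixel-map of trend fits
#'
#' @param x A `kd_trends` tibble from [kd_trends()].
#' @param ... Unused.
#' @return A one-row tibble with pixel counts per classification and the
#'   median fitted slope.
#' @method glance kd_trends
#' @export
glance.kd_trends <- function(x, ...) {
  tibble::tibble(
    n_pixels = nrow(x),
    n_increasing = sum(x$classification == "increasing"),
    n_decreasing = sum(x$classification == "decreasing"),
    n_no_change = sum(x$classification == "no_change"),
    n_insufficient = sum(x$classification == "insufficient_data"),
    median_slope = stats::median(x$slope, na.rm = TRUE)
  )
}
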