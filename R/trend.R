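# Per-pixel trend detection: ARIMA(p,1,q) prefilter to absorb serial
# autocorrelation, median (tau = 0.5) regression on the fitted values, and a
# 95% confidence interval for the slope by rank-score test inversion.

#' Select an ARIMA(p, 1, q) model for an annual Kd series
#'
#' Fits all orders with `p, q` in `0:2` and one non-seasonal difference
#' (d = 1 fixed), always including a linear drift term, and returns the
#' AIC-minimising fit. Twenty annual values cannot support larger orders.
#' Series whose non-missing values are exactly collinear in time (zero
#' residual variance) are handled analytically as a drifted random walk,
#' order (0, 1, 0).
#'
#' @param series Numeric vector of annual values; `NA` marks missing years.
#' @param p_max,q_max Upper bounds of the order search grid (default 2).
#' @return A list: `order` (p, d, q), `fitted` (in-sample one-step
#'   predictions, same length as `series`, `NA` where the input is missing;
#'   the first non-missing value is carried through unchanged), `aic`, and
#'   `degenerate` (TRUE for the collinear fallback).
#' @export
select_arima <- function(series, p_max = 2, q_max = 2) {
  n <- length(series)
  ok <- !is.na(series)
  t_all <- seq_len(n)
  # exactly (or numerically) deterministic linear series: ML degenerates
  fit0 <- stats::lm.fit(cbind(1, t_all[ok]), series[ok])
  scale <- max(1, stats::sd(series[ok]))
  if (sqrt(mean(fit0$residuals^2)) < 1e-9 * scale) {
    fitted <- rep(NA_real_, n)
    fitted[ok] <- cbind(1, t_all[ok]) %*% fit0$coefficients
    first <- which(ok)[1]
    fitted[first] <- series[first]
    return(list(order = c(0L, 1L, 0L), fitted = fitted, aic = -Inf,
                degenerate = TRUE))
  }
  best <- NULL
  for (p in 0:p_max) for (q in 0:q_max) {
    fit <- tryCatch(
      stats::arima(series, order = c(p, 1, q), xreg = t_all, method = "ML"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit) && is.finite(fit$aic) &&
        (is.null(best) || fit$aic < best$aic)) {
      best <- list(fit = fit, aic = fit$aic, order = c(p, 1L, q))
    }
  }
  if (is.null(best)) {
    fit <- tryCatch(
      stats::arima(series, order = c(0, 1, 0), xreg = t_all, method = "CSS"),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    best <- list(fit = fit, aic = NA_real_, order = c(0L, 1L, 0L))
  }
  fitted <- series - as.numeric(stats::residuals(best$fit))
  first <- which(ok)[1]
  fitted[first] <- series[first]
  list(order = best$order, fitted = fitted, aic = best$aic, degenerate = FALSE)
}

#' Exact median (L1) regression line
#'
#' Minimises the sum of absolute residuals of `y` on `x` by enumerating all
#' candidate lines through pairs of observations (an optimal L1 simple
#' regression always interpolates at least two points). Exact and fast for
#' the short annual series this package handles.
#'
#' @param x,y Numeric vectors of equal length (>= 3 finite pairs).
#' @return List with `slope` and `intercept`.
#' @export
median_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("median_line needs at least 3 finite points", call. = FALSE)
  # constant response (to numerical precision): flat line, no trend
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1))
    return(list(slope = 0, intercept = stats::median(y)))
  xm <- mean(x)
  xc <- x - xm
  ij <- utils::combn(n, 2)
  dx <- xc[ij[2, ]] - xc[ij[1, ]]
  keep <- abs(dx) > 0
  b <- (y[ij[2, keep]] - y[ij[1, keep]]) / dx[keep]
  a <- y[ij[1, keep]] - b * xc[ij[1, keep]]
  # objective for each candidate line
  res <- abs(outer(y, rep(1, length(b))) - outer(xc, b) -
               matrix(a, length(x), length(b), byrow = TRUE))
  obj <- colSums(res)
  tol <- 1e-10 * max(obj[1], 1)
  best <- which(obj <= min(obj) + tol)
  # deterministic, sign-equivariant tie-break: smallest |slope|, then value
  best <- best[order(abs(b[best]), b[best], a[best])][1]
  list(slope = b[best], intercept = a[best] - b[best] * xm)
}

#' Rank-score inversion confidence interval for a median-regression slope
#'
#' Inverts the Gutenbrunner-Jureckova regression rank-score test for the
#' hypothesis `slope = b` in the model `y = a + b x + e` at `tau = 0.5`
#' (iid-error variant). The test statistic is piecewise constant in `b`
#' with breakpoints at the pairwise slopes, so the inversion is exact: the
#' interval endpoints are breakpoints where the standardised statistic
#' crosses the critical value (Student t with n - 2 df).
#'
#' @param x,y Numeric vectors of equal length.
#' @param level Confidence level (default 0.95).
#' @return List with `ci_low` and `ci_high`.
#' @export
rank_ci <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("rank_ci needs at least 4 finite points", call. = FALSE)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("x is constant", call. = FALSE)
  # constant response (to numerical precision): the rank test is scale-free,
  # so machine noise must not masquerade as a trend
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1))
    return(list(ci_low = 0, ci_high = 0))
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  keep <- abs(dx) > 0
  bp <- sort(unique((y[ij[2, keep]] - y[ij[1, keep]]) / dx[keep]))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 2)

  tstat <- function(b) {
    z <- y - b * x
    xi <- sort(z)[ceiling(n / 2)]        # tau = 0.5 order-statistic fit
    a <- ifelse(z > xi, 1, 0)
    n_eq <- sum(z == xi)
    if (n_eq > 0) a[z == xi] <- min(1, max(0, (n / 2 - sum(z > xi)) / n_eq))
    sum(xc * (a - 0.5)) / sqrt(0.25 * sxx)
  }

  m <- length(bp)
  eps <- max(1e-9, 1e-6 * (bp[m] - bp[1]))
  mids <- c(bp[1] - eps,
            if (m > 1) (bp[-m] + bp[-1]) / 2 else numeric(0),
            bp[m] + eps)
  tv <- vapply(mids, tstat, numeric(1))   # non-increasing in b
  inside <- which(abs(tv) <= tcrit)
  if (length(inside) == 0) {
    # statistic jumps across the acceptance band: zero-width interval at the
    # breakpoint where it crosses (degenerate, e.g. exactly collinear data)
    j <- which(diff(sign(tv)) < 0)[1]
    if (is.na(j)) j <- 1
    return(list(ci_low = bp[j], ci_high = bp[j]))
  }
  lo <- if (min(inside) == 1) -Inf else bp[min(inside) - 1]
  hi <- if (max(inside) == length(mids)) Inf else bp[max(inside)]
  list(ci_low = lo, ci_high = hi)
}

#' Fit the darkening trend of one annual Kd(490) series
#'
#' The full per-pixel chain: ARIMA(p,1,q) prefilter ([select_arima()]),
#' median regression of the fitted values on calendar year
#' ([median_line()]), 95% CI by rank-score inversion ([rank_ci()]), and
#' classification: `increasing` when the CI lies above zero, `decreasing`
#' when below, `no_change` when it straddles zero. For significant pixels
#' the regression line is evaluated at the first and last year to give the
#' endpoint Kd predictions; otherwise both endpoints are the median of the
#' observed (raw) series. Endpoints are floored at the Kd validity minimum
#' (0.01 m^-1).
#'
#' @param kd Numeric vector of annual Kd(490), m^-1 (`NA` = missing).
#' @param years Calendar years, same length as `kd`, consecutive.
#' @param min_valid_years Minimum number of non-missing years required
#'   (default 10); fewer yields classification `insufficient_data`.
#' @param level Confidence level for the slope interval (default 0.95).
#' @return An object of class `kd_trend_fit`; see [tidy.kd_trend_fit()] and
#'   [glance.kd_trend_fit()].
#' @examples
#' y <- ar1_series(20, mean = 0.1, slope = 0.003, sigma = 0.004, seed = 7)
#' fit_kd_trend(y, 2003:2022)
#' @export
fit_kd_trend <- function(kd, years, min_valid_years = 10, level = 0.95) {
  stopifnot(length(kd) == length(years))
  n_valid <- sum(!is.na(kd))
  empty <- list(
    slope = NA_real_, intercept = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, classification = "insufficient_data",
    kd_start = NA_real_, kd_end = NA_real_, n_valid = n_valid,
    order = c(NA_integer_, NA_integer_, NA_integer_), aic = NA_real_,
    years = years, fitted = rep(NA_real_, length(kd)), series = kd,
    level = level
  )
  if (n_valid < min_valid_years) return(new_kd_trend_fit(empty))
  sel <- select_arima(kd)
  if (is.null(sel)) return(new_kd_trend_fit(empty))
  ok <- !is.na(sel$fitted)
  ml <- median_line(years[ok], sel$fitted[ok])
  ci <- rank_ci(years[ok], sel$fitted[ok], level = level)
  cls <- if (ci$ci_low > 0) "increasing"
         else if (ci$ci_high < 0) "decreasing"
         else "no_change"
  if (cls == "no_change") {
    med <- stats::median(kd, na.rm = TRUE)
    kd_start <- kd_end <- max(KD_MIN, med)
  } else {
    kd_start <- max(KD_MIN, ml$intercept + ml$slope * years[1])
    kd_end <- max(KD_MIN, ml$intercept + ml$slope * years[length(years)])
  }
  new_kd_trend_fit(list(
    slope = ml$slope, intercept = ml$intercept,
    ci_low = ci$ci_low, ci_high = ci$ci_high, classification = cls,
    kd_start = kd_start, kd_end = kd_end, n_valid = n_valid,
    order = sel$order, aic = sel$aic, years = years, fitted = sel$fitted,
    series = kd, level = level
  ))
}

new_kd_trend_fit <- function(x) structure(x, class = "kd_trend_fit")

#' @export
print.kd_trend_fit <- function(x, ...) {
  cat("<kd_trend_fit>\n")
  if (x$classification == "insufficient_data") {
    cat(sprintf("  insufficient data (%d valid years)\n", x$n_valid))
    return(invisible(x))
  }
  cat(sprintf("  ARIMA(%d,%d,%d) + drift; median-regression slope %.3g m^-1 yr^-1\n",
              x$order[1], x$order[2], x$order[3], x$slope))
  cat(sprintf("  %d%% CI [%.3g, %.3g] -> %s\n", round(100 * x$level),
              x$ci_low, x$ci_high, x$classification))
  cat(sprintf("  predicted Kd: %.4g (start) -> %.4g (end) m^-1\n",
              x$kd_start, x$kd_end))
  invisible(x)
}

#' Map the trend fit over every pixel of a Kd stack
#'
#' Applies [fit_kd_trend()] to each pixel of a long-format Kd stack. Pixels
#' are processed independently, so the result does not depend on the number
#' of workers or on processing order; per-pixel failures are recorded as
#' `insufficient_data` and never abort the map.
#'
#' @param data A `kd_stack` tibble (see [simulate_kd_stack()] or
#'   [read_kd_stack()]) or any data frame with columns `pixel`, `year`,
#'   `kd` (and optionally `row`, `col`, `lat`, `lon`).
#' @param min_valid_years,level Passed to [fit_kd_trend()].
#' @param workers Number of worker processes (forked via the parallel
#'   package when > 1).
#' @return A tibble of class `kd_trends`, one row per pixel: coordinates,
#'   `slope`, `ci_low`, `ci_high`, `classification`, `kd_start`, `kd_end`,
#'   `n_valid`, `arima_p`, `arima_q`.
#' @export
kd_trends <- function(data, min_valid_years = 10, level = 0.95, workers = 1) {
  need <- c("pixel", "year", "kd")
  if (!all(need %in% names(data)))
    stop("data must contain columns pixel, year, kd", call. = FALSE)
  grid <- attr(data, "grid")
  data <- dplyr::arrange(tibble::as_tibble(data), .data$pixel, .data$year)
  coord_cols <- intersect(c("row", "col", "lat", "lon"), names(data))
  coords <- dplyr::distinct(data, .data$pixel,
                            dplyr::across(dplyr::all_of(coord_cols)))
  series <- split(data$kd, data$pixel)
  yearss <- split(data$year, data$pixel)
  one <- function(i) {
    fit <- tryCatch(
      fit_kd_trend(series[[i]], yearss[[i]],
                   min_valid_years = min_valid_years, level = level),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        slope = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        classification = "insufficient_data", kd_start = NA_real_,
        kd_end = NA_real_, n_valid = sum(!is.na(series[[i]])),
        arima_p = NA_integer_, arima_q = NA_integer_
      ))
    }
    tibble::tibble(
      slope = fit$slope, ci_low = fit$ci_low, ci_high = fit$ci_high,
      classification = fit$classification, kd_start = fit$kd_start,
      kd_end = fit$kd_end, n_valid = fit$n_valid,
      arima_p = fit$order[1], arima_q = fit$order[3]
    )
  }
  idx <- seq_along(series)
  rows <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, one, mc.cores = workers)
  } else {
    lapply(idx, one)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(pixel = as.integer(names(series))),
    dplyr::bind_rows(rows)
  )
  out <- dplyr::left_join(coords, out, by = "pixel")
  out <- tibble::new_tibble(out, class = "kd_trends")
  attr(out, "grid") <- grid
  attr(out, "years") <- attr(data, "years")
  out
}
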