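#' Monthly maximum-value composite
#'
#' Collapses a dated acquisition stack to one value per pixel per calendar
#' month: the maximum over the month's non-missing acquisitions. The
#' maximum-value composite is the standard defence against cloud, aerosol
#' and view-angle contamination in optical vegetation-index series, which
#' bias NDVI low. Months with no valid acquisition are missing.
#'
#' @param stack an [acq_stack].
#' @param period length-2 vector (date-parseable) delimiting whole
#'   calendar months; defaults to Jan 2000 -- Dec 2019, giving a 240-month
#'   index.
#' @return a [monthly_series] covering every month in `period`.
#' @export
monthly_max_composite <- function(stack, period = c("2000-01-01", "2019-12-31")) {
  period <- as.Date(period)
  months <- month_index_seq(period[1], period[2])
  inside <- stack$dates >= period[1] & stack$dates <= period[2]
  if (!any(inside)) stop("stack has zero layers inside the composite period")
  layer_ym <- as.integer(format(stack$dates, "%Y")) * 12L +
    as.integer(format(stack$dates, "%m")) - 1L
  ym <- months$year * 12L + (months$month - 1L)
  group <- match(layer_ym, ym, nomatch = 0L)
  group[!inside] <- 0L
  vals <- .group_max(stack$values, group, length(ym))
  monthly_series(stack$grid, months$year, months$month, vals)
}

month_index_seq <- function(from, to) {
  y0 <- as.integer(format(from, "%Y")); m0 <- as.integer(format(from, "%m"))
  y1 <- as.integer(format(to, "%Y")); m1 <- as.integer(format(to, "%m"))
  ym <- (y0 * 12L + m0 - 1L):(y1 * 12L + m1 - 1L)
  list(year = ym %/% 12L, month = ym %% 12L + 1L)
}

#' Multi-annual monthly climatology
#'
#' For each pixel and calendar month, the arithmetic mean of the monthly
#' composite across all years in the series, with the number of
#' contributing years recorded. Means backed by fewer than `min_years`
#' years are set missing: a "multi-annual" average needs more than a year
#' or two of support.
#'
#' @param monthly a [monthly_series] (normally the monthly composite).
#' @param min_years minimum contributing years per calendar month
#'   (default 3).
#' @return an object of class `climatology`: 12-column `means` and
#'   `counts` matrices (January..December), plus the grid.
#' @export
compute_climatology <- function(monthly, min_years = 3) {
  means <- matrix(NA_real_, nrow(monthly$values), 12)
  counts <- matrix(0L, nrow(monthly$values), 12)
  for (m in 1:12) {
    cols <- which(monthly$month == m)
    if (length(cols) == 0) next
    sub <- monthly$values[, cols, drop = FALSE]
    cnt <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[cnt < min_years] <- NA_real_
    means[, m] <- mu
    counts[, m] <- cnt
  }
  structure(list(grid = monthly$grid, means = means, counts = counts,
                 min_years = min_years),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> %s, 12 monthly means (min_years = %d), %.1f%% missing\n",
              format(x$grid), x$min_years, 100 * mean(is.na(x$means))))
  invisible(x)
}

#' Remove the seasonal cycle (decycling)
#'
#' Subtracts each pixel's multi-annual monthly mean from the monthly
#' composite, leaving seasonal anomalies. Missing wherever either operand
#' is missing.
#'
#' @param monthly a [monthly_series].
#' @param clim the matching [compute_climatology] result.
#' @return a [monthly_series] of anomalies.
#' @export
decycle <- function(monthly, clim) {
  stopifnot(inherits(clim, "climatology"))
  stop_if_grid_mismatch(monthly$grid, clim$grid, "monthly series and climatology")
  anom <- monthly$values - clim$means[, monthly$month, drop = FALSE]
  monthly_series(monthly$grid, monthly$year, monthly$month, anom)
}

#' 12-month moving average
#'
#' Smooths the anomaly series with a 12-month trailing window, labelled by
#' the window's final month; the first 11 months, which have no complete
#' window, are removed (240 months in, 229 out). By default a window must
#' be complete (12 non-missing values) to produce output; lowering
#' `min_valid_in_window` averages over the valid values instead, which is
#' the practical choice for gap-ridden series where a strict rule would
#' delete most pixels.
#'
#' @param anomaly a [monthly_series] (normally decycled anomalies).
#' @param min_valid_in_window minimum non-missing values a 12-month window
#'   needs (default 12, i.e. complete windows only).
#' @return a [monthly_series] 11 months shorter than the input.
#' @export
moving_average_12 <- function(anomaly, min_valid_in_window = 12) {
  n <- length(anomaly$year)
  if (n < 12) stop("moving average needs at least 12 months")
  stopifnot(min_valid_in_window >= 1, min_valid_in_window <= 12)
  out <- .rolling_mean_12(anomaly$values, as.integer(min_valid_in_window))
  idx <- 12:n
  monthly_series(anomaly$grid, anomaly$year[idx], anomaly$month[idx], out)
}

#' Full preprocessing chain
#'
#' Composite, climatology, decycling and 12-month smoothing in one call:
#' the series on which the per-pixel trend statistic is computed.
#'
#' @inheritParams monthly_max_composite
#' @inheritParams compute_climatology
#' @inheritParams moving_average_12
#' @return a [monthly_series] of smoothed anomalies.
#' @export
preprocess_stack <- function(stack, period = c("2000-01-01", "2019-12-31"),
                             min_years = 3, min_valid_in_window = 12) {
  monthly <- monthly_max_composite(stack, period)
  clim <- compute_climatology(monthly, min_years = min_years)
  anom <- decycle(monthly, clim)
  moving_average_12(anom, min_valid_in_window = min_valid_in_window)
}
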