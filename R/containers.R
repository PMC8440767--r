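#' Dated NDVI acquisition stack
#'
#' The in-memory form of a stack of dated NDVI rasters on a shared grid.
#' Values are stored as an `n_cells x n_dates` matrix in column-major cell
#' order (see [cell_centroids]); `NA` is the missing-data mask.
#'
#' @param grid a [grid_spec].
#' @param dates `Date` vector, one per layer, strictly increasing.
#' @param values numeric matrix, `n_cells(grid)` rows, `length(dates)`
#'   columns; entries in `[-1, 1]` or `NA`.
#' @param period optional length-2 `Date` (or parseable) vector; when
#'   given, all layer dates must fall inside it.
#' @param validate check every value lies in `[-1, 1]` (default). The
#'   synthetic generator skips the scan because its output is clipped by
#'   construction.
#' @return an object of class `acq_stack`.
#' @export
acq_stack <- function(grid, dates, values, period = NULL, validate = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable acquisition date")
  if (is.unsorted(dates, strictly = TRUE)) {
    o <- order(dates)
    if (anyDuplicated(dates)) stop("duplicate acquisition dates")
    dates <- dates[o]; values <- values[, o, drop = FALSE]
  }
  values <- as.matrix(values)
  if (nrow(values) != n_cells(grid) || ncol(values) != length(dates))
    stop("values must be an n_cells x n_dates matrix")
  if (validate) {
    rng <- suppressWarnings(range(values, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9))
      stop("NDVI values outside [-1, 1]")
  }
  if (!is.null(period)) {
    period <- as.Date(period)
    if (any(dates < period[1] | dates > period[2]))
      stop("acquisition dates fall outside the configured study period")
  }
  structure(list(grid = grid, dates = dates, values = values),
            class = "acq_stack")
}

#' @export
print.acq_stack <- function(x, ...) {
  cat(sprintf("<acq_stack> %s, %d layers (%s .. %s), %.1f%% missing\n",
              format(x$grid), length(x$dates), min(x$dates), max(x$dates),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Monthly per-pixel series
#'
#' A per-pixel series on a contiguous calendar-month index (no gaps in the
#' index; gaps in the data are `NA`).
#'
#' @param grid a [grid_spec].
#' @param year,month integer vectors of equal length defining the month
#'   index; must be contiguous in calendar order.
#' @param values numeric matrix, `n_cells(grid)` x `length(year)`.
#' @return an object of class `monthly_series`.
#' @export
monthly_series <- function(grid, year, month, values) {
  stopifnot(inherits(grid, "grid_spec"))
  year <- as.integer(year); month <- as.integer(month)
  stopifnot(length(year) == length(month), all(month >= 1 & month <= 12))
  ym <- year * 12L + (month - 1L)
  if (length(ym) > 1 && !all(diff(ym) == 1L))
    stop("month index must be contiguous calendar months")
  values <- as.matrix(values)
  if (nrow(values) != n_cells(grid) || ncol(values) != length(ym))
    stop("values must be an n_cells x n_months matrix")
  structure(list(grid = grid, year = year, month = month, values = values),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x$year)
  cat(sprintf("<monthly_series> %s, %d months (%d-%02d .. %d-%02d), %.1f%% missing\n",
              format(x$grid), n, x$year[1], x$month[1], x$year[n], x$month[n],
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Grove polygon set
#'
#' Grove (tree-planting plot) polygons in the shared projected CRS. Each
#' polygon is a list of rings (first ring the shell, later rings holes),
#' each ring an `n x 2` coordinate matrix in metres.
#'
#' @param polygons list of polygons.
#' @param ids unique character ids, one per polygon.
#' @param crs_id CRS identifier the coordinates are expressed in.
#' @return an object of class `grove_set` with per-polygon `area_ha`.
#' @export
grove_set <- function(polygons, ids = NULL, crs_id = "EPSG:32637") {
  if (is.null(ids)) ids <- as.character(seq_along(polygons))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate grove ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) != length(polygons)) stop("one id per polygon required")
  check_projected_crs(crs_id)
  area_ha <- vapply(polygons, polygon_area, numeric(1)) / 1e4
  structure(list(polygons = polygons, ids = ids, area_ha = area_ha,
                 crs_id = as.character(crs_id)),
            class = "grove_set")
}

#' @export
print.grove_set <- function(x, ...) {
  cat(sprintf("<grove_set> %d polygons, median area %.3f ha, CRS %s\n",
              length(x$polygons),
              if (length(x$area_ha)) stats::median(x$area_ha) else NA_real_,
              x$crs_id))
  invisible(x)
}

#' @export
length.grove_set <- function(x) length(x$polygons)

#' Study-area and agricultural masks
#'
#' @param grid a [grid_spec].
#' @param agricultural,study_area logical matrices (`n_rows x n_cols`) or
#'   vectors of length `n_cells(grid)`. Every agricultural cell must lie in
#'   the study area.
#' @return an object of class `study_mask`.
#' @export
study_mask <- function(grid, agricultural, study_area) {
  agricultural <- as.logical(agricultural); study_area <- as.logical(study_area)
  stopifnot(length(agricultural) == n_cells(grid),
            length(study_area) == n_cells(grid))
  agricultural[is.na(agricultural)] <- FALSE
  study_area[is.na(study_area)] <- FALSE
  if (any(agricultural & !study_area))
    stop("agricultural mask must be a subset of the study area")
  structure(list(grid = grid, agricultural = agricultural, study_area = study_area),
            class = "study_mask")
}

#' @export
print.study_mask <- function(x, ...) {
  cat(sprintf("<study_mask> %s: %d study-area cells, %d agricultural\n",
              format(x$grid), sum(x$study_area), sum(x$agricultural)))
  invisible(x)
}
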