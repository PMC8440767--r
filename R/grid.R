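#' Define a raster grid
#'
#' A `grid_spec` fixes the georeferencing every other object in the package
#' shares: a projected, metre-unit CRS, the coordinate of the grid's
#' upper-left corner, the pixel size, and the raster dimensions. The
#' centroid of cell (r, c) (1-based) is
#' `(origin_x + (c - 0.5) * pixel_size, origin_y - (r - 0.5) * pixel_size)`.
#'
#' Geographic (degree-unit) reference systems are rejected: every buffer and
#' ring distance in the analysis is metric, so all inputs must share one
#' projected CRS. The package never resamples rasters and never reprojects;
#' reproject upstream if needed.
#'
#' @param n_rows,n_cols raster dimensions.
#' @param origin_x,origin_y coordinates of the upper-left raster corner, in
#'   metres in the projected CRS.
#' @param pixel_size cell edge length in metres (default 30, the Landsat
#'   pixel).
#' @param crs_id character identifier of the projected CRS, e.g.
#'   `"EPSG:32637"`. Purely declarative: it is carried through and compared
#'   for equality, never interpreted beyond a geographic-CRS sanity check.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = n_rows * pixel_size,
                      pixel_size = 30, crs_id = "EPSG:32637") {
  stopifnot(n_rows >= 1, n_cols >= 1, is.finite(origin_x), is.finite(origin_y))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (metres)")
  check_projected_crs(crs_id)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
                 pixel_size = as.numeric(pixel_size), crs_id = as.character(crs_id)),
            class = "grid_spec")
}

# crude but explicit: reject the common geographic identifiers outright
check_projected_crs <- function(crs_id) {
  geo <- c("EPSG:4326", "EPSG:4269", "EPSG:4267", "CRS:84", "OGC:CRS84")
  id <- toupper(trimws(as.character(crs_id)))
  if (id %in% geo || grepl("LONGLAT|GEOGCS|GEOGCRS", id))
    stop("CRS '", crs_id, "' looks geographic (degree units); ",
         "reproject all inputs to a shared projected metre-unit CRS first")
  invisible(TRUE)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g m, origin (%.1f, %.1f), %s\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$pixel_size)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) <= tol && abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$pixel_size - b$pixel_size) <= tol && identical(a$crs_id, b$crs_id)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grids_equal(a, b))
    stop(what, " are on different grids (dimensions, origin, pixel size or CRS differ)")
  invisible(TRUE)
}

#' Cell centroid coordinates
#'
#' Coordinates of cell centroids in the projected CRS. Cells are addressed
#' in column-major order (the native ordering of an R matrix with `n_rows`
#' rows), so cell index `i` maps to row `((i - 1) %% n_rows) + 1`, column
#' `((i - 1) %/% n_rows) + 1`.
#'
#' @param grid a [grid_spec].
#' @param cells integer cell indices (default all cells).
#' @return a two-column matrix `x`, `y` of centroid coordinates in metres.
#' @export
cell_centroids <- function(grid, cells = seq_len(n_cells(grid))) {
  r <- ((cells - 1L) %% grid$n_rows) + 1L
  c_ <- ((cells - 1L) %/% grid$n_rows) + 1L
  cbind(x = grid$origin_x + (c_ - 0.5) * grid$pixel_size,
        y = grid$origin_y - (r - 0.5) * grid$pixel_size)
}

cell_index <- function(grid, row, col) (col - 1L) * grid$n_rows + row
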