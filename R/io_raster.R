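# Raster I/O: ESRI ASCII grid (.asc), a plain-text single-band raster
# format. The CRS identifier travels in a one-line sidecar `<path>.crs`
# because the .asc header has no CRS slot. Values are written with %.17g
# so a write -> read round trip is bit-identical for doubles.

#' Write a single grid to an ESRI ASCII raster
#'
#' @param values numeric matrix (`n_rows x n_cols`, row 1 = top) or vector
#'   of length `n_cells(grid)` in column-major cell order.
#' @param grid a [grid_spec].
#' @param path output path (conventionally `.asc`). A sidecar `<path>.crs`
#'   records the CRS identifier.
#' @param nodata sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_grid <- function(values, grid, path, nodata = -9999) {
  m <- as_cell_matrix(values, grid)
  if (any(!is.na(m) & m == nodata))
    stop("nodata sentinel ", nodata, " collides with a data value")
  hdr <- c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", sprintf("%.17g", grid$origin_x)),
    paste("yllcorner", sprintf("%.17g", grid$origin_y - grid$n_rows * grid$pixel_size)),
    paste("cellsize", sprintf("%.17g", grid$pixel_size)),
    paste("NODATA_value", sprintf("%.17g", nodata))
  )
  m[is.na(m)] <- nodata
  rows <- vapply(seq_len(grid$n_rows),
                 function(r) paste(sprintf("%.17g", m[r, ]), collapse = " "),
                 character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  writeLines(grid$crs_id, paste0(path, ".crs"))
  invisible(path)
}

as_cell_matrix <- function(values, grid) {
  if (is.matrix(values)) {
    if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
      stop("values matrix does not match the grid dimensions")
    return(values)
  }
  if (length(values) != n_cells(grid))
    stop("values length does not match the grid")
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Read an ESRI ASCII raster
#'
#' @param path path to the `.asc` file. A `<path>.crs` sidecar, if present,
#'   supplies the CRS identifier; otherwise `crs_id` is used.
#' @param crs_id fallback CRS identifier.
#' @return a list with `grid` (a [grid_spec]) and `values` (an
#'   `n_rows x n_cols` matrix with `NA` where the file holds the nodata
#'   sentinel).
#' @export
read_grid <- function(path, crs_id = "EPSG:32637") {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("raster ", path, " has ", length(vals), " values, expected ", nr * nc)
  sidecar <- paste0(path, ".crs")
  if (file.exists(sidecar)) crs_id <- trimws(readLines(sidecar, n = 1))
  grid <- grid_spec(nr, nc,
                    origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + nr * hdr$cellsize,
                    pixel_size = hdr$cellsize, crs_id = crs_id)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(grid = grid, values = m)
}

#' Read a dated raster stack
#'
#' Layers are listed in a plain-text manifest, one `path,ISO-date` pair per
#' line (CSV with header `path,date`; relative paths are resolved against
#' the manifest's directory). Alternatively pass the raster paths plus a
#' `dates` vector directly.
#'
#' @param manifest path to the manifest CSV, or a character vector of
#'   raster paths (then `dates` is required).
#' @param dates acquisition dates, one per path, when `manifest` is a
#'   vector of raster paths.
#' @param period optional study period (length-2, date-parseable); layers
#'   must fall inside it.
#' @param crs_id fallback CRS identifier for rasters without a sidecar.
#' @return an [acq_stack].
#' @export
read_stack <- function(manifest, dates = NULL, period = NULL,
                       crs_id = "EPSG:32637") {
  if (length(manifest) == 1 && is.null(dates)) {
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "date") %in% names(tab)))
      stop("manifest must be a CSV with columns 'path' and 'date'")
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", tab$path), tab$path,
                    file.path(dirname(manifest), tab$path))
    dates <- tab$date
  } else {
    paths <- manifest
    if (is.null(dates) || length(dates) != length(paths))
      stop("one date per raster path is required")
  }
  if (length(paths) == 0) stop("stack has zero layers")
  parsed <- as.Date(as.character(dates), format = "%Y-%m-%d")
  if (anyNA(parsed))
    stop("unparseable date(s) in manifest: ",
         paste(dates[is.na(parsed)], collapse = ", "))
  first <- read_grid(paths[1], crs_id = crs_id)
  grid <- first$grid
  vals <- matrix(NA_real_, n_cells(grid), length(paths))
  vals[, 1] <- as.vector(first$values)
  if (length(paths) > 1) {
    for (k in 2:length(paths)) {
      g <- read_grid(paths[k], crs_id = crs_id)
      if (!grids_equal(grid, g$grid))
        stop("raster '", paths[k], "' is not on the same grid as '", paths[1], "'")
      vals[, k] <- as.vector(g$values)
    }
  }
  acq_stack(grid, parsed, vals, period = period)
}

#' Write an acquisition stack as .asc layers plus a manifest
#'
#' @param stack an [acq_stack].
#' @param dir output directory (created if needed).
#' @param prefix layer filename prefix.
#' @return the manifest path, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "ndvi") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%s.asc", prefix, format(stack$dates, "%Y%m%d"))
  for (k in seq_along(files)) {
    write_grid(stack$values[, k], stack$grid, file.path(dir, files[k]))
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(data.frame(path = files, date = format(stack$dates, "%Y-%m-%d")),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a study/agricultural mask
#'
#' Accepts either a 0/1 ESRI ASCII raster on the analysis grid or a
#' GeoJSON polygon file (rasterised by centroid containment).
#'
#' @param path `.asc` raster or `.geojson`/`.json` polygon file.
#' @param grid the analysis [grid_spec].
#' @return a logical vector of length `n_cells(grid)`.
#' @export
read_mask <- function(path, grid) {
  if (grepl("\\.asc$", path, ignore.case = TRUE)) {
    g <- read_grid(path, crs_id = grid$crs_id)
    stop_if_grid_mismatch(grid, g$grid, "mask raster and analysis grid")
    v <- as.vector(g$values)
    return(!is.na(v) & v != 0)
  }
  gs <- read_groves(path, crs_id = grid$crs_id)
  rasterize_polygons(gs, grid)
}

# centroid-containment rasterisation of a polygon set
rasterize_polygons <- function(gs, grid) {
  out <- logical(n_cells(grid))
  if (length(gs$polygons) == 0) return(out)
  for (poly in gs$polygons) {
    idx <- bbox_cells(grid, polygon_bbox(poly), pad = 0)
    if (length(idx) == 0) next
    ctr <- cell_centroids(grid, idx)
    out[idx] <- out[idx] | points_in_polygon(ctr[, 1], ctr[, 2], poly)
  }
  out
}

# cell indices whose centroids could fall within bbox (+ pad metres)
bbox_cells <- function(grid, bbox, pad = 0) {
  ps <- grid$pixel_size
  c0 <- max(1L, floor((bbox["xmin"] - pad - grid$origin_x) / ps - 0.5) + 1L)
  c1 <- min(grid$n_cols, ceiling((bbox["xmax"] + pad - grid$origin_x) / ps + 0.5))
  r0 <- max(1L, floor((grid$origin_y - bbox["ymax"] - pad) / ps - 0.5) + 1L)
  r1 <- min(grid$n_rows, ceiling((grid$origin_y - bbox["ymin"] + pad) / ps + 0.5))
  if (c1 < c0 || r1 < r0) return(integer(0))
  as.integer(outer(r0:r1, (c0:c1 - 1L) * grid$n_rows, `+`))
}
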