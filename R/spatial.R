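#' Grove pixel set
#'
#' A pixel belongs to a grove if its centroid lies within `buffer_m`
#' (default 15 m, half a pixel) of a grove polygon -- i.e. inside the
#' polygon union dilated by the buffer. The buffer pulls in boundary
#' pixels, where trees are typically planted, that a bare
#' centroid-in-polygon test would miss given small grove polygons.
#'
#' @param groves a [grove_set].
#' @param grid the analysis [grid_spec].
#' @param buffer_m dilation distance in metres (default 15).
#' @return logical vector over cells, `TRUE` for grove pixels.
#' @export
grove_pixels <- function(groves, grid, buffer_m = 15) {
  if (!identical(groves$crs_id, grid$crs_id))
    stop("grove CRS '", groves$crs_id, "' does not match grid CRS '",
         grid$crs_id, "'; reproject the vectors upstream")
  out <- logical(n_cells(grid))
  for (poly in groves$polygons) {
    idx <- bbox_cells(grid, polygon_bbox(poly), pad = buffer_m)
    if (length(idx) == 0) next
    todo <- idx[!out[idx]]
    if (length(todo) == 0) next
    ctr <- cell_centroids(grid, todo)
    out[todo] <- points_near_polygon(ctr[, 1], ctr[, 2], poly, buffer_m)
  }
  out
}

#' Successive distance rings around grove pixels
#'
#' Ring `k` contains the pixels whose centroid lies within `k * ring_width`
#' metres of the union of grove-pixel footprints (the 30 m squares, not
#' their centroids) but not within `(k - 1) * ring_width`; grove pixels are
#' excluded. Buffering footprints rather than centroids makes ring 1 the
#' 8-neighbourhood of an isolated grove pixel, which is the intent of
#' one-pixel-wide rings (a centroid buffer would drop the diagonals); the
#' centroid variant is available for sensitivity analysis.
#'
#' @param grove_set logical vector over cells (from [grove_pixels]).
#' @param grid the [grid_spec].
#' @param K number of rings (default 17, i.e. out to 510 m).
#' @param ring_width ring increment in metres (default 30).
#' @param buffer_of `"footprint"` (default) or `"centroid"`.
#' @return integer vector over cells: ring index `1..K`, `0` for grove
#'   pixels, `NA` beyond the outermost ring.
#' @export
distance_rings <- function(grove_set, grid, K = 17, ring_width = 30,
                           buffer_of = c("footprint", "centroid")) {
  buffer_of <- match.arg(buffer_of)
  if (K < 1) stop("K must be at least 1")
  d <- grove_distance(grove_set, grid, max_dist = K * ring_width,
                      buffer_of = buffer_of)
  ring <- rep(NA_integer_, length(d))
  fin <- is.finite(d)
  ring[fin] <- as.integer(ceiling(d[fin] / ring_width - 1e-9))
  ring[fin & ring > K] <- NA_integer_
  ring[grove_set] <- 0L
  ring
}

# Minimum distance from each cell centroid to the grove pixel set, exact
# Euclidean; distances beyond max_dist are Inf. "footprint" measures to the
# grove pixel's square, "centroid" to its centre point.
grove_distance <- function(grove_set, grid, max_dist, buffer_of = "footprint") {
  nr <- grid$n_rows; ncg <- grid$n_cols; ps <- grid$pixel_size
  h <- if (buffer_of == "footprint") ps / 2 else 0
  dmin <- rep(Inf, n_cells(grid))
  gcells <- which(grove_set)
  if (length(gcells) == 0) return(dmin)
  reach <- as.integer(ceiling((max_dist + h) / ps))
  off <- -reach:reach
  for (g in gcells) {
    r0 <- ((g - 1L) %% nr) + 1L
    c0 <- ((g - 1L) %/% nr) + 1L
    rr <- r0 + off; rr <- rr[rr >= 1 & rr <= nr]
    cc <- c0 + off; cc <- cc[cc >= 1 & cc <= ncg]
    ddr <- pmax(0, abs(rr - r0) * ps - h)
    ddc <- pmax(0, abs(cc - c0) * ps - h)
    blk <- sqrt(outer(ddr^2, ddc^2, `+`))
    idx <- outer(rr, (cc - 1L) * nr, `+`)
    dmin[idx] <- pmin(dmin[idx], blk)
  }
  dmin[dmin > max_dist] <- Inf
  dmin
}

#' Classify every pixel of the scene
#'
#' Label precedence: grove, then distance ring (rings are computed over
#' all study-area pixels, agricultural or not), then other-agricultural
#' (agricultural land beyond the outermost ring), else excluded. Pixels
#' outside the study area are always excluded.
#'
#' @param grove_set logical vector from [grove_pixels].
#' @param rings integer vector from [distance_rings] (same grid), or
#'   `NULL` to compute with defaults.
#' @param mask a [study_mask].
#' @param K,ring_width ring layout (used when `rings` is `NULL`, and
#'   recorded in the result).
#' @return an object of class `pixel_classes`: integer `label` codes over
#'   cells (0 excluded, 1 grove, `1 + k` for ring `k`, 255
#'   other-agricultural) plus a `code_table`.
#' @export
classify_pixels <- function(grove_set, rings = NULL, mask, K = 17,
                            ring_width = 30) {
  grid <- mask$grid
  if (length(grove_set) != n_cells(grid))
    stop("grove pixel set does not match the mask grid")
  if (is.null(rings)) rings <- distance_rings(grove_set, grid, K, ring_width)
  if (length(rings) != n_cells(grid))
    stop("ring assignment does not match the mask grid")
  label <- integer(n_cells(grid))  # 0 = excluded
  in_ring <- !is.na(rings) & rings >= 1L & mask$study_area
  label[in_ring] <- 1L + rings[in_ring]
  label[mask$agricultural & label == 0L] <- 255L
  label[grove_set & mask$study_area] <- 1L
  code_table <- data.frame(
    code = c(0L, 1L, 1L + seq_len(K), 255L),
    label = c("excluded", "grove", paste0("ring_", seq_len(K)), "other_agri"),
    stringsAsFactors = FALSE)
  structure(list(grid = grid, label = label, K = as.integer(K),
                 ring_width = ring_width, code_table = code_table),
            class = "pixel_classes")
}

#' @export
print.pixel_classes <- function(x, ...) {
  counts <- label_counts(x)
  cat(sprintf("<pixel_classes> %s, K = %d rings of %g m\n",
              format(x$grid), x$K, x$ring_width))
  print(counts)
  invisible(x)
}

label_code <- function(pc, label) {
  i <- match(label, pc$code_table$label)
  if (anyNA(i)) stop("unknown class label: ",
                     paste(label[is.na(i)], collapse = ", "))
  pc$code_table$code[i]
}

#' Cells carrying a given class label
#'
#' @param pc a [pixel_classes].
#' @param label a label from the code table (`"grove"`, `"ring_3"`,
#'   `"other_agri"`, `"excluded"`).
#' @return integer cell indices.
#' @export
label_cells <- function(pc, label) which(pc$label == label_code(pc, label))

label_counts <- function(pc) {
  n <- vapply(pc$code_table$code, function(cd) sum(pc$label == cd), integer(1))
  stats::setNames(n, pc$code_table$label)
}

#' Area of a class, in hectares
#'
#' Pixel count times the pixel area, in hectares.
#'
#' @param pc a [pixel_classes].
#' @param label class label.
#' @return hectares.
#' @export
area_ha <- function(pc, label) {
  sum(pc$label == label_code(pc, label)) * pc$grid$pixel_size^2 / 1e4
}
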