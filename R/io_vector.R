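# Vector I/O: GeoJSON, parsed with jsonlite. Coordinates must already be
# in the shared projected metre CRS (the package has no reprojection
# engine); a GeoJSON "crs" member, when present, is compared against the
# expected identifier and a mismatch is a hard error telling the caller to
# reproject upstream.

#' Read grove polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features (a bare
#' geometry or single Feature also works). Feature ids are taken from the
#' feature `id`, then `properties$id`, else the 1-based feature index;
#' duplicates are an error. Self-intersecting rings (e.g. GPS bow-ties)
#' are repaired by splitting them into their simple loops, with a warning.
#'
#' @param path GeoJSON file.
#' @param crs_id the projected CRS the coordinates are expected in.
#' @return a [grove_set].
#' @export
read_groves <- function(path, crs_id = "EPSG:32637") {
  if (!file.exists(path)) stop("no such vector file: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_geojson_crs(js, crs_id)
  feats <- switch(js$type %||% "",
    FeatureCollection = js$features,
    Feature = list(js),
    Polygon = ,
    MultiPolygon = list(list(geometry = js, properties = list())),
    stop("unsupported GeoJSON type: ", js$type %||% "<missing>")
  )
  polygons <- list(); ids <- character(0)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    geom <- f$geometry
    if (is.null(geom) || !(geom$type %in% c("Polygon", "MultiPolygon")))
      stop("feature ", k, " is not a polygon (got ",
           geom$type %||% "no geometry", ")")
    rings <- if (geom$type == "Polygon") {
      lapply(geom$coordinates, coord_ring)
    } else {
      unlist(lapply(geom$coordinates, function(part) lapply(part, coord_ring)),
             recursive = FALSE)
    }
    if (!polygon_is_valid(rings)) {
      warning("feature ", k, ": self-intersecting ring repaired", call. = FALSE)
      rings <- repair_polygon(rings)
    }
    id <- f$id %||% f$properties$id %||% as.character(k)
    polygons[[length(polygons) + 1]] <- rings
    ids <- c(ids, as.character(id))
  }
  grove_set(polygons, ids, crs_id = crs_id)
}

coord_ring <- function(ring) {
  m <- matrix(unlist(lapply(ring, function(p) c(p[[1]], p[[2]]))),
              ncol = 2, byrow = TRUE)
  ring_open(m)
}

check_geojson_crs <- function(js, crs_id) {
  nm <- js$crs$properties$name
  if (is.null(nm)) return(invisible(TRUE))
  norm <- function(s) {
    s <- toupper(s)
    s <- sub("^URN:OGC:DEF:CRS:EPSG:[0-9.]*:", "EPSG:", s)
    s
  }
  if (norm(nm) != norm(crs_id))
    stop("GeoJSON CRS '", nm, "' does not match the analysis CRS '", crs_id,
         "'; reproject the vectors upstream")
  check_projected_crs(norm(nm))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write grove polygons to GeoJSON
#'
#' @param groves a [grove_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_groves <- function(groves, path) {
  features <- lapply(seq_along(groves$polygons), function(k) {
    rings <- lapply(groves$polygons[[k]], function(r) {
      r <- ring_close(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature", id = groves$ids[k],
         properties = list(area_ha = groves$area_ha[k]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = groves$crs_id)),
             features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
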