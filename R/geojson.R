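# GeoJSON (RFC 7946) polygon layers via jsonlite.

geojson_ring_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(pt) c(pt[[1L]], pt[[2L]])))
}

#' Read a polygon layer from GeoJSON
#'
#' Accepts a FeatureCollection (or a single Feature) of Polygon /
#' MultiPolygon geometries. The tract identifier is taken from the
#' `id_property` member of each feature's properties, falling back to the
#' feature-level `id`.
#'
#' @param path path to a `.geojson` / `.json` file.
#' @param id_property property name holding the identifier (default
#'   `"GEOID"`, the census convention).
#' @return named list of `gi_geom` objects.
#' @export
read_geojson <- function(path, id_property = "GEOID") {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(j$type %||% "",
                  FeatureCollection = j$features,
                  Feature = list(j),
                  stop("not a GeoJSON Feature or FeatureCollection: ", path))
  if (!length(feats)) stop("GeoJSON file contains no features: ", path)
  out <- vector("list", length(feats))
  ids <- character(length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_property]] %||% f$id
    if (is.null(id)) stop("feature ", i, " in ", path, " has no '", id_property, "' identifier")
    ids[i] <- as.character(id)
    g <- f$geometry
    out[[i]] <- switch(g$type %||% "",
      Polygon = gi_multipolygon(list(lapply(g$coordinates, geojson_ring_matrix))),
      MultiPolygon = gi_multipolygon(lapply(g$coordinates, function(part)
        lapply(part, geojson_ring_matrix))),
      stop("feature ", ids[i], ": unsupported geometry type '", g$type, "'"))
  }
  names(out) <- ids
  validate_polygon_set(out)
  out
}

#' Write a polygon layer to GeoJSON
#'
#' @param polygons named list of `gi_geom` objects.
#' @param path output path.
#' @param id_property property name to store the identifier under.
#' @export
write_geojson <- function(polygons, path, id_property = "GEOID") {
  validate_polygon_set(polygons)
  feats <- lapply(names(polygons), function(id) {
    parts <- lapply(polygons[[id]]$parts, function(part)
      lapply(part, function(ring) lapply(seq_len(nrow(ring)), function(i)
        c(ring[i, 1L], ring[i, 2L]))))
    geom <- if (length(parts) == 1L) {
      list(type = "Polygon", coordinates = parts[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = parts)
    }
    list(type = "Feature",
         properties = stats::setNames(list(id), id_property),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
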