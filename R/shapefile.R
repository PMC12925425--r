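# Minimal ESRI Shapefile support (shape type 5, Polygon).
#
# No pre-installed package reads shapefiles in this stack, and the format
# is simple enough for the polygon subset this package needs: the .shp
# geometry file, its .shx offset index and a dBase III .dbf attribute
# table carrying one character identifier column. Z/M shapes, null
# shapes and non-character attributes are out of scope.

shp_base <- function(path) sub("\\.(shp|shx|dbf)$", "", path, ignore.case = TRUE)

# orientation convention: outer rings clockwise (negative shoelace area),
# holes counter-clockwise
orient_ring <- function(ring, clockwise) {
  a <- ring_area(ring)
  if ((clockwise && a > 0) || (!clockwise && a < 0)) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Write a polygon layer as an ESRI Shapefile
#'
#' Produces `<base>.shp`, `<base>.shx` and `<base>.dbf` with a single
#' character attribute column holding the identifier.
#'
#' @param polygons named list of `gi_geom` objects.
#' @param path output path (with or without the `.shp` extension).
#' @param id_field attribute column name (at most 10 characters).
#' @export
write_shapefile <- function(polygons, path, id_field = "GEOID") {
  validate_polygon_set(polygons)
  if (nchar(id_field) > 10L) stop("dBase field names are limited to 10 characters")
  base <- shp_base(path)
  ids <- names(polygons)

  records <- lapply(polygons, function(g) {
    rings <- unlist(lapply(g$parts, function(part) {
      c(list(orient_ring(part[[1L]], clockwise = TRUE)),
        lapply(part[-1L], orient_ring, clockwise = FALSE))
    }), recursive = FALSE)
    npts <- vapply(rings, nrow, 0L)
    pts <- do.call(rbind, rings)
    list(parts = cumsum(c(0L, npts[-length(npts)])), points = pts,
         bbox = c(min(pts[, 1L]), min(pts[, 2L]), max(pts[, 1L]), max(pts[, 2L])))
  })
  content_words <- vapply(records, function(r)
    (4L + 32L + 8L + 4L * length(r$parts) + 16L * nrow(r$points)) %/% 2L, 0L)
  gbox <- c(min(vapply(records, function(r) r$bbox[1L], 0)),
            min(vapply(records, function(r) r$bbox[2L], 0)),
            max(vapply(records, function(r) r$bbox[3L], 0)),
            max(vapply(records, function(r) r$bbox[4L], 0)))

  write_header <- function(con, file_words) {
    writeBin(9994L, con, size = 4L, endian = "big")
    writeBin(integer(5L), con, size = 4L, endian = "big")
    writeBin(as.integer(file_words), con, size = 4L, endian = "big")
    writeBin(1000L, con, size = 4L, endian = "little")
    writeBin(5L, con, size = 4L, endian = "little")
    writeBin(c(gbox, 0, 0, 0, 0), con, size = 8L, endian = "little")
  }

  shp <- file(paste0(base, ".shp"), "wb")
  on.exit(close(shp), add = TRUE)
  write_header(shp, 50L + sum(content_words + 4L))
  for (i in seq_along(records)) {
    r <- records[[i]]
    writeBin(i, shp, size = 4L, endian = "big")
    writeBin(content_words[i], shp, size = 4L, endian = "big")
    writeBin(5L, shp, size = 4L, endian = "little")
    writeBin(r$bbox, shp, size = 8L, endian = "little")
    writeBin(length(r$parts), shp, size = 4L, endian = "little")
    writeBin(nrow(r$points), shp, size = 4L, endian = "little")
    writeBin(as.integer(r$parts), shp, size = 4L, endian = "little")
    writeBin(as.vector(t(r$points)), shp, size = 8L, endian = "little")
  }

  shx <- file(paste0(base, ".shx"), "wb")
  on.exit(close(shx), add = TRUE)
  write_header(shx, 50L + 4L * length(records))
  offset <- 50L
  for (i in seq_along(records)) {
    writeBin(offset, shx, size = 4L, endian = "big")
    writeBin(content_words[i], shx, size = 4L, endian = "big")
    offset <- offset + 4L + content_words[i]
  }

  flen <- max(1L, min(254L, max(nchar(ids))))
  dbf <- file(paste0(base, ".dbf"), "wb")
  on.exit(close(dbf), add = TRUE)
  writeBin(as.raw(c(0x03, 126L, 1L, 1L)), dbf)
  writeBin(length(ids), dbf, size = 4L, endian = "little")
  writeBin(c(32L + 32L + 1L, 1L + flen), dbf, size = 2L, endian = "little")
  writeBin(raw(20L), dbf)
  nm <- charToRaw(id_field)
  writeBin(c(nm, raw(11L - length(nm))), dbf)
  writeBin(charToRaw("C"), dbf)
  writeBin(raw(4L), dbf)
  writeBin(as.raw(c(flen, 0L)), dbf)
  writeBin(raw(14L), dbf)
  writeBin(as.raw(0x0D), dbf)
  for (id in ids) {
    writeBin(charToRaw(" "), dbf)
    writeBin(charToRaw(formatC(id, width = -flen)), dbf)
  }
  writeBin(as.raw(0x1A), dbf)
  invisible(paste0(base, ".shp"))
}

read_dbf_ids <- function(path, id_field) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 4L)
  nrec <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hsize <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  rsize <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 20L)
  nfields <- (hsize - 33L) %/% 32L
  fields <- vector("list", nfields)
  for (i in seq_len(nfields)) {
    d <- readBin(con, "raw", 32L)
    nb <- d[1:11]
    z <- which(nb == as.raw(0L))
    nm <- rawToChar(if (length(z)) nb[seq_len(z[1L] - 1L)] else nb)
    fields[[i]] <- list(name = nm, len = as.integer(d[17L]))
  }
  readBin(con, "raw", 1L)  # 0x0D terminator
  want <- which(vapply(fields, `[[`, "", "name") == id_field)
  if (!length(want)) stop("attribute table ", path, " has no '", id_field, "' column")
  pre <- if (want > 1L) sum(vapply(fields[seq_len(want - 1L)], `[[`, 0L, "len")) else 0L
  flen <- fields[[want]]$len
  ids <- character(nrec)
  for (i in seq_len(nrec)) {
    rec <- readBin(con, "raw", rsize)
    ids[i] <- trimws(rawToChar(rec[(2L + pre):(1L + pre + flen)]))
  }
  ids
}

#' Read a polygon layer from an ESRI Shapefile
#'
#' Reads shape type 5 (Polygon) records from `<base>.shp` and identifiers
#' from the `id_field` column of `<base>.dbf`. Clockwise rings open a new
#' polygon part, counter-clockwise rings become holes of the preceding
#' part, per the shapefile orientation convention.
#'
#' @param path path to the `.shp` file (extension optional).
#' @param id_field attribute column holding the identifier.
#' @return named list of `gi_geom` objects.
#' @export
read_shapefile <- function(path, id_field = "GEOID") {
  base <- shp_base(path)
  ids <- read_dbf_ids(paste0(base, ".dbf"), id_field)
  con <- file(paste0(base, ".shp"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (!identical(magic, 9994L)) stop("not a shapefile: ", base, ".shp")
  readBin(con, "raw", 96L)  # rest of the 100-byte header
  out <- list()
  repeat {
    recno <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (!length(recno)) break
    readBin(con, "integer", 1L, size = 4L, endian = "big")
    type <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (type != 5L) stop("unsupported shape type ", type, " in record ", recno)
    readBin(con, "double", 4L, size = 8L, endian = "little")
    nparts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    starts <- readBin(con, "integer", nparts, size = 4L, endian = "little")
    xy <- matrix(readBin(con, "double", 2L * npts, size = 8L, endian = "little"),
                 ncol = 2L, byrow = TRUE)
    ends <- c(starts[-1L], npts)
    parts <- list()
    for (p in seq_len(nparts)) {
      ring <- xy[(starts[p] + 1L):ends[p], , drop = FALSE]
      if (ring_area(ring) <= 0 || !length(parts)) {
        parts[[length(parts) + 1L]] <- list(ring)   # clockwise: new outer
      } else {
        cur <- parts[[length(parts)]]
        parts[[length(parts)]] <- c(cur, list(ring))  # hole of previous outer
      }
    }
    out[[length(out) + 1L]] <- gi_multipolygon(parts)
  }
  if (length(out) != length(ids))
    stop("record count mismatch between .shp (", length(out), ") and .dbf (",
         length(ids), ") for ", base)
  names(out) <- ids
  validate_polygon_set(out)
  out
}

#' Read a polygon layer, dispatching on file extension
#'
#' `.geojson`/`.json` files go through [read_geojson()], `.shp` (or an
#' extensionless base with a `.shp` sibling) through [read_shapefile()].
#'
#' @param path input path.
#' @param id_property identifier property/column name.
#' @return named list of `gi_geom` objects.
#' @export
read_geometry <- function(path, id_property = "GEOID") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json"))
    return(read_geojson(path, id_property))
  if (ext == "shp" || file.exists(paste0(shp_base(path), ".shp")))
    return(read_shapefile(path, id_property))
  stop("cannot determine geometry format of ", path,
       " (expected .geojson/.json or .shp)")
}
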