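# Planar polygon primitives.
#
# A geometry (`gi_geom`) is a list of "parts"; each part is a list of ring
# matrices (2 columns, closed: first row == last row), the first ring being
# the outer boundary and any further rings holes. This mirrors the GeoJSON
# Polygon/MultiPolygon nesting. All coordinates are planar (projected or
# small-extent lon/lat); no great-circle support.

as_ring <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 2L) stop("a ring must be a 2-column numeric matrix")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

close_ring <- function(m) {
  m <- as_ring(m)
  if (nrow(m) < 3L) stop("a ring needs at least 3 distinct vertices")
  if (!isTRUE(all(m[1L, ] == m[nrow(m), ]))) m <- rbind(m, m[1L, ])
  m
}

#' Construct a polygon geometry
#'
#' @param outer outer ring: 2-column coordinate matrix (closed or open;
#'   an open ring is closed automatically).
#' @param holes optional list of hole rings.
#' @return a `gi_geom` object with one part.
#' @export
gi_polygon <- function(outer, holes = list()) {
  part <- c(list(close_ring(outer)), lapply(holes, close_ring))
  structure(list(parts = list(part)), class = "gi_geom")
}

#' Construct a multi-part polygon geometry
#'
#' @param parts list of parts; each part is a list of rings (outer first)
#'   or a bare matrix (taken as an outer ring with no holes).
#' @return a `gi_geom` object.
#' @export
gi_multipolygon <- function(parts) {
  parts <- lapply(parts, function(p) {
    if (is.matrix(p) || is.data.frame(p)) p <- list(p)
    lapply(p, close_ring)
  })
  structure(list(parts = parts), class = "gi_geom")
}

#' @export
print.gi_geom <- function(x, ...) {
  np <- length(x$parts)
  nv <- sum(vapply(x$parts, function(p) sum(vapply(p, nrow, 0L)) - length(p), 0L))
  cat(sprintf("<gi_geom: %d part(s), %d vertices>\n", np, nv))
  invisible(x)
}

ring_area <- function(ring) {
  # signed shoelace area; positive for counter-clockwise rings
  x <- ring[, 1L]; y <- ring[, 2L]; n <- nrow(ring)
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

geom_rings <- function(g) unlist(g$parts, recursive = FALSE)

geom_vertices <- function(g) {
  do.call(rbind, lapply(geom_rings(g), function(r) r[-nrow(r), , drop = FALSE]))
}

geom_bbox <- function(g) {
  v <- geom_vertices(g)
  c(xmin = min(v[, 1L]), ymin = min(v[, 2L]),
    xmax = max(v[, 1L]), ymax = max(v[, 2L]))
}

# all boundary edges as a matrix [x1 y1 x2 y2]; zero-length edges dropped
geom_edges <- function(g) {
  e <- do.call(rbind, lapply(geom_rings(g), function(r) {
    n <- nrow(r)
    cbind(r[-n, , drop = FALSE], r[-1L, , drop = FALSE])
  }))
  keep <- (e[, 1L] != e[, 3L]) | (e[, 2L] != e[, 4L])
  e[keep, , drop = FALSE]
}

validate_geom <- function(g, id = "<geometry>") {
  if (!inherits(g, "gi_geom") || length(g$parts) == 0L)
    stop("invalid or empty geometry for id ", id)
  for (part in g$parts) {
    for (ring in part) {
      if (nrow(ring) < 4L || !all(is.finite(ring)))
        stop("invalid or empty geometry for id ", id)
      if (!all(ring[1L, ] == ring[nrow(ring), ]))
        stop("unclosed ring in geometry for id ", id)
    }
    if (abs(ring_area(part[[1L]])) <= 0)
      stop("degenerate (zero-area) geometry for id ", id)
  }
  invisible(TRUE)
}

validate_polygon_set <- function(polygons) {
  ids <- names(polygons)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("polygons must be a named list (names are tract identifiers)")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate polygon id(s): ", paste(dup, collapse = ", "))
  for (i in seq_along(polygons)) validate_geom(polygons[[i]], ids[i])
  invisible(TRUE)
}

# crossing count of a rightward ray from pt against one ring
ring_crossings <- function(pt, ring) {
  n <- nrow(ring) - 1L
  x1 <- ring[1:n, 1L]; y1 <- ring[1:n, 2L]
  x2 <- ring[2:(n + 1L), 1L]; y2 <- ring[2:(n + 1L), 2L]
  straddle <- (y1 > pt[2L]) != (y2 > pt[2L])
  if (!any(straddle)) return(0L)
  xi <- x1[straddle] + (pt[2L] - y1[straddle]) *
    (x2[straddle] - x1[straddle]) / (y2[straddle] - y1[straddle])
  sum(xi > pt[1L])
}

point_in_part <- function(pt, part) {
  # even-odd rule over outer ring and holes
  (sum(vapply(part, function(r) ring_crossings(pt, r), 0L)) %% 2L) == 1L
}

#' Test whether a point lies inside a polygon geometry
#'
#' Even-odd ray casting over each part's rings (holes are excluded
#' automatically). Points exactly on the boundary are not guaranteed a
#' stable answer; use [representative_point()] to obtain strictly interior
#' probes.
#'
#' @param pt length-2 numeric vector `c(x, y)`.
#' @param g a `gi_geom`.
#' @return logical scalar.
#' @export
point_in_geom <- function(pt, g) {
  any(vapply(g$parts, function(p) point_in_part(pt, p), TRUE))
}

#' Deterministic interior point of a polygon
#'
#' Returns a point guaranteed to lie strictly inside the largest part of
#' the geometry (holes respected). The construction scans a horizontal
#' line placed between two distinct vertex y-levels near the vertical
#' midpoint of the part, intersects it with the boundary, and takes the
#' midpoint of the widest interior interval. Unlike the centroid, the
#' result is always inside, even for concave polygons; unlike random
#' sampling, it is deterministic.
#'
#' @param g a `gi_geom`.
#' @return length-2 numeric vector `c(x, y)`.
#' @export
representative_point <- function(g) {
  areas <- vapply(g$parts, function(p) abs(ring_area(p[[1L]])), 0)
  part <- g$parts[[which.max(areas)]]
  vy <- sort(unique(unlist(lapply(part, function(r) r[, 2L]))))
  if (length(vy) < 2L) stop("degenerate geometry: all vertices at one y")
  mid <- (vy[1L] + vy[length(vy)]) / 2
  # choose the inter-vertex y-interval containing (or nearest to) the
  # midline, then probe at its centre so no vertex lies on the scanline
  k <- findInterval(mid, vy, all.inside = TRUE)
  ystar <- (vy[k] + vy[k + 1L]) / 2
  xs <- unlist(lapply(part, function(r) {
    n <- nrow(r) - 1L
    x1 <- r[1:n, 1L]; y1 <- r[1:n, 2L]
    x2 <- r[2:(n + 1L), 1L]; y2 <- r[2:(n + 1L), 2L]
    st <- (y1 > ystar) != (y2 > ystar)
    x1[st] + (ystar - y1[st]) * (x2[st] - x1[st]) / (y2[st] - y1[st])
  }))
  xs <- sort(xs)
  if (length(xs) < 2L || length(xs) %% 2L != 0L)
    stop("failed to locate an interior interval (invalid geometry?)")
  lo <- xs[seq(1L, length(xs), by = 2L)]
  hi <- xs[seq(2L, length(xs), by = 2L)]
  w <- which.max(hi - lo)
  c((lo[w] + hi[w]) / 2, ystar)
}
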