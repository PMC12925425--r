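# Queen/rook contiguity from polygon boundaries.
#
# Queen neighbors share at least one boundary point (an edge or a corner
# vertex); rook neighbors must share a boundary segment of positive
# length (a common edge). Contact is detected geometrically: shared
# (snapped) vertices, collinear edge overlap, and vertex-on-edge
# T-junctions all count as boundary contact, so lattices whose shared
# edges are subdivided differently on either side are still linked.

# total collinear overlap length between two edge sets [x1 y1 x2 y2]
edge_overlap_length <- function(EA, EB, eps) {
  m1 <- nrow(EA); m2 <- nrow(EB)
  ia <- rep.int(seq_len(m1), m2)
  ib <- rep(seq_len(m2), each = m1)
  p1x <- EA[ia, 1L]; p1y <- EA[ia, 2L]
  d1x <- EA[ia, 3L] - p1x; d1y <- EA[ia, 4L] - p1y
  len1 <- sqrt(d1x^2 + d1y^2)
  q1x <- EB[ib, 1L]; q1y <- EB[ib, 2L]
  q2x <- EB[ib, 3L]; q2y <- EB[ib, 4L]
  c1 <- d1x * (q1y - p1y) - d1y * (q1x - p1x)
  c2 <- d1x * (q2y - p1y) - d1y * (q2x - p1x)
  col <- abs(c1) <= eps * len1 & abs(c2) <= eps * len1
  if (!any(col)) return(0)
  t1 <- ((q1x - p1x) * d1x + (q1y - p1y) * d1y)[col] / len1[col]
  t2 <- ((q2x - p1x) * d1x + (q2y - p1y) * d1y)[col] / len1[col]
  lo <- pmax(pmin(t1, t2), 0)
  hi <- pmin(pmax(t1, t2), len1[col])
  sum(pmax(0, hi - lo))
}

# does any vertex in V lie on an edge of E (within dist)?
any_vertex_on_edge <- function(V, E, dist) {
  m1 <- nrow(V); m2 <- nrow(E)
  iv <- rep.int(seq_len(m1), m2)
  ie <- rep(seq_len(m2), each = m1)
  px <- V[iv, 1L]; py <- V[iv, 2L]
  ax <- E[ie, 1L]; ay <- E[ie, 2L]
  dx <- E[ie, 3L] - ax; dy <- E[ie, 4L] - ay
  len2 <- dx^2 + dy^2
  t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
  d2 <- (ax + t * dx - px)^2 + (ay + t * dy - py)^2
  any(d2 <= dist^2)
}

snap_geom <- function(g, tol) {
  if (tol <= 0) return(g)
  g$parts <- lapply(g$parts, function(p) lapply(p, function(r) round(r / tol) * tol))
  g
}

vertex_keys <- function(V) paste(sprintf("%.17g", V[, 1L]), sprintf("%.17g", V[, 2L]))

#' Build a queen or rook contiguity graph from polygons
#'
#' Two polygons are queen neighbors if their boundaries share at least one
#' point (after snapping coordinates to `snap_tolerance`); they are rook
#' neighbors only if their shared boundary has total length strictly
#' greater than `snap_tolerance` (with the default tolerance of 0, any
#' positive-length common edge counts, corner-only contacts never do).
#' Candidate pairs are pre-filtered by bounding-box overlap, so the cost
#' is near-linear on tract-like data.
#'
#' @param polygons named list of `gi_geom` objects; names are the tract
#'   identifiers. Geometries must be valid planar polygons in a shared
#'   coordinate system.
#' @param mode `"queen"` or `"rook"`.
#' @param snap_tolerance coordinates within this distance are treated as
#'   coincident before adjacency testing (default 0: exact coordinates).
#'   Real shapefiles carry sliver gaps; synthetic fixtures do not.
#' @return a `neighbor_graph`: list with `mode`, `snap_tolerance`, and
#'   `neighbors`, a named list mapping each id to the sorted character
#'   vector of its neighbors (self excluded). The relation is symmetric
#'   and irreflexive by construction.
#' @seealso [row_standardize_with_self()]
#' @examples
#' lat <- make_lattice(3, 3)
#' g <- build_neighbor_graph(lat$polygons, "queen")
#' lengths(g$neighbors)  # 8 for the interior cell, 5 edges, 3 corners
#' @export
build_neighbor_graph <- function(polygons, mode = c("queen", "rook"),
                                 snap_tolerance = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(snap_tolerance) || snap_tolerance < 0)
    stop("snap_tolerance must be a non-negative number")
  validate_polygon_set(polygons)
  ids <- names(polygons)
  n <- length(ids)
  polygons <- lapply(polygons, snap_geom, tol = snap_tolerance)

  V <- lapply(polygons, geom_vertices)
  E <- lapply(polygons, geom_edges)
  K <- lapply(V, vertex_keys)
  bb <- t(vapply(polygons, geom_bbox, numeric(4L)))
  scale <- max(1, abs(bb))
  eps <- 1e-9 * scale
  touch <- max(snap_tolerance, eps)

  nb <- rep(list(character(0L)), n)
  names(nb) <- ids
  if (n > 1L) {
    ord <- order(bb[, "xmin"])
    active <- integer(0L)
    for (oi in ord) {
      active <- active[bb[active, "xmax"] >= bb[oi, "xmin"] - touch]
      for (oj in active) {
        if (bb[oj, "ymin"] > bb[oi, "ymax"] + touch ||
            bb[oj, "ymax"] < bb[oi, "ymin"] - touch) next
        shared_vertex <- any(K[[oi]] %in% K[[oj]])
        linked <-
          if (mode == "rook") {
            edge_overlap_length(E[[oi]], E[[oj]], eps) > snap_tolerance
          } else {
            shared_vertex ||
              edge_overlap_length(E[[oi]], E[[oj]], eps) > 0 ||
              any_vertex_on_edge(V[[oi]], E[[oj]], touch) ||
              any_vertex_on_edge(V[[oj]], E[[oi]], touch)
          }
        if (linked) {
          nb[[oi]] <- c(nb[[oi]], ids[oj])
          nb[[oj]] <- c(nb[[oj]], ids[oi])
        }
      }
      active <- c(active, oi)
    }
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  structure(list(mode = mode, snap_tolerance = snap_tolerance, neighbors = nb),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  k <- lengths(x$neighbors)
  cat(sprintf("<neighbor_graph: %s contiguity, %d polygons, mean %.2f neighbors, %d island(s)>\n",
              x$mode, length(k), if (length(k)) mean(k) else 0, sum(k == 0L)))
  invisible(x)
}

#' Self-included, row-standardized spatial weights
#'
#' Converts a contiguity graph into one weights row per tract. Each tract
#' counts itself as a neighbor ("self-inclusion"), every linked tract gets
#' weight 1, and the row is divided by its sum, so a tract with k
#' neighbors carries k+1 equal weights of 1/(k+1). An island tract (no
#' neighbors) gets the single weight {self: 1}.
#'
#' @param graph a `neighbor_graph` from [build_neighbor_graph()].
#' @return named list of `weights_row` objects, each with fields `focal`,
#'   `weights` (named numeric, self included), `W` (row sum, always 1),
#'   `S1` (sum of squared weights, 1/(k+1)) and `n_neigh` (k, self
#'   excluded).
#' @export
row_standardize_with_self <- function(graph) {
  if (!inherits(graph, "neighbor_graph")) stop("graph must be a neighbor_graph")
  ids <- names(graph$neighbors)
  out <- lapply(ids, function(i) {
    nbr <- graph$neighbors[[i]]
    k <- length(nbr)
    w <- rep.int(1 / (k + 1), k + 1L)
    names(w) <- c(i, nbr)
    structure(list(focal = i, weights = w, W = sum(w), S1 = sum(w^2),
                   n_neigh = k),
              class = "weights_row")
  })
  names(out) <- ids
  out
}
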