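# Assignment of tracts to their larger reference unit.

#' Assign each tract a larger areal unit (CBSA or county)
#'
#' A tract belongs to the core-based statistical area (CBSA) whose polygon
#' contains the tract's deterministic representative interior point; a
#' tract inside no CBSA polygon falls back to the county spelled by the
#' first five digits of its FIPS identifier. The county fallback is purely
#' lexical: it never consults geometry. With no CBSA layer at all, every
#' tract is assigned its county.
#'
#' The point-in-polygon rule (rather than full polygon containment) is
#' deliberate: real tract boundaries follow CBSA boundaries imperfectly,
#' and an interior-point spatial join is robust to such slivers.
#'
#' @param tracts named list of `gi_geom` polygons; names are tract FIPS
#'   identifiers (10 or 11 digits; canonicalized internally).
#' @param cbsa_polygons optional named list of `gi_geom` polygons keyed by
#'   CBSA code. Must be mutually non-overlapping: a representative point
#'   falling inside two CBSA polygons is an input error.
#' @return an `areal_partition`: list with `assignment` (data frame
#'   `fips`, `unit_id`, `unit_kind`) and `units` (named list of member
#'   fips vectors, keyed `"<kind>:<unit_id>"` so a CBSA code can never
#'   collide with a county code).
#' @export
assign_larger_unit <- function(tracts, cbsa_polygons = NULL) {
  validate_polygon_set(tracts)
  fips <- format_fips(names(tracts), pad = TRUE)
  names(tracts) <- fips
  unit_id <- county_fips(fips)
  unit_kind <- rep("county", length(fips))

  if (!is.null(cbsa_polygons) && length(cbsa_polygons)) {
    validate_polygon_set(cbsa_polygons)
    cbsa_ids <- names(cbsa_polygons)
    for (i in seq_along(tracts)) {
      pt <- representative_point(tracts[[i]])
      hit <- cbsa_ids[vapply(cbsa_polygons, point_in_geom, TRUE, pt = pt)]
      if (length(hit) > 1L)
        stop("tract ", fips[i], " falls inside overlapping CBSA polygons: ",
             paste(hit, collapse = ", "))
      if (length(hit) == 1L) {
        unit_id[i] <- hit
        unit_kind[i] <- "cbsa"
      }
    }
  }

  assignment <- data.frame(fips = fips, unit_id = unit_id,
                           unit_kind = unit_kind, stringsAsFactors = FALSE)
  units <- split(fips, paste(unit_kind, unit_id, sep = ":"))
  structure(list(assignment = assignment, units = units),
            class = "areal_partition")
}

#' @export
print.areal_partition <- function(x, ...) {
  k <- table(x$assignment$unit_kind)
  cat(sprintf("<areal_partition: %d tracts in %d unit(s) (%s)>\n",
              nrow(x$assignment), length(x$units),
              paste(sprintf("%s: %d", names(k), k), collapse = ", ")))
  invisible(x)
}
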