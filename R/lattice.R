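# Synthetic lattice "cities": square tracts with valid-shaped FIPS
# identifiers and seeded population scenarios, so every module (and the
# full pipeline) is testable without any census download.

mint_fips <- function(n, state = "17", county = "031") {
  # plausible state/county digits so the identifiers pass the same FIPS
  # validation real data does; tract codes step by 100 like real ones
  sprintf("%s%s%06d", state, county, seq_len(n) * 100L)
}

#' Generate a rectangular lattice of square tracts
#'
#' Builds an `nrows` x `ncols` grid of axis-aligned unit squares:
#' edge-adjacent along rows and columns (rook and queen), corner-adjacent
#' diagonally (queen only). Cells are numbered row-major starting at the
#' bottom-left origin.
#'
#' @param nrows,ncols grid dimensions (>= 1).
#' @param cell_size side length of each square tract.
#' @param origin coordinates of the bottom-left corner.
#' @param state,county digits used to mint the 11-digit identifiers.
#' @return a `gi_lattice`: list with `polygons` (named list of `gi_geom`),
#'   `fips` (row-major identifier vector) and the grid parameters.
#' @export
make_lattice <- function(nrows, ncols, cell_size = 1, origin = c(0, 0),
                         state = "17", county = "031") {
  if (!is.numeric(nrows) || !is.numeric(ncols) || nrows < 1 || ncols < 1)
    stop("nrows and ncols must be at least 1")
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  fips <- mint_fips(nrows * ncols, state = state, county = county)
  polygons <- vector("list", nrows * ncols)
  s <- cell_size
  for (r in seq_len(nrows)) {
    for (c in seq_len(ncols)) {
      x <- origin[1L] + (c - 1L) * s
      y <- origin[2L] + (r - 1L) * s
      polygons[[(r - 1L) * ncols + c]] <- gi_polygon(
        rbind(c(x, y), c(x + s, y), c(x + s, y + s), c(x, y + s)))
    }
  }
  names(polygons) <- fips
  structure(list(polygons = polygons, fips = fips, nrows = nrows,
                 ncols = ncols, cell_size = cell_size, origin = origin),
            class = "gi_lattice")
}

#' Identifier of the lattice cell at (row, col)
#' @param lattice a `gi_lattice`.
#' @param row,col 1-based grid coordinates (row 1 at the bottom).
#' @return the cell's FIPS identifier.
#' @export
lattice_id <- function(lattice, row, col) {
  stopifnot(inherits(lattice, "gi_lattice"),
            row >= 1, row <= lattice$nrows, col >= 1, col <= lattice$ncols)
  lattice$fips[(row - 1L) * lattice$ncols + col]
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit(if (had) assign(".Random.seed", old, envir = genv)
          else suppressWarnings(rm(".Random.seed", envir = genv)))
  set.seed(seed)
  force(code)
}

default_shares <- function(groups) {
  # a realistic mid-size US metro composition for the published four
  # groups; generic group sets share 90% equally, 10% "other"
  std <- c(nhWhite = 0.55, nhBlack = 0.18, nhAsian = 0.07, Hispanic = 0.15)
  if (all(groups %in% names(std))) std[groups]
  else stats::setNames(rep(0.9 / length(groups), length(groups)), groups)
}

#' Generate a seeded population scenario for a lattice
#'
#' Three scenarios: `"uniform"` draws every tract's group counts from one
#' multinomial composition; `"planted_cluster"` gives the target group a
#' high share `p_in` inside a rectangular block of cells and a low share
#' `p_out` elsewhere (binomial draws), splitting the remainder among the
#' other groups; `"islands"` draws like `"uniform"` (island-ness is a
#' property of the geometry, not the counts). Draws are reproducible:
#' the same seed yields the same table, and the caller's random state is
#' left untouched.
#'
#' @param lattice a `gi_lattice` (or a character vector of tract ids for
#'   the non-spatial scenarios).
#' @param groups group column names.
#' @param total total population per tract.
#' @param scenario one of `"uniform"`, `"planted_cluster"`, `"islands"`.
#' @param target_group the clustered group (default: first group).
#' @param cluster_rows,cluster_cols grid rows/columns of the planted
#'   block.
#' @param p_in,p_out target-group share inside/outside the block; must
#'   satisfy `0 <= p_out <= p_in <= 1`.
#' @param shares baseline composition for the remaining groups (named,
#'   summing to at most 1).
#' @param seed integer seed.
#' @return population data frame: `FIPS_ID`, `total`, one column per
#'   group.
#' @export
make_population <- function(lattice, groups = gistar_default_groups(),
                            total = 1000L,
                            scenario = c("uniform", "planted_cluster", "islands"),
                            target_group = groups[[1L]],
                            cluster_rows = NULL, cluster_cols = NULL,
                            p_in = 0.8, p_out = 0.1,
                            shares = default_shares(groups), seed = 1L) {
  scenario <- match.arg(scenario)
  ids <- if (inherits(lattice, "gi_lattice")) lattice$fips else as.character(lattice)
  if (!length(ids)) stop("no tract identifiers")
  if (any(shares < 0) || sum(shares) > 1 + 1e-12)
    stop("shares must be non-negative and sum to at most 1")
  nt <- length(ids)
  counts <- matrix(0L, nrow = nt, ncol = length(groups),
                   dimnames = list(ids, groups))

  with_seed(seed, {
    if (scenario %in% c("uniform", "islands")) {
      p <- c(shares, other = max(0, 1 - sum(shares)))
      draw <- stats::rmultinom(nt, size = total, prob = p)
      counts[, groups] <- t(draw[seq_along(groups), , drop = FALSE])
    } else {
      if (!inherits(lattice, "gi_lattice"))
        stop("planted_cluster needs a gi_lattice (block is given in grid coordinates)")
      if (is.null(cluster_rows) || is.null(cluster_cols))
        stop("planted_cluster needs cluster_rows and cluster_cols")
      if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
        stop("need 0 <= p_out <= p_in <= 1")
      if (!target_group %in% groups) stop("target_group must be one of groups")
      block <- as.vector(outer(cluster_cols, cluster_rows, function(c, r)
        (r - 1L) * lattice$ncols + c))
      others <- setdiff(groups, target_group)
      osh <- shares[others]
      osh <- if (sum(osh) > 0) osh / sum(osh) * 0.9 else
        stats::setNames(rep(0.9 / max(1, length(others)), length(others)), others)
      for (i in seq_len(nt)) {
        p <- if (i %in% block) p_in else p_out
        tg <- stats::rbinom(1L, total, p)
        counts[i, target_group] <- tg
        if (length(others)) {
          rest <- stats::rmultinom(1L, total - tg, prob = c(osh, other = 0.1))
          counts[i, others] <- rest[seq_along(others), 1L]
        }
      }
    }
  })
  out <- data.frame(FIPS_ID = ids, total = rep.int(as.integer(total), nt),
                    stringsAsFactors = FALSE)
  for (g in groups) out[[g]] <- unname(counts[, g])
  out
}

#' Minimal fixture reproducing one indicator code end-to-end
#'
#' Builds the smallest geometry/population pair whose [run_pipeline()]
#' output contains the requested reserved code in known cells: a 1x1
#' lattice (-99), a 3x3 lattice with one unpopulated tract (-100), a 3x3
#' lattice where one group has no members anywhere (-199, the other
#' groups still score), a 2x2 lattice under queen contiguity where every
#' tract touches every other (-299), and spatially separated squares
#' (-399).
#'
#' @param code one of -99, -100, -199, -299, -399.
#' @param seed seed for the population draws.
#' @return list with `geometry` (named list of `gi_geom`), `population`
#'   (data frame), `contiguity` (the mode the fixture assumes) and
#'   `expected` (data frame `fips`, `group`, `code` enumerating the cells
#'   guaranteed to carry the code).
#' @export
make_degenerate_fixture <- function(code, seed = 42L) {
  groups <- gistar_default_groups()
  cells <- function(fips, gs, code)
    expand.grid(fips = fips, group = gs, code = code,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  code <- as.integer(code)
  if (code == -99L) {
    lat <- make_lattice(1, 1)
    pop <- make_population(lat, groups, seed = seed)
    list(geometry = lat$polygons, population = pop, contiguity = "queen",
         expected = cells(lat$fips, groups, -99L))
  } else if (code == -100L) {
    lat <- make_lattice(3, 3)
    pop <- make_population(lat, groups, seed = seed)
    dead <- lattice_id(lat, 2, 2)
    pop[pop$FIPS_ID == dead, c("total", groups)] <- 0L
    list(geometry = lat$polygons, population = pop, contiguity = "queen",
         expected = cells(dead, groups, -100L))
  } else if (code == -199L) {
    lat <- make_lattice(3, 3)
    pop <- make_population(lat, groups, seed = seed)
    pop[["nhAsian"]] <- 0L
    list(geometry = lat$polygons, population = pop, contiguity = "queen",
         expected = cells(lat$fips, "nhAsian", -199L))
  } else if (code == -299L) {
    lat <- make_lattice(2, 2)
    pop <- make_population(lat, groups, seed = seed)
    list(geometry = lat$polygons, population = pop, contiguity = "queen",
         expected = cells(lat$fips, groups, -299L))
  } else if (code == -399L) {
    # three unit squares with unit-wide gaps: no contact at all
    fips <- mint_fips(3L)
    sq <- function(x) gi_polygon(rbind(c(x, 0), c(x + 1, 0),
                                       c(x + 1, 1), c(x, 1)))
    geom <- stats::setNames(list(sq(0), sq(3), sq(6)), fips)
    pop <- make_population(fips, groups, seed = seed)
    list(geometry = geom, population = pop, contiguity = "queen",
         expected = cells(fips, groups, -399L))
  } else {
    stop("unknown indicator code: ", code)
  }
}
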