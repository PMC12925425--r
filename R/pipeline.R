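# End-to-end orchestration: partition tracts into larger units, build
# within-unit contiguity, score every tract per group, code the
# degenerate cells, and bind one national table.

#' Pipeline run configuration
#'
#' @param groups ordered group column names (result column order follows).
#' @param contiguity `"queen"` or `"rook"`.
#' @param snap_tolerance coordinate snap distance for adjacency (see
#'   [build_neighbor_graph()]).
#' @param output_path optional CSV path; when set, [run_pipeline()] also
#'   writes the result table there.
#' @param pad_fips keep leading zeros in the written `FIPS_ID` column?
#' @param id_col,total_col population-table column names.
#' @param verbose log unit counts, indicator-code tallies and timing?
#' @return a `gistar_config` list.
#' @export
run_config <- function(groups = gistar_default_groups(),
                       contiguity = c("queen", "rook"),
                       snap_tolerance = 0, output_path = NULL,
                       pad_fips = FALSE, id_col = "FIPS_ID",
                       total_col = "total", verbose = FALSE) {
  contiguity <- match.arg(contiguity)
  if (!length(groups) || anyDuplicated(groups) || any(!nzchar(groups)))
    stop("groups must be a non-empty vector of unique, non-empty names")
  structure(list(groups = as.character(groups), contiguity = contiguity,
                 snap_tolerance = snap_tolerance, output_path = output_path,
                 pad_fips = isTRUE(pad_fips), id_col = id_col,
                 total_col = total_col, verbose = isTRUE(verbose)),
            class = "gistar_config")
}

#' Classify a tract/group cell that cannot receive a Gi* score
#'
#' Applies the reserved indicator codes in fixed precedence order
#' (unit-level conditions before tract-level connectivity):
#' single-tract unit (-99), zero focal population (-100), no target
#' population in the unit (-199), focal tract adjacent to every other
#' member (-299), all members islands (-399). Returns `NA` when no
#' condition holds and a Z-score should be computed.
#'
#' @param members tract ids of the unit.
#' @param graph `neighbor_graph` restricted to the unit members.
#' @param totals named total-population vector covering the members.
#' @param group_counts named group-count vector covering the members.
#' @param focal the focal tract id.
#' @return integer code or `NA_integer_`.
#' @export
classify_degenerate <- function(members, graph, totals, group_counts, focal) {
  deg <- lengths(graph$neighbors[members])
  if (length(members) == 1L) return(-99L)
  if (totals[[focal]] == 0L) return(-100L)
  if (sum(group_counts[members]) == 0L) return(-199L)
  if (length(graph$neighbors[[focal]]) == length(members) - 1L) return(-299L)
  if (all(deg == 0L)) return(-399L)
  NA_integer_
}

score_unit_group <- function(members, graph, totals, counts) {
  vals <- stats::setNames(rep(NA_real_, length(members)), members)
  codes <- vapply(members, function(f)
    classify_degenerate(members, graph, totals, counts, f), NA_integer_)
  vals[!is.na(codes)] <- as.numeric(codes[!is.na(codes)])
  open <- members[is.na(codes)]
  if (!length(open)) return(vals)

  # zero-population tracts are coded -100 above and leave the unit
  # entirely: they drop out of x_bar, s, n and of neighbors' weight rows
  # (weights re-standardized over the remaining members)
  reduced <- members[totals[members] > 0L]
  props <- compute_group_proportions(counts[reduced], totals[reduced])
  if (props$n < 2L || props$s <= 0) {
    warning("unit with ", props$n, " populated tract(s) has zero variance in ",
            "group proportions; Gi* undefined, emitting missing values",
            call. = FALSE)
    return(vals)
  }
  wl <- list()
  for (f in open) {
    nbr <- intersect(graph$neighbors[[f]], reduced)
    k <- length(nbr)
    # after dropping unpopulated tracts a focal tract can become adjacent
    # to every remaining member; the denominator n*S1 - W^2 vanishes
    if (props$n / (k + 1) - 1 <= 0) {
      vals[[f]] <- -299
      next
    }
    w <- rep.int(1 / (k + 1), k + 1L)
    names(w) <- c(f, nbr)
    wl[[f]] <- structure(list(focal = f, weights = w, W = 1, S1 = 1 / (k + 1),
                              n_neigh = k), class = "weights_row")
  }
  if (length(wl)) vals[names(wl)] <- gi_star_unit(props, wl)
  vals
}

#' Run the full Gi* pipeline
#'
#' For each larger areal unit independently: restrict to its member
#' tracts, build the contiguity graph on those members only (a tract's
#' geometric neighbors outside its unit never contribute), compute group
#' proportions, code degenerate cells, and score the rest with the
#' self-included row-standardized Gi*. Unit results are bound into one
#' table sorted by FIPS; no tract is ever dropped.
#'
#' @param geometry tract polygons: a named list of `gi_geom` objects or a
#'   path readable by [read_geometry()].
#' @param population population table: a data frame or a CSV path (see
#'   [read_population_table()]); its tract set must equal the geometry's.
#' @param cbsa_geometry optional CBSA polygons (named list or path); when
#'   absent every tract uses its county as the larger unit.
#' @param config a [run_config()] object.
#' @return a `gistar_result` data frame: `FIPS_ID` plus, for each group
#'   `g` in order, `g_Gstat` (Z-score, indicator code, or `NA` for
#'   zero-variance units) and `g_n_neigh` (within-unit neighbor count,
#'   self excluded, identical across groups).
#' @examples
#' lat <- make_lattice(5, 5)
#' pop <- make_population(lat, scenario = "planted_cluster",
#'                        cluster_rows = 1:2, cluster_cols = 1:2, seed = 1)
#' res <- run_pipeline(lat$polygons, pop, config = run_config())
#' head(res[, 1:3])
#' @export
run_pipeline <- function(geometry, population, cbsa_geometry = NULL,
                         config = run_config()) {
  if (!inherits(config, "gistar_config")) stop("config must come from run_config()")
  t0 <- proc.time()[["elapsed"]]
  if (is.character(geometry)) geometry <- read_geometry(geometry)
  validate_polygon_set(geometry)
  names(geometry) <- format_fips(names(geometry), pad = TRUE)
  if (is.character(population))
    population <- read_population_table(population, config$groups,
                                        id_col = config$id_col,
                                        total_col = config$total_col)
  else
    population <- validate_population(population, config$groups,
                                      id_col = config$id_col,
                                      total_col = config$total_col)
  if (is.character(cbsa_geometry)) cbsa_geometry <- read_geometry(cbsa_geometry)

  gids <- names(geometry)
  pids <- population$FIPS_ID
  only_g <- setdiff(gids, pids)
  only_p <- setdiff(pids, gids)
  if (length(only_g) || length(only_p))
    stop("tract identifier mismatch between geometry and population table; ",
         "geometry-only: [", paste(utils::head(only_g, 5L), collapse = ", "),
         "], population-only: [", paste(utils::head(only_p, 5L), collapse = ", "), "]")

  part <- assign_larger_unit(geometry, cbsa_geometry)
  totals <- stats::setNames(population$total, pids)
  counts <- lapply(stats::setNames(config$groups, config$groups),
                   function(g) stats::setNames(population[[g]], pids))

  unit_keys <- sort(names(part$units))
  rows <- vector("list", length(unit_keys))
  for (u in seq_along(unit_keys)) {
    members <- sort(part$units[[unit_keys[u]]])
    graph <- build_neighbor_graph(geometry[members], config$contiguity,
                                  config$snap_tolerance)
    deg <- lengths(graph$neighbors)[members]
    df <- data.frame(FIPS_ID = members, stringsAsFactors = FALSE)
    for (g in config$groups) {
      df[[paste0(g, "_Gstat")]] <-
        unname(score_unit_group(members, graph, totals, counts[[g]]))
      df[[paste0(g, "_n_neigh")]] <- unname(as.integer(deg))
    }
    rows[[u]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$FIPS_ID), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- config$groups
  class(out) <- c("gistar_result", "data.frame")

  if (config$verbose) {
    kinds <- table(part$assignment$unit_kind)
    message(sprintf("units: %d (%s); tracts: %d", length(unit_keys),
                    paste(sprintf("%s %d", names(kinds), kinds), collapse = ", "),
                    nrow(out)))
    gs <- unlist(out[paste0(config$groups, "_Gstat")], use.names = FALSE)
    for (code in gistar_codes()) {
      nc <- sum(!is.na(gs) & gs == code)
      if (nc) message(sprintf("  indicator %d: %d cell(s)", code, nc))
    }
    message(sprintf("elapsed: %.2f s", proc.time()[["elapsed"]] - t0))
  }
  if (!is.null(config$output_path))
    write_results_csv(out, config$output_path, pad_fips = config$pad_fips)
  out
}
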