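# Population tables: one row per tract, one count column per group plus
# a total-population column (the groups are a subset of the population,
# not a partition of it).

#' Default racial/ethnic group set
#'
#' The four groups of the published tables: non-Hispanic White,
#' non-Hispanic Black, non-Hispanic Asian and Hispanic adults.
#' @return character vector of group names in output order.
#' @export
gistar_default_groups <- function() c("nhWhite", "nhBlack", "nhAsian", "Hispanic")

as_count_column <- function(v, col, what = "count") {
  x <- suppressWarnings(as.numeric(v))
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad))
    stop("column '", col, "' has non-integer or negative ", what,
         " in row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  as.integer(round(x))
}

validate_population <- function(df, groups, id_col = "FIPS_ID", total_col = "total") {
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("population table is empty: no tracts")
  need <- c(id_col, total_col, groups)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("population table is missing column(s): ", paste(miss, collapse = ", "))
  fips <- format_fips(df[[id_col]], pad = TRUE)
  if (anyDuplicated(fips))
    stop("duplicate tract identifier(s) in population table: ",
         paste(unique(fips[duplicated(fips)]), collapse = ", "))
  out <- data.frame(FIPS_ID = fips, stringsAsFactors = FALSE)
  out$total <- as_count_column(df[[total_col]], total_col, "total")
  for (g in groups) out[[g]] <- as_count_column(df[[g]], g)
  gsum <- Reduce(`+`, out[groups])
  for (g in groups) {
    bad <- which(out[[g]] > out$total)
    if (length(bad))
      stop("group '", g, "' exceeds total population in row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which(gsum > out$total)
  if (length(bad))
    stop("summed group counts exceed total population in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  out
}

#' Read a tract population table from CSV
#'
#' Expects a header row with a tract-identifier column, one integer count
#' column per group and a total-population column. Identifiers are
#' canonicalized to the padded 11-digit form; counts are validated
#' (integer, non-negative, each group and the group sum bounded by the
#' total).
#'
#' @param path CSV path.
#' @param groups group column names (default the four published groups).
#' @param id_col,total_col identifier and total column names.
#' @return data frame with columns `FIPS_ID`, `total`, then one column
#'   per group, in the given order.
#' @export
read_population_table <- function(path, groups = gistar_default_groups(),
                                  id_col = "FIPS_ID", total_col = "total") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  validate_population(df, groups, id_col = id_col, total_col = total_col)
}
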