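# The deposit result schema: FIPS_ID, then for each group g the pair
# g_Gstat (Z-score or negative indicator code) and g_n_neigh.

#' Reserved indicator codes for undefined Gi* cells
#'
#' @return named integer vector mapping each reason to its code:
#'   single-tract unit (-99), zero focal population (-100), no target
#'   population anywhere in the unit (-199), focal tract connected to
#'   every other unit member (-299), all unit members islands (-399).
#' @export
gistar_codes <- function() {
  c(single_tract = -99L, zero_population = -100L, no_target_population = -199L,
    fully_connected = -299L, all_islands = -399L)
}

is_indicator_code <- function(v) {
  !is.na(v) & v %in% as.numeric(gistar_codes())
}

result_groups <- function(table) {
  g <- attr(table, "groups")
  if (!is.null(g)) return(g)
  sub("_Gstat$", "", grep("_Gstat$", names(table), value = TRUE))
}

#' Write a Gi* result table to CSV
#'
#' Emits the exact deposit schema: header
#' `FIPS_ID,{g}_Gstat,{g}_n_neigh,...` in group order (nine columns with
#' the default four groups). Z-scores are printed with fixed precision,
#' indicator codes as bare integers (ASCII hyphen-minus), missing cells
#' (zero-variance units) as empty fields, and `FIPS_ID` in numeric style
#' without its leading zero unless `pad_fips`.
#'
#' @param table a `gistar_result` (or compatible data frame).
#' @param path output CSV path.
#' @param pad_fips keep the leading zero on identifiers?
#' @param digits decimal places for Z-scores (default 6).
#' @export
write_results_csv <- function(table, path, pad_fips = FALSE, digits = 6L) {
  groups <- result_groups(table)
  if (!length(groups)) stop("no *_Gstat columns found in result table")
  cols <- c("FIPS_ID", as.vector(rbind(paste0(groups, "_Gstat"),
                                       paste0(groups, "_n_neigh"))))
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("result table is missing column(s): ", paste(miss, collapse = ", "))

  fmt_g <- function(v) {
    out <- character(length(v))
    code <- is_indicator_code(v)
    out[code] <- sprintf("%d", as.integer(v[code]))
    out[is.na(v)] <- ""
    fin <- !code & !is.na(v)
    out[fin] <- formatC(v[fin], format = "f", digits = digits)
    out
  }
  m <- cbind(format_fips(table$FIPS_ID, pad = pad_fips))
  for (g in groups) {
    m <- cbind(m, fmt_g(table[[paste0(g, "_Gstat")]]),
               sprintf("%d", as.integer(table[[paste0(g, "_n_neigh")]])))
  }
  con <- file(path, "wb")  # binary mode: byte-identical output on any OS
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","),
               apply(m, 1L, paste, collapse = ",")), con)
  invisible(path)
}

#' Read a Gi* result table written by [write_results_csv()]
#'
#' @param path CSV path.
#' @return a `gistar_result` data frame; identifiers are re-canonicalized
#'   to the 11-digit form, empty Gstat cells become `NA`.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"FIPS_ID" %in% names(df)) stop("not a Gi* result table (no FIPS_ID column): ", path)
  groups <- sub("_Gstat$", "", grep("_Gstat$", names(df), value = TRUE))
  out <- data.frame(FIPS_ID = format_fips(df$FIPS_ID, pad = TRUE),
                    stringsAsFactors = FALSE)
  for (g in groups) {
    gs <- df[[paste0(g, "_Gstat")]]
    out[[paste0(g, "_Gstat")]] <- ifelse(gs == "", NA_real_,
                                         suppressWarnings(as.numeric(gs)))
    out[[paste0(g, "_n_neigh")]] <- as.integer(df[[paste0(g, "_n_neigh")]])
  }
  attr(out, "groups") <- groups
  class(out) <- c("gistar_result", "data.frame")
  out
}
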