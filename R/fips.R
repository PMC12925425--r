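#' Parse census-tract FIPS identifiers
#'
#' A tract FIPS code is an 11-digit identifier formed of a 2-digit state
#' code, a 3-digit county code and a 6-digit tract code. Data that has
#' round-tripped through numeric software (including the published deposit
#' tables) drops the single leading zero of states 01-09, so 10-digit
#' inputs are accepted and left-padded with one zero before splitting.
#'
#' @param x character or numeric vector of identifiers; each element must
#'   be 10 or 11 digits after stripping whitespace.
#' @return an object of class `fips_id`: a data frame with columns
#'   `state`, `county`, `tract` and `canonical` (the zero-padded
#'   11-character form used everywhere inside the package).
#' @examples
#' parse_fips("17031010100")
#' parse_fips(1031010100)$canonical  # "01031010100"
#' @export
parse_fips <- function(x) {
  if (length(x) == 0L) stop("no FIPS identifiers supplied")
  s <- if (is.numeric(x)) sprintf("%.0f", x) else trimws(as.character(x))
  bad <- is.na(s) | !grepl("^[0-9]{10,11}$", s)
  if (any(bad)) {
    stop("invalid FIPS identifier(s) (need 10 or 11 digits): ",
         paste(utils::head(unique(s[bad]), 5L), collapse = ", "))
  }
  s <- ifelse(nchar(s) == 10L, paste0("0", s), s)
  out <- data.frame(state     = substr(s, 1L, 2L),
                    county    = substr(s, 3L, 5L),
                    tract     = substr(s, 6L, 11L),
                    canonical = s,
                    stringsAsFactors = FALSE)
  class(out) <- c("fips_id", "data.frame")
  out
}

#' Format FIPS identifiers
#'
#' Renders identifiers either in the canonical zero-padded 11-character
#' form (`pad = TRUE`) or in the numeric-style dialect that drops the one
#' possible leading zero (`pad = FALSE`), as used by the deposit tables.
#'
#' @param x a `fips_id` object or anything [parse_fips()] accepts.
#' @param pad keep the leading zero?
#' @return character vector of formatted identifiers.
#' @export
format_fips <- function(x, pad = TRUE) {
  s <- if (inherits(x, "fips_id")) x$canonical else parse_fips(x)$canonical
  if (pad) s else sub("^0", "", s)
}

# state+county prefix (5 chars) of canonical identifiers
county_fips <- function(x) substr(format_fips(x, pad = TRUE), 1L, 5L)
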