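# The standardized local Gi* statistic.
#
# For tract i in an areal unit of n tracts with group proportions x_j,
# mean x_bar and population standard deviation s = sqrt(sum(x^2)/n -
# x_bar^2), and self-included weights w_ij with row sum W_i and squared
# sum S1_i:
#
#   Gi* = (sum_j w_ij x_j - x_bar W_i) / (s * sqrt((n S1_i - W_i^2)/(n-1)))
#
# This is the Ord-Getis (1995) standardized "star" form: the focal tract
# is part of its own neighborhood and of the reference mean. With
# row-standardized weights W_i = 1. The result is a Z-score: positive
# where the group is locally overrepresented relative to the unit mean.

#' Group proportions within an areal unit
#'
#' Divides per-tract group counts by total population and summarizes the
#' unit: tracts with zero total population cannot yield a proportion and
#' are flagged (downstream they receive indicator code -100 and are
#' excluded from the unit mean and standard deviation).
#'
#' @param counts named integer vector: group count per tract.
#' @param totals named integer vector: total population per tract; names
#'   must match `counts`.
#' @return a `group_proportions` object: list with `x` (named proportions
#'   over tracts with positive totals), `n`, `x_bar`, `s` (population
#'   standard deviation) and `zero_total` (flagged tract ids).
#' @export
compute_group_proportions <- function(counts, totals) {
  if (is.null(names(counts)) || is.null(names(totals)) ||
      !setequal(names(counts), names(totals)) ||
      length(counts) != length(totals))
    stop("counts and totals must be named vectors over the same tract set")
  counts <- counts[names(totals)]
  if (any(!is.finite(counts)) || any(!is.finite(totals)) ||
      any(counts < 0) || any(totals < 0))
    stop("counts and totals must be non-negative and finite")
  over <- counts > totals
  if (any(over))
    stop("group count exceeds total population for tract(s): ",
         paste(names(totals)[over], collapse = ", "))
  zero <- names(totals)[totals == 0]
  keep <- totals > 0
  x <- counts[keep] / totals[keep]
  n <- length(x)
  x_bar <- if (n) mean(x) else NA_real_
  s <- if (n) sqrt(max(0, sum(x^2) / n - x_bar^2)) else NA_real_
  structure(list(x = x, n = n, x_bar = x_bar, s = s, zero_total = zero),
            class = "group_proportions")
}

#' @export
print.group_proportions <- function(x, ...) {
  cat(sprintf("<group_proportions: n = %d, x_bar = %.4f, s = %.4f, %d zero-total tract(s)>\n",
              x$n, x$x_bar, x$s, length(x$zero_total)))
  invisible(x)
}

#' Standardized local Gi* Z-scores for one areal unit
#'
#' Evaluates the self-included Ord-Getis Gi* statistic for each weights
#' row supplied. The unit mean `x_bar` and population standard deviation
#' `s` are taken over all `n` tracts of the unit (including each focal
#' tract: the "star" form). Scores are returned only for the tracts that
#' have a weights row, so callers may score a subset of the unit.
#'
#' @param xv a `group_proportions` object describing the whole unit.
#' @param weights named list of `weights_row` objects (see
#'   [row_standardize_with_self()]); every referenced tract must be in
#'   `xv$x`.
#' @return named numeric vector of Z-scores, one per weights row.
#' @section Errors and limiting cases: a unit with `s = 0` (constant
#'   proportions) has no defined Z-score and raises a condition of class
#'   `gistar_zero_variance`. A focal tract connected to every other unit
#'   member makes the denominator `n*S1 - W^2` vanish -- but with
#'   self-included row-standardized weights its numerator is then exactly
#'   zero as well (the neighborhood average over the whole unit *is* the
#'   unit mean), so the statistic is returned as 0 by convention. The
#'   pipeline never exposes such cells: [classify_degenerate()] codes
#'   them -299 first.
#' @examples
#' lat <- make_lattice(1, 3)
#' w <- row_standardize_with_self(build_neighbor_graph(lat$polygons, "rook"))
#' x <- stats::setNames(c(1, 0, 0), lat$fips)
#' t <- stats::setNames(c(10, 10, 10), lat$fips)
#' gi_star_unit(compute_group_proportions(x * t, t), w)
#' # 0.7071, 0, -1.4142: the populated end of the chain is a local hotspot
#' @export
gi_star_unit <- function(xv, weights) {
  if (!inherits(xv, "group_proportions")) stop("xv must be a group_proportions object")
  n <- xv$n
  if (n < 2L) stop("Gi* needs at least two tracts with population in the unit")
  if (!is.finite(xv$s) || xv$s <= 0)
    stop(errorCondition("zero variance: all group proportions in the unit are equal",
                        class = c("gistar_zero_variance", "error", "condition")))
  x <- xv$x
  out <- vapply(weights, function(wr) {
    w <- wr$weights
    miss <- setdiff(names(w), names(x))
    if (length(miss))
      stop("weights row for ", wr$focal, " refers to tract(s) outside the unit: ",
           paste(miss, collapse = ", "))
    W <- sum(w)
    S1 <- sum(w^2)
    d <- n * S1 - W^2
    # d = 0 iff the row spans the whole unit with equal weights
    # (Cauchy-Schwarz); the numerator is then analytically 0 too, so the
    # fully-connected limit is scored 0 rather than 0/0
    if (d <= 1e-9 * max(W^2, 1)) return(0)
    (sum(w * x[names(w)]) - xv$x_bar * W) / (xv$s * sqrt(d / (n - 1)))
  }, numeric(1))
  names(out) <- vapply(weights, `[[`, "", "focal")
  out
}
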