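# Independent oracles and fixture helpers. These deliberately do not
# share code paths with the package: adjacency is decided by classifying
# every edge pair of every polygon pair with a parametric segment
# intersection test, and the Gi* oracle is a literal double-loop
# transcription of the standardized formula.

# ---- brute-force contiguity oracle ------------------------------------

oracle_poly_edges <- function(g) {
  rings <- unlist(g$parts, recursive = FALSE)
  do.call(rbind, lapply(rings, function(r)
    cbind(r[-nrow(r), , drop = FALSE], r[-1L, , drop = FALSE])))
}

# relation of two closed segments: "none", "point" or "segment"
oracle_seg_relation <- function(p1, p2, q1, q2, eps = 1e-9) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  w <- q1 - p1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) > eps) {
    t <- (w[1] * d2[2] - w[2] * d2[1]) / den
    u <- (w[1] * d1[2] - w[2] * d1[1]) / den
    if (t >= -eps && t <= 1 + eps && u >= -eps && u <= 1 + eps) return("point")
    return("none")
  }
  if (abs(d1[1] * w[2] - d1[2] * w[1]) > eps) return("none")  # parallel, offset
  L <- sqrt(sum(d1^2))
  tb <- sort(c(sum((q1 - p1) * d1), sum((q2 - p1) * d1)) / L)
  lo <- max(0, tb[1])
  hi <- min(L, tb[2])
  if (hi - lo > eps) "segment" else if (hi - lo >= -eps) "point" else "none"
}

oracle_neighbors <- function(polys, mode = c("queen", "rook")) {
  mode <- match.arg(mode)
  ids <- names(polys)
  n <- length(ids)
  E <- lapply(polys, oracle_poly_edges)
  bb <- t(vapply(E, function(e)
    c(min(e[, c(1, 3)]), min(e[, c(2, 4)]), max(e[, c(1, 3)]), max(e[, c(2, 4)])),
    numeric(4)))
  nb <- stats::setNames(rep(list(character(0)), n), ids)
  if (n < 2) return(nb)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bb[i, 1] > bb[j, 3] || bb[j, 1] > bb[i, 3] ||
          bb[i, 2] > bb[j, 4] || bb[j, 2] > bb[i, 4]) next
      rel <- "none"
      for (a in seq_len(nrow(E[[i]]))) {
        for (b in seq_len(nrow(E[[j]]))) {
          r <- oracle_seg_relation(E[[i]][a, 1:2], E[[i]][a, 3:4],
                                   E[[j]][b, 1:2], E[[j]][b, 3:4])
          if (r == "segment") rel <- "segment"
          else if (r == "point" && rel == "none") rel <- "point"
          if (rel == "segment") break
        }
        if (rel == "segment") break
      }
      linked <- if (mode == "queen") rel != "none" else rel == "segment"
      if (linked) {
        nb[[i]] <- c(nb[[i]], ids[j])
        nb[[j]] <- c(nb[[j]], ids[i])
      }
    }
  }
  lapply(nb, sort)
}

# lattice whose grid nodes are jointly jittered: adjacency is provably
# that of the unperturbed lattice, but coordinates are irregular
perturbed_lattice <- function(nr, nc, jitter = 0.2) {
  X <- outer(rep(1, nr + 1), 0:nc) +
    matrix(stats::runif((nr + 1) * (nc + 1), -jitter, jitter), nr + 1)
  Y <- outer(0:nr, rep(1, nc + 1)) +
    matrix(stats::runif((nr + 1) * (nc + 1), -jitter, jitter), nr + 1)
  polys <- vector("list", nr * nc)
  nm <- character(nr * nc)
  k <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      k <- k + 1L
      nm[k] <- sprintf("c%02d_%02d", r, c)
      polys[[k]] <- gi_polygon(rbind(c(X[r, c], Y[r, c]),
                                     c(X[r, c + 1], Y[r, c + 1]),
                                     c(X[r + 1, c + 1], Y[r + 1, c + 1]),
                                     c(X[r + 1, c], Y[r + 1, c])))
    }
  }
  stats::setNames(polys, nm)
}

# expected queen/rook degree of cell (r, c) on an nr x nc lattice
lattice_degree <- function(nr, nc, r, c, mode) {
  rows <- max(1, r - 1):min(nr, r + 1)
  cols <- max(1, c - 1):min(nc, c + 1)
  if (mode == "queen") length(rows) * length(cols) - 1L
  else (length(rows) - 1L) + (length(cols) - 1L)
}

# ---- Gi* oracle --------------------------------------------------------

# literal double-loop evaluation; w is a named list of weights rows
# (weight 0 for every unit member absent from the row)
oracle_gi_star <- function(x, wrows) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  out <- numeric(length(wrows))
  names(out) <- names(wrows)
  for (i in names(wrows)) {
    w <- wrows[[i]]$weights
    W <- 0; S1 <- 0; num <- 0
    for (j in names(x)) {
      wij <- if (j %in% names(w)) unname(w[j]) else 0
      W <- W + wij
      S1 <- S1 + wij^2
      num <- num + wij * x[[j]]
    }
    d <- n * S1 - W^2
    out[i] <- if (d <= 1e-9 * max(W^2, 1)) 0 else
      (num - xbar * W) / (s * sqrt(d / (n - 1)))
  }
  out
}

# group_proportions object from a bare proportion vector (for invariance
# properties where counts/totals would force rounding)
props_from_x <- function(x) {
  structure(list(x = x, n = length(x), x_bar = mean(x),
                 s = sqrt(max(0, sum(x^2) / length(x) - mean(x)^2)),
                 zero_total = character(0)),
            class = "group_proportions")
}
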