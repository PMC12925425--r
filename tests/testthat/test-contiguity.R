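test_that("lattice neighbor counts match the closed-form degrees", {
  for (dims in list(c(3, 3), c(4, 6), c(5, 5), c(3, 8))) {
    lat <- make_lattice(dims[1], dims[2])
    for (mode in c("queen", "rook")) {
      g <- build_neighbor_graph(lat$polygons, mode)
      for (r in seq_len(dims[1])) {
        for (c in seq_len(dims[2])) {
          expect_identical(
            length(g$neighbors[[lattice_id(lat, r, c)]]),
            lattice_degree(dims[1], dims[2], r, c, mode),
            info = sprintf("%s %dx%d cell (%d,%d)", mode, dims[1], dims[2], r, c))
        }
      }
    }
  }
})

test_that("corner-only contact links under queen but not rook", {
  polys <- list(
    a = gi_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
    b = gi_polygon(rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))))
  q <- build_neighbor_graph(polys, "queen")
  r <- build_neighbor_graph(polys, "rook")
  expect_identical(q$neighbors$a, "b")
  expect_identical(q$neighbors$b, "a")
  expect_identical(r$neighbors$a, character(0))
  expect_identical(r$neighbors$b, character(0))
})

test_that("T-junction contact (subdivided shared edge) is detected", {
  # b's left edge covers only the middle third of a's right edge, with no
  # shared vertices at all: still a positive-length common boundary
  polys <- list(
    a = gi_polygon(rbind(c(0, 0), c(1, 0), c(1, 3), c(0, 3))),
    b = gi_polygon(rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))))
  expect_identical(build_neighbor_graph(polys, "queen")$neighbors$a, "b")
  expect_identical(build_neighbor_graph(polys, "rook")$neighbors$a, "b")
})

test_that("graphs are symmetric, irreflexive, and rook is a subset of queen", {
  set.seed(101)
  for (rep in 1:10) {
    polys <- perturbed_lattice(sample(3:6, 1), sample(3:6, 1))
    q <- build_neighbor_graph(polys, "queen")$neighbors
    r <- build_neighbor_graph(polys, "rook")$neighbors
    for (i in names(polys)) {
      expect_false(i %in% q[[i]])
      for (j in q[[i]]) expect_true(i %in% q[[j]])
      expect_true(all(r[[i]] %in% q[[i]]))
    }
  }
})

test_that("adjacency is invariant under a common rotation and translation", {
  set.seed(7)
  polys <- perturbed_lattice(4, 4)
  theta <- 37 * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- lapply(polys, function(g) {
    g$parts <- lapply(g$parts, function(p) lapply(p, function(ring)
      sweep(ring %*% t(rot), 2, c(123.4, -56.7), `+`)))
    g
  })
  for (mode in c("queen", "rook")) {
    expect_identical(build_neighbor_graph(polys, mode)$neighbors,
                     build_neighbor_graph(moved, mode)$neighbors)
  }
})

test_that("snap tolerance bridges sliver gaps", {
  polys <- list(
    a = gi_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
    b = gi_polygon(rbind(c(1.01, 0), c(2, 0), c(2, 1), c(1.01, 1))))
  expect_identical(build_neighbor_graph(polys, "rook")$neighbors$a, character(0))
  expect_identical(build_neighbor_graph(polys, "rook", snap_tolerance = 0.05)$neighbors$a, "b")
})

test_that("invalid inputs are rejected with the offending id", {
  sq <- gi_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  flat <- gi_polygon(rbind(c(0, 0), c(1, 0), c(2, 0)))  # zero area
  expect_error(build_neighbor_graph(list(a = sq, a = sq), "queen"), "duplicate")
  expect_error(build_neighbor_graph(list(ok = sq, degenerate = flat), "queen"),
               "degenerate")
  expect_error(build_neighbor_graph(setNames(list(sq), NA), "queen"), "named")
})

test_that("self-included row-standardization yields uniform rows summing to 1", {
  lat <- make_lattice(3, 3)
  g <- build_neighbor_graph(lat$polygons, "queen")
  w <- row_standardize_with_self(g)
  for (i in names(w)) {
    k <- length(g$neighbors[[i]])
    expect_identical(w[[i]]$n_neigh, k)
    expect_setequal(names(w[[i]]$weights), c(i, g$neighbors[[i]]))
    expect_equal(unname(w[[i]]$weights), rep(1 / (k + 1), k + 1))
    expect_equal(w[[i]]$W, 1, tolerance = 1e-12)
    expect_equal(w[[i]]$S1, 1 / (k + 1), tolerance = 1e-12)
  }
  # center of the 3x3 queen lattice: 9 equal weights of 1/9
  ctr <- lattice_id(lat, 2, 2)
  expect_equal(unname(w[[ctr]]$weights), rep(1 / 9, 9))
})

test_that("an island tract gets the degenerate self-only row", {
  sq <- function(x) gi_polygon(rbind(c(x, 0), c(x + 1, 0), c(x + 1, 1), c(x, 1)))
  g <- build_neighbor_graph(list(a = sq(0), b = sq(5)), "queen")
  w <- row_standardize_with_self(g)
  expect_identical(w$a$weights, c(a = 1))
  expect_identical(w$a$n_neigh, 0L)
})
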