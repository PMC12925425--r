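chain_fixture <- function(x_vals = c(1, 0, 0), total = 10L) {
  lat <- make_lattice(1, 3)
  w <- row_standardize_with_self(build_neighbor_graph(lat$polygons, "rook"))
  t <- setNames(rep(total, 3), lat$fips)
  list(lat = lat, w = w,
       props = compute_group_proportions(setNames(x_vals * total, lat$fips), t))
}

test_that("group proportions divide counts by totals and flag zero totals", {
  counts <- c(a = 30, b = 100, c = 0)
  totals <- c(a = 100, b = 100, c = 0)
  names(counts) <- names(totals) <- c("17031000100", "17031000200", "17031000300")
  p <- compute_group_proportions(counts, totals)
  expect_equal(unname(p$x), c(0.30, 1.0))
  expect_identical(p$zero_total, "17031000300")
  expect_identical(p$n, 2L)
  # cached summaries equal recomputation from x
  expect_equal(p$x_bar, mean(p$x), tolerance = 1e-12)
  expect_equal(p$s, sqrt(sum(p$x^2) / p$n - mean(p$x)^2), tolerance = 1e-12)
})

test_that("inconsistent counts are rejected with the tract id", {
  expect_error(compute_group_proportions(c(a = 1200), c(a = 1000)), "a")
  expect_error(compute_group_proportions(c(a = -1), c(a = 10)), "non-negative")
  expect_error(compute_group_proportions(c(a = 1), c(b = 10)), "same tract set")
})

test_that("the 3-chain reproduces the hand-derived Z-scores", {
  fx <- chain_fixture()
  z <- gi_star_unit(fx$props, fx$w)
  expect_equal(unname(z), c(0.70711, 0, -1.41421), tolerance = 1e-5)
  # the middle tract is the fully-connected limiting case, scored 0
  expect_identical(unname(z[2]), 0)
})

test_that("constant proportions raise the zero-variance condition", {
  fx <- chain_fixture(c(0.4, 0.4, 0.4))
  expect_error(gi_star_unit(fx$props, fx$w), class = "gistar_zero_variance")
})

test_that("Gi* is location-scale invariant", {
  set.seed(42)
  lat <- make_lattice(4, 4)
  w <- row_standardize_with_self(build_neighbor_graph(lat$polygons, "queen"))
  x <- setNames(runif(16, 0.1, 0.9), lat$fips)
  z0 <- gi_star_unit(props_from_x(x), w)
  for (ab in list(c(0.05, 0.1), c(-0.02, 0.3), c(0.5, 0.4))) {
    z1 <- gi_star_unit(props_from_x(ab[1] + ab[2] * x), w)
    expect_equal(z1, z0, tolerance = 1e-9)
  }
})

test_that("relabeling tracts permutes the output identically", {
  set.seed(99)
  lat <- make_lattice(3, 4)
  w <- row_standardize_with_self(build_neighbor_graph(lat$polygons, "queen"))
  x <- setNames(runif(12), lat$fips)
  z <- gi_star_unit(props_from_x(x), w)
  perm <- sample(names(x))
  z_perm <- gi_star_unit(props_from_x(x[perm]), w[perm])
  expect_equal(z_perm, z[perm], tolerance = 1e-12)
})

test_that("implementation agrees with the double-loop oracle on random units", {
  set.seed(2024)
  for (rep in 1:25) {
    polys <- perturbed_lattice(sample(2:6, 1), sample(2:6, 1))
    w <- row_standardize_with_self(
      build_neighbor_graph(polys, sample(c("queen", "rook"), 1)))
    x <- setNames(runif(length(polys)), names(polys))
    expect_equal(gi_star_unit(props_from_x(x), w), oracle_gi_star(x, w),
                 tolerance = 1e-10)
  }
})

test_that("a weights row referencing a tract outside the unit is rejected", {
  fx <- chain_fixture()
  w <- fx$w
  w[[1]]$weights <- c(w[[1]]$weights, stranger = 0.1)
  expect_error(gi_star_unit(fx$props, w), "outside the unit")
})
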