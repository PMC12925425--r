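big_square <- function(x0, y0, x1, y1) {
  gi_polygon(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

test_that("tracts inside a CBSA polygon are assigned to it, others to their county", {
  lat <- make_lattice(4, 4)                      # county 17031
  cbsa <- list("10420" = big_square(-0.5, -0.5, 2.5, 4.5))  # covers columns 1-2
  p <- assign_larger_unit(lat$polygons, cbsa)
  a <- p$assignment
  in_cbsa <- a$unit_kind == "cbsa"
  expect_identical(sum(in_cbsa), 8L)
  expect_true(all(a$unit_id[in_cbsa] == "10420"))
  expect_true(all(a$unit_id[!in_cbsa] == "17031"))
  # units is the exact inverse of assignment
  expect_setequal(unlist(p$units), a$fips)
  expect_identical(sort(p$units[["cbsa:10420"]]), sort(a$fips[in_cbsa]))
})

test_that("county fallback is lexical and applies to all tracts without a CBSA layer", {
  lat <- make_lattice(2, 3, state = "06", county = "075")
  p <- assign_larger_unit(lat$polygons)
  expect_true(all(p$assignment$unit_kind == "county"))
  expect_true(all(p$assignment$unit_id == "06075"))
  expect_identical(names(p$units), "county:06075")
  # identifier arriving in the zero-stripped numeric dialect still lands
  # in the zero-padded county
  one <- lat$polygons[1]
  names(one) <- sub("^0", "", names(one))
  expect_identical(assign_larger_unit(one)$assignment$unit_id, "06075")
})

test_that("overlapping CBSA polygons are rejected with both unit ids", {
  lat <- make_lattice(1, 1)
  cbsa <- list(A = big_square(-1, -1, 2, 2), B = big_square(-2, -2, 3, 3))
  expect_error(assign_larger_unit(lat$polygons, cbsa), "A, B")
})

test_that("assignment partitions the tract set and is deterministic", {
  set.seed(5)
  polys <- perturbed_lattice(5, 5)
  names(polys) <- gistar:::mint_fips(length(polys))
  cbsa <- list("20100" = big_square(-1, -1, 2.6, 2.6))
  p1 <- assign_larger_unit(polys, cbsa)
  p2 <- assign_larger_unit(polys, cbsa)
  expect_identical(p1, p2)
  expect_identical(sum(lengths(p1$units)), length(polys))
  expect_identical(anyDuplicated(unlist(p1$units)), 0L)
})

test_that("the representative point is interior even for concave tracts", {
  cshape <- gi_polygon(rbind(c(0, 0), c(3, 0), c(3, 1), c(1, 1),
                             c(1, 2), c(3, 2), c(3, 3), c(0, 3)))
  # centroid of this C-shape lies in the notch, outside the polygon
  rp <- representative_point(cshape)
  expect_true(point_in_geom(rp, cshape))
  holed <- gi_polygon(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
                      holes = list(rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3))))
  rp2 <- representative_point(holed)
  expect_true(point_in_geom(rp2, holed))
})
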