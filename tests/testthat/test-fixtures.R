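test_that("make_lattice mints unique 11-digit identifiers on a proper grid", {
  lat <- make_lattice(3, 3)
  expect_length(lat$polygons, 9L)
  expect_true(all(nchar(lat$fips) == 11L))
  expect_identical(anyDuplicated(lat$fips), 0L)
  expect_s3_class(parse_fips(lat$fips), "fips_id")  # validates like real data
  expect_length(make_lattice(1, 1)$polygons, 1L)
  expect_error(make_lattice(0, 3), "at least 1")
})

test_that("population draws are seeded and reproducible", {
  lat <- make_lattice(4, 4)
  p1 <- make_population(lat, seed = 123)
  p2 <- make_population(lat, seed = 123)
  p3 <- make_population(lat, seed = 124)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  # the caller's RNG state is untouched
  set.seed(55); before <- .Random.seed
  make_population(lat, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("uniform scenarios respect count constraints and have no empty tracts", {
  lat <- make_lattice(5, 5)
  pop <- make_population(lat, seed = 9)
  groups <- gistar_default_groups()
  expect_true(all(pop$total > 0))
  expect_true(all(rowSums(pop[groups]) <= pop$total))
  expect_true(all(vapply(pop[groups], is.integer, TRUE)))
})

test_that("planted clusters hit the target share on average", {
  lat <- make_lattice(3, 3)
  p_in <- 0.8; total <- 1000; reps <- 100
  block <- c(outer(2:3, 2:3, function(r, c) lattice_id(lat, r, c)))
  shares <- vapply(seq_len(reps), function(s) {
    pop <- make_population(lat, scenario = "planted_cluster",
                           target_group = "nhBlack",
                           cluster_rows = 2:3, cluster_cols = 2:3,
                           p_in = p_in, p_out = 0.1, total = total, seed = s)
    mean(pop$nhBlack[pop$FIPS_ID %in% block] / total)
  }, 0)
  se <- sqrt(p_in * (1 - p_in) / total) / sqrt(reps * length(block))
  expect_lt(abs(mean(shares) - p_in), 3 * se)
})

test_that("scenario parameters are validated", {
  lat <- make_lattice(3, 3)
  expect_error(make_population(lat, scenario = "planted_cluster",
                               cluster_rows = 1, cluster_cols = 1,
                               p_in = 0.2, p_out = 0.5), "p_out <= p_in")
  expect_error(make_population(lat, scenario = "planted_cluster"),
               "cluster_rows")
  expect_error(make_population(lat, shares = c(a = 0.9, b = 0.9)),
               "at most 1")
})

test_that("every degenerate fixture round-trips through files to its code", {
  td <- withr::local_tempdir()
  for (code in gistar_codes()) {
    fx <- make_degenerate_fixture(code)
    geo <- file.path(td, sprintf("g%d.geojson", abs(code)))
    popf <- file.path(td, sprintf("p%d.csv", abs(code)))
    write_geojson(fx$geometry, geo)
    write.csv(fx$population, popf, row.names = FALSE)
    res <- run_pipeline(geo, popf,
                        config = run_config(contiguity = fx$contiguity))
    expect_identical(nrow(res), length(fx$geometry))
    for (k in seq_len(nrow(fx$expected))) {
      got <- res[res$FIPS_ID == fx$expected$fips[k],
                 paste0(fx$expected$group[k], "_Gstat")]
      expect_identical(got, as.numeric(fx$expected$code[k]),
                       info = sprintf("code %d cell %s/%s", code,
                                      fx$expected$fips[k], fx$expected$group[k]))
    }
  }
  expect_error(make_degenerate_fixture(-42), "unknown indicator code")
})
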