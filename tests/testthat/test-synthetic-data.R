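test_that("generated rasters hit target fractions and are seed-deterministic", {
  specs <- dplyr::bind_rows(class_spec(1, 0.5, 0), class_spec(2, 0.5, 0))
  r1 <- generate_landuse_raster(64, 64, specs, seed = 7)
  r2 <- generate_landuse_raster(64, 64, specs, seed = 7)
  expect_identical(r1$values, r2$values)
  fr <- class_fractions(r1)
  expect_lt(max(abs(fr - 0.5)), 0.05)
  r3 <- generate_landuse_raster(64, 64, specs, seed = 8)
  expect_false(identical(r1$values, r3$values))

  # multi-class with clumping: every class within tolerance
  specs6 <- dplyr::bind_rows(
    class_spec(1, 0.55, 50), class_spec(2, 0.2, 20), class_spec(3, 0.1, 10),
    class_spec(4, 0.08, 5), class_spec(5, 0.04, 2), class_spec(6, 0.03, 2)
  )
  r6 <- generate_landuse_raster(48, 48, specs6, seed = 11)
  fr6 <- class_fractions(r6)
  expect_lt(max(abs(fr6 - specs6$target_fraction)), 0.05)
  expect_true(all(!is.na(r6$values)))
})

test_that("a single class with fraction 1 yields a uniform one-patch raster", {
  r <- generate_landuse_raster(8, 8, class_spec(4, 1, 0), seed = 1)
  expect_true(all(r$values == 4L))
  expect_equal(nrow(label_patches(r)), 1)
})

test_that("invalid class specifications are rejected", {
  bad <- dplyr::bind_rows(class_spec(1, 0.6, 0), class_spec(2, 0.5, 0))
  expect_error(generate_landuse_raster(16, 16, bad, seed = 1), "sum to 1")
  dup <- dplyr::bind_rows(class_spec(1, 0.5, 0), class_spec(1, 0.5, 0))
  expect_error(generate_landuse_raster(16, 16, dup, seed = 1), "unique")
  expect_error(generate_landuse_raster(4, 4, class_spec(1, 1, 0), seed = 1),
               "at least 8")
  tiny <- dplyr::bind_rows(class_spec(1, 0.9995, 0), class_spec(2, 0.0005, 0))
  expect_error(generate_landuse_raster(8, 8, tiny, seed = 1), "too small")
})

test_that("patch inventory of a generated raster matches the flood-fill oracle", {
  r <- demo_raster_2class(n = 32, seed = 3)
  got <- label_patches(r)
  want <- flood_fill_patches(r$values)
  expect_identical(patch_signature(as.data.frame(got)),
                   patch_signature(want))
})

test_that("mean patch count is non-increasing in clumping", {
  mean_patches <- function(clump) {
    mean(vapply(1:5, function(s) {
      r <- demo_raster_2class(n = 32, seed = s, clump = c(clump, clump))
      nrow(label_patches(r))
    }, numeric(1)))
  }
  counts <- vapply(c(0, 2, 10, 50), mean_patches, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("evolve_landuse applies rules only to eligible cells and conserves the grid", {
  r <- demo_raster_2class(n = 16, seed = 5)
  # no rules: identity
  same <- evolve_landuse(r, transition_rule(1, 2, 0)[0, ], seed = 1)
  expect_identical(same$values, r$values)
  # rate 1: no source cells remain
  gone <- evolve_landuse(r, transition_rule(1, 2, 1), seed = 1)
  expect_false(any(gone$values == 1L))
  expect_identical(dim(gone$values), dim(r$values))
  expect_true(all(gone$values %in% as.integer(r$legend)))
  # unknown code rejected
  expect_error(evolve_landuse(r, transition_rule(9, 2, 0.5), seed = 1),
               "absent")
})

test_that("conversion counts are binomial: mean over seeds within 3 s.e.", {
  m <- matrix(1L, 40, 25)                       # exactly 1000 eligible cells
  r <- land_raster(m, legend = c(a = 1L, b = 2L))
  rule <- transition_rule(1, 2, rate = 0.3, adjacency_bias = 1)
  conv <- vapply(1:200, function(s)
    sum(evolve_landuse(r, rule, seed = s)$values == 2L), numeric(1))
  se <- sqrt(1000 * 0.3 * 0.7 / 200)
  expect_lt(abs(mean(conv) - 300), 3 * se)
})

test_that("random-field points honor the pure-nugget variogram and preconditions", {
  spec <- field_spec("spherical", nugget = 1, partial_sill = 0, range_ = 10)
  emps <- lapply(1:10, function(s) {
    pts <- generate_autocorrelated_points(200, c(0, 100, 0, 100), spec,
                                          seed = s)
    empirical_variogram(pts, n_lags = 8, max_dist = 50)
  })
  pooled <- pool_empirical_variograms(emps)
  expect_lt(max(abs(pooled$gamma - 1)), 0.1)   # flat at the nugget

  expect_error(generate_autocorrelated_points(10, c(0, 1, 0, 1), spec, 1),
               "at least 30")
  expect_error(generate_autocorrelated_points(50, c(0, 0, 0, 1), spec, 1),
               "extent")
  p1 <- generate_autocorrelated_points(50, c(0, 1, 0, 1), spec, 3)
  p2 <- generate_autocorrelated_points(50, c(0, 1, 0, 1), spec, 3)
  expect_identical(p1, p2)
})

test_that("ascii grid round-trips a raster exactly", {
  r <- demo_raster_2class(n = 16, seed = 2)
  r$values[1, 1] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path, legend = r$legend)
  expect_identical(back$values, r$values)
  expect_equal(back$cell_size, r$cell_size)
  expect_equal(back$xll, r$xll)
})
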