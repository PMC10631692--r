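test_that("empirical variogram matches hand-enumerated pairs", {
  # 3 collinear points, values 0/1/0, unit spacing, 2 bins over max_dist 2:
  # gamma(1) = ((0-1)^2 + (1-0)^2) / (2*2) = 0.5; gamma(2) = 0
  pts <- tibble::tibble(x = c(0, 1, 2), y = 0, value = c(0, 1, 0))
  expect_warning(emp <- empirical_variogram(pts, n_lags = 2, max_dist = 2),
                 "unreliable")
  expect_equal(emp$gamma, c(0.5, 0))
  expect_equal(emp$n_pairs, c(2L, 1L))

  # constant field: flat zero
  withr::with_seed(1, {
    cpts <- tibble::tibble(x = runif(40), y = runif(40), value = 2)
  })
  empc <- empirical_variogram(cpts, n_lags = 5)
  expect_true(all(empc$gamma == 0))
})

test_that("model fitting is exact on noiseless model-generated curves", {
  for (family in c("spherical", "exponential")) {
    h <- seq(2, 60, by = 4)
    emp <- tibble::tibble(
      bin = seq_along(h), h = h,
      gamma = variogram_curve(h, family, 0.1, 0.9, 30),
      n_pairs = rep(100L, length(h))
    )
    attr(emp, "bin_width") <- 4
    class(emp) <- c("empirical_variogram", class(emp))
    vm <- fit_variogram_model(emp, family)
    expect_equal(vm$nugget, 0.1, tolerance = 1e-6)
    expect_equal(vm$sill, 1.0, tolerance = 1e-6)
    expect_equal(vm$range_, 30, tolerance = 1e-5)
  }
  small <- tibble::tibble(bin = 1:3, h = 1:3, gamma = 1:3 / 3, n_pairs = 5L)
  expect_error(fit_variogram_model(small, "spherical"), "at least 4")
})

test_that("parameters are recovered from simulated fields (pooled seeds)", {
  for (family in c("spherical", "exponential")) {
    errs <- variogram_recovery_errors(family, seeds = 1:10)
    expect_lt(errs[["nugget"]], 0.25)
    expect_lt(errs[["sill"]], 0.25)
    expect_lt(errs[["range"]], 0.25)
  }
})

test_that("nugget/sill ratio reproduces reported percentages", {
  expect_equal(nugget_sill_ratio(0.90281e-5, 0.48700e-4), 18.5,
               tolerance = 0.1 / 18.5)
  expect_equal(nugget_sill_ratio(0.24545e-4, 0.17858e-3), 13.7,
               tolerance = 0.1 / 13.7)
  expect_equal(nugget_sill_ratio(0, 2), 0)
  expect_error(nugget_sill_ratio(1, 0), "positive")
})

test_that("ordinary kriging is exact, unbiased, and matches the matrix oracle", {
  model <- fit_variogram_model(
    structure(tibble::tibble(bin = 1:8, h = seq(5, 40, 5),
                             gamma = variogram_curve(seq(5, 40, 5),
                                                     "spherical", 0, 1, 30),
                             n_pairs = 50L),
              bin_width = 5, class = c("empirical_variogram", "data.frame")),
    "spherical")
  withr::with_seed(2, {
    pts <- tibble::tibble(x = runif(25, 0, 50), y = runif(25, 0, 50),
                          value = rnorm(25))
  })
  # exactness at data points for a nugget-0 model
  at_data <- ordinary_kriging(model, pts, pts[1:10, c("x", "y")])
  expect_equal(at_data$pred, pts$value[1:10], tolerance = 1e-9)
  expect_lt(max(at_data$var), 1e-9)

  # symmetry: equidistant equal-valued points predict their common value
  sym3 <- ordinary_kriging(model,
                           tibble::tibble(x = c(-5, 5, 0), y = c(0, 0, 40),
                                          value = c(7, 7, 7)),
                           tibble::tibble(x = 0, y = 0))
  expect_equal(sym3$pred, 7)

  # 5-point weights equal explicit matrix inversion
  p5 <- pts[1:5, ]
  target <- c(20, 20)
  got <- ordinary_kriging(model, p5, tibble::tibble(x = 20, y = 20))
  w_or <- brute_kriging_weights(model, p5, target)
  expect_equal(got$pred, sum(w_or * p5$value), tolerance = 1e-9)
  expect_equal(sum(w_or), 1, tolerance = 1e-9)

  # kriging variance grows monotonically along a ray leaving the data cloud
  ray <- tibble::tibble(x = seq(50, 120, 10), y = 25)
  kv <- ordinary_kriging(model, pts, ray)$var
  expect_true(all(diff(kv) > -1e-12))

  # duplicate locations are averaged with a warning
  dup <- dplyr::bind_rows(pts[1:5, ], pts[1, ])
  expect_warning(ordinary_kriging(model, dup, tibble::tibble(x = 1, y = 1)),
                 "duplicate")
  expect_error(ordinary_kriging(model, pts[1:2, ], tibble::tibble(x = 0, y = 0)),
               "at least 3")
})
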