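test_that("fishnet tiles square boundaries exactly and clips edge cells", {
  net <- build_fishnet(square_boundary(30000), 10)
  expect_equal(nrow(net), 9)
  expect_equal(unique(net$area), 1e8)           # all full 100 km^2 cells

  net25 <- build_fishnet(square_boundary(25000), 10)
  expect_equal(nrow(net25), 9)
  expect_setequal(unique(net25$area) / 1e6, c(100, 50, 25))
  # conservation: clipped areas sum to the boundary area
  expect_equal(sum(net25$area), 25000^2)

  expect_error(build_fishnet(square_boundary(1000), 0), "positive")
  expect_error(build_fishnet(rbind(c(0, 0), c(1, 1)), 10), "valid polygon")
})

test_that("fishnet area conservation holds for an irregular boundary", {
  poly <- rbind(c(2000, 1000), c(52000, 4000), c(61000, 30000),
                c(30000, 58000), c(500, 41000))
  for (cell_km in c(5, 10)) {
    net <- build_fishnet(poly, cell_km, min_area_frac = 0)
    expect_lt(abs(sum(net$area) - polygon_area(poly)) / polygon_area(poly),
              1e-3)
  }
})

test_that("per-cell ERI is the class-area-weighted loss and stays convex", {
  # 20x20 km boundary, 10 km cells -> 4 cells of 100 raster cells each
  net <- build_fishnet(square_boundary(20000), 10)
  m <- matrix(1L, 20, 20)
  m[, 11:20] <- 2L                              # right half rubber
  m[1:10, 1:10] <- 1L
  r <- land_raster(m, cell_size = 1000)
  loss <- c(`1` = 0.026, `2` = 0.106)
  g <- compute_eri(net, r, loss)
  expect_equal(sort(unique(round(g$eri, 6))), c(0.026, 0.106))

  # half-and-half cell: hand arithmetic
  m2 <- matrix(1L, 10, 10); m2[, 6:10] <- 2L
  net1 <- build_fishnet(square_boundary(10000), 10)
  g2 <- compute_eri(net1, land_raster(m2, cell_size = 1000), loss)
  expect_equal(g2$eri, 0.5 * 0.026 + 0.5 * 0.106)

  # convexity on a random raster: min R <= ERI <= max R
  r3 <- demo_raster_2class(n = 40, seed = 6)
  net3 <- build_fishnet(square_boundary(40000), 10)
  g3 <- compute_eri(net3, r3, loss)
  expect_true(all(g3$eri >= 0.026 - 1e-12 & g3$eri <= 0.106 + 1e-12))

  expect_error(compute_eri(net3, r3, c(`1` = 0.1)), "loss index")
})

test_that("area-weighted mean ERI is invariant to fishnet refinement", {
  r <- demo_raster_2class(n = 48, seed = 21)
  loss <- c(`1` = 0.03, `2` = 0.2)
  b <- square_boundary(48000)
  m1 <- with(compute_eri(build_fishnet(b, 12), r, loss),
             sum(eri * area) / sum(area))
  m2 <- with(compute_eri(build_fishnet(b, 6), r, loss),
             sum(eri * area) / sum(area))
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("grade classification uses left-closed intervals with I = safest", {
  g <- classify_grades(c(0.041, 0.045, 0.058, 0.042, 0, 1))
  expect_equal(as.character(g), c("I", "II", "IV", "II", "I", "V"))
  expect_true(is.ordered(g))
  expect_error(classify_grades(c(0.5, 1.2)), "lie in")
  expect_error(classify_grades(c(0.5, NA)), "finite")
})

test_that("exact Jenks breaks isolate well-separated clusters", {
  vals <- rep(c(1, 5, 9, 13, 17), each = 3)
  sch <- jenks_scheme(vals, k = 5)
  oracle <- brute_jenks_starts(vals, 5)
  # oracle class starts at sorted positions 4, 7, 10, 13 -> breaks between
  # cluster values
  expect_equal(oracle$starts, c(1, 4, 7, 10, 13))
  expect_equal(sch$breaks, c(3, 7, 11, 15))
  expect_equal(sch$provenance, "jenks")
  # classification splits the clusters one grade each
  g <- classify_grades(vals / max(vals), grade_scheme(sch$breaks / max(vals)))
  expect_equal(as.integer(table(g)), rep(3L, 5))
})

test_that("grade area proportions are area-weighted and sum to 100", {
  grades <- factor(c("I", "I", "I", "II", "II", "II", "V", "V", "V"),
                   levels = c("I", "II", "III", "IV", "V"), ordered = TRUE)
  p <- grade_area_proportions(grades, rep(1, 9))
  expect_equal(p$pct, c(100 / 3, 100 / 3, 0, 0, 100 / 3))
  expect_equal(sum(p$pct), 100, tolerance = 1e-6)

  # clipped-cell weighting: a 25 km square fishnet has unequal cell areas
  net25 <- build_fishnet(square_boundary(25000), 10)
  gr <- factor(rep("I", 9), levels = c("I", "II", "III", "IV", "V"),
               ordered = TRUE)
  gr[net25$area == 25e6] <- "V"                 # the corner cell
  p2 <- grade_area_proportions(gr, net25$area)
  expect_equal(p2$pct[p2$grade == "V"], 100 * 25 / 625)
})

test_that("grade transition matrices tally areas with exact marginals", {
  net <- build_fishnet(square_boundary(40000), 10)
  r <- demo_raster_2class(n = 40, seed = 13)
  g1 <- compute_eri(net, r, c(`1` = 0.03, `2` = 0.2))
  withr::with_seed(99, {
    g1$grade <- factor(sample(c("I", "II", "III", "IV", "V"), nrow(g1), TRUE),
                       levels = c("I", "II", "III", "IV", "V"), ordered = TRUE)
  })
  # identity transition is diagonal
  m_id <- grade_transition_matrix(g1, g1)
  expect_true(all(m_id[row(m_id) != col(m_id)] == 0))

  g2 <- g1
  withr::with_seed(100, {
    g2$grade <- factor(sample(c("I", "II", "III", "IV", "V"), nrow(g2), TRUE),
                       levels = c("I", "II", "III", "IV", "V"), ordered = TRUE)
  })
  m <- grade_transition_matrix(g1, g2)
  # brute-force pairwise tally
  for (a in 1:5) for (b in 1:5) {
    sel <- as.integer(g1$grade) == a & as.integer(g2$grade) == b
    expect_equal(m[a, b], sum(g1$area[sel]) / 1e6)
  }
  # marginals equal each epoch's grade areas
  pa <- grade_area_proportions(g1$grade, g1$area)
  pb <- grade_area_proportions(g2$grade, g2$area)
  expect_equal(unname(rowSums(m)), pa$area / 1e6)
  expect_equal(unname(colSums(m)), pb$area / 1e6)
  expect_equal(sum(m), sum(g1$area) / 1e6)

  g3 <- g2[-1, ]
  expect_error(grade_transition_matrix(g1, g3), "same fishnet")
})
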