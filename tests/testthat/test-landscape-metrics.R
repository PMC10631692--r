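test_that("patch labeling handles minimal and checkerboard geometries", {
  one <- land_raster(matrix(1L, 1, 1))
  # a 1x1 raster is below generator limits but valid for labeling
  p1 <- label_patches(one)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$cell_count, 1L)
  expect_equal(p1$perimeter, 4L)

  cb <- land_raster(matrix(c(1L, 2L, 2L, 1L), 2, 2))
  p <- label_patches(cb)
  expect_equal(nrow(p), 4)                       # rook disconnects diagonals
  expect_true(all(p$cell_count == 1L))
  expect_true(all(p$perimeter == 4L))

  allna <- land_raster(matrix(NA_integer_, 2, 2))
  expect_error(label_patches(allna), "no non-nodata")
})

test_that("patch labeling equals the flood-fill oracle on random rasters", {
  for (s in c(3, 17)) {
    specs <- dplyr::bind_rows(class_spec(1, 0.4, 1), class_spec(2, 0.35, 5),
                              class_spec(3, 0.25, 0))
    r <- generate_landuse_raster(64, 64, specs, seed = s)
    got <- label_patches(r)
    expect_identical(patch_signature(as.data.frame(got)),
                     patch_signature(flood_fill_patches(r$values)))
  }
  # with nodata holes
  r <- demo_raster_2class(n = 24, seed = 9)
  r$values[sample(seq_len(576), 60)] <- NA_integer_
  expect_identical(patch_signature(as.data.frame(label_patches(r))),
                   patch_signature(flood_fill_patches(r$values)))
})

test_that("structure metrics match closed forms for simple landscapes", {
  # one class, one patch covering everything: C = 1/A, S = sqrt(1/A)/2
  r <- land_raster(matrix(1L, 10, 10), cell_size = 1000)
  m <- class_structure_metrics(label_patches(r))
  A <- 100 * 1000^2 / 1e8                       # cells -> 1e4 hm^2
  expect_equal(m$C, 1 / A)
  expect_equal(m$S, 0.5 * sqrt(1 / A))
  # a full square patch has fractal dimension exactly 1
  expect_equal(m$D, 1)

  # square k^2-cell patch in a larger matrix: D = 2 ln(4k/4) / ln(k^2) = 1
  mat <- matrix(2L, 12, 12); mat[4:9, 4:9] <- 1L
  ms <- class_structure_metrics(label_patches(land_raster(mat)))
  expect_equal(ms$D[ms$class_code == 1], 1)
})

test_that("per-class metrics equal an exhaustive per-patch recomputation", {
  r <- demo_raster_2class(n = 64, seed = 11)
  got <- class_structure_metrics(label_patches(r))
  oracle <- flood_fill_patches(r$values)
  cell_unit <- r$cell_size^2 / 1e8
  A_tot <- sum(oracle$cell_count) * cell_unit
  for (cls in unique(oracle$class_code)) {
    sub <- oracle[oracle$class_code == cls, ]
    n_i <- nrow(sub)
    A_i <- sum(sub$cell_count) * cell_unit
    D_i <- mean(ifelse(sub$cell_count == 1, 1,
                       2 * log(sub$perimeter / 4) / log(sub$cell_count)))
    row <- got[got$class_code == cls, ]
    expect_equal(row$C, n_i / A_i)
    expect_equal(row$S, 0.5 * sqrt(n_i / A_tot) * (A_tot / A_i))
    expect_equal(row$D, D_i)
  }
})

test_that("C and S transform as predicted when the cell area unit doubles", {
  r <- demo_raster_2class(n = 32, seed = 4)
  p <- label_patches(r)
  m1 <- class_structure_metrics(p, cell_area_unit = 0.01)
  m2 <- class_structure_metrics(p, cell_area_unit = 0.02)
  expect_equal(m2$C, m1$C / 2)                  # patches per doubled area
  expect_equal(m2$S, m1$S / sqrt(2))            # sqrt(n/A) halves under A->2A
  expect_equal(m2$D, m1$D)                      # dimension is unit-free
})

test_that("disturbance index is the exact weighted sum and is linear", {
  w <- disturbance_weights(0.5, 0.3, 0.2)
  expect_equal(disturbance_index(0.004, 0.037, 1.252, w), 0.2635)
  expect_equal(disturbance_index(0.082, 1.387, 1.253, w), 0.7077)
  expect_equal(disturbance_index(0.622, 2.715, 1.339, w), 1.3933)
  # degenerate weights pick out one component
  expect_equal(disturbance_index(0.3, 9, 9, disturbance_weights(1, 0, 0)), 0.3)
  # linearity
  expect_equal(disturbance_index(0.2, 0.4, 1.6, w),
               2 * disturbance_index(0.1, 0.2, 0.8, w))
  expect_error(disturbance_index(-1, 0, 0, w), "non-negative")
  expect_error(disturbance_weights(0.5, 0.3, 0.3), "sum to 1")
})

test_that("loss index is the exact product of disturbance and vulnerability", {
  expect_equal(loss_index(0.379, 0.28), 0.10612)
  expect_equal(loss_index(0.903, 0.24), 0.21672)
  expect_equal(loss_index(5, 0), 0)
  expect_error(loss_index(-1, 0.5), "non-negative")
  expect_error(loss_index(1, 1.5), "\\[0, 1\\]")
})

test_that("metrics_table assembles per-epoch rows with R = E * F row-wise", {
  specs <- dplyr::bind_rows(class_spec(1, 0.7, 30), class_spec(2, 0.3, 10))
  r1 <- generate_landuse_raster(32, 32, specs, seed = 1)
  r2 <- evolve_landuse(r1, transition_rule(1, 2, 0.1), seed = 2)
  vul <- c(`1` = 0.10, `2` = 0.28)
  tab <- metrics_table(list(e1 = r1, e2 = r2), vulnerability = vul)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$R, tab$E * tab$F)
  expect_equal(tab$E, disturbance_index(tab$C, tab$S, tab$D))
  # rubber area grows under a forest->rubber rule
  rubber <- tab[tab$class_code == 2, ]
  expect_gt(rubber$area[rubber$epoch == "e2"],
            rubber$area[rubber$epoch == "e1"])

  r_bad <- land_raster(matrix(3L, 32, 32))
  expect_error(metrics_table(list(r1, r_bad), vulnerability = vul), "legend")
})
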