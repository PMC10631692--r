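# Independent brute-force oracles. These deliberately share no code with the
# package implementation: flood fill instead of graph components, explicit
# double loops instead of vectorized algebra.

# queue-based flood fill over rook neighbors; returns one row per patch
flood_fill_patches <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0] || is.na(mat[r0, c0])) next
    cls <- mat[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    cells <- list()
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells[[length(cells) + 1]] <- cur
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cur[1] + d[1]; cc <- cur[2] + d[2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc && !seen[r, cc] &&
            !is.na(mat[r, cc]) && mat[r, cc] == cls) {
          seen[r, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(r, cc)
        }
      }
    }
    perim <- 0
    for (cur in cells) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cur[1] + d[1]; cc <- cur[2] + d[2]
        if (r < 1 || r > nr || cc < 1 || cc > nc || is.na(mat[r, cc]) ||
            mat[r, cc] != cls) perim <- perim + 1
      }
    }
    out[[length(out) + 1]] <-
      data.frame(class_code = cls, cell_count = length(cells),
                 perimeter = perim)
  }
  do.call(rbind, out)
}

# canonical multiset of patches for comparing inventories
patch_signature <- function(df) {
  df <- df[order(df$class_code, df$cell_count, df$perimeter), ]
  paste(df$class_code, df$cell_count, df$perimeter, sep = ":", collapse = ";")
}

# direct evaluation of the global Moran's I double sum
brute_moran <- function(values, W) {
  n <- length(values)
  xb <- mean(values)
  s2 <- sum((values - xb)^2) / n
  num <- 0; s0 <- 0
  for (i in seq_len(n)) {
    nb <- W$neighbors[[i]]
    for (k in seq_along(nb)) {
      j <- nb[k]; w <- W$weights[[i]][k]
      num <- num + w * (values[i] - xb) * (values[j] - xb)
      s0 <- s0 + w
    }
  }
  num / (s2 * s0)
}

# GM(1,1) coefficients by explicit normal equations
gm11_normal_equations <- function(x0, alpha = 0.5) {
  n <- length(x0)
  x1 <- cumsum(x0)
  z <- alpha * x1[2:n] + (1 - alpha) * x1[1:(n - 1)]
  B <- cbind(-z, rep(1, n - 1))
  Y <- x0[2:n]
  sol <- solve(t(B) %*% B) %*% t(B) %*% Y
  c(a = sol[1, 1], b = sol[2, 1])
}

# exhaustive Jenks: best k-partition of sorted x by scanning all break
# combinations
brute_jenks_starts <- function(x, k) {
  x <- sort(x); n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  combos <- utils::combn(2:n, k - 1)
  best <- NULL; best_cost <- Inf
  for (j in seq_len(ncol(combos))) {
    starts <- c(1, combos[, j])
    ends <- c(starts[-1] - 1, n)
    cost <- sum(vapply(seq_len(k), function(m) ssd(x[starts[m]:ends[m]]),
                       numeric(1)))
    if (cost < best_cost) { best_cost <- cost; best <- starts }
  }
  list(starts = best, cost = best_cost, sorted = x)
}

# kriging weights for one target by explicit matrix inversion
brute_kriging_weights <- function(model, points, target) {
  n <- nrow(points)
  gamma_fn <- function(h) variogram_curve(h, model$family, model$nugget,
                                          model$psill, model$range_)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt((points$x[i] - points$x[j])^2 + (points$y[i] - points$y[j])^2)
    A[i, j] <- gamma_fn(h)
  }
  A[n + 1, seq_len(n)] <- 1; A[seq_len(n), n + 1] <- 1
  b <- c(vapply(seq_len(n), function(i)
    gamma_fn(sqrt((points$x[i] - target[1])^2 + (points$y[i] - target[2])^2)),
    numeric(1)), 1)
  (solve(A) %*% b)[seq_len(n)]
}

# variogram recovery experiment: pooled over replicate seeds (see the
# methods vignette for the design)
variogram_recovery_errors <- function(family, seeds, nugget = 0.1,
                                      psill = 0.9, range_ = 30,
                                      n_points = 400, extent = 150,
                                      max_dist = 105, n_lags = 12) {
  spec <- field_spec(family, nugget = nugget, partial_sill = psill,
                     range_ = range_)
  emps <- lapply(seeds, function(s) {
    pts <- generate_autocorrelated_points(n_points, c(0, extent, 0, extent),
                                          spec, seed = s)
    empirical_variogram(pts, n_lags = n_lags, max_dist = max_dist)
  })
  vm <- fit_variogram_model(pool_empirical_variograms(emps), family)
  sill_true <- nugget + psill
  c(nugget = abs(vm$nugget - nugget) / sill_true,
    sill = abs(vm$sill - sill_true) / sill_true,
    range = abs(vm$range_ - range_) / range_)
}

# small deterministic two-class raster used across tests
demo_raster_2class <- function(n = 32, seed = 3, clump = c(10, 10)) {
  specs <- dplyr::bind_rows(
    class_spec(1, 0.6, clumping = clump[1]),
    class_spec(2, 0.4, clumping = clump[2])
  )
  generate_landuse_raster(n, n, specs, seed = seed)
}

square_boundary <- function(side_m) {
  rbind(c(0, 0), c(side_m, 0), c(side_m, side_m), c(0, side_m))
}
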