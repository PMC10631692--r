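#' Contiguity spatial weights for a fishnet
#'
#' Rook contiguity links cells sharing an edge (grid row/col neighbors);
#' queen also links diagonal neighbors. Optionally row-standardized.
#'
#' @param net a [build_fishnet()] grid (or any tibble with `grid_row`,
#'   `grid_col`).
#' @param scheme `"rook"` or `"queen"`.
#' @param standardize row-standardize the weights (default TRUE).
#' @return a `spatial_weights` list: `n`, `neighbors` (list of integer
#'   vectors), `weights` (list of numeric vectors), `scheme`, `standardized`.
#'   Island cells (no neighbors) trigger a warning.
#' @export
build_weights <- function(net, scheme = c("rook", "queen"),
                          standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(net)
  if (n < 2) abort("need at least 2 cells")
  r <- net$grid_row; c_ <- net$grid_col
  offsets <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (scheme == "queen")
    offsets <- c(offsets, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  key <- paste(r, c_)
  lut <- setNames(seq_len(n), key)
  neighbors <- vector("list", n)
  for (off in offsets) {
    j <- unname(lut[paste(r + off[1], c_ + off[2])])
    ok <- !is.na(j)
    for (i in which(ok)) neighbors[[i]] <- c(neighbors[[i]], j[i])
  }
  neighbors <- lapply(neighbors, function(x) sort(unique(x)))
  islands <- which(vapply(neighbors, length, 1L) == 0)
  if (length(islands) > 0)
    warn(paste0("island cell(s) with no neighbors: ",
                paste(islands, collapse = ", ")))
  weights <- lapply(neighbors, function(nb) {
    if (length(nb) == 0) numeric(0)
    else if (standardize) rep(1 / length(nb), length(nb))
    else rep(1, length(nb))
  })
  structure(list(n = n, neighbors = neighbors, weights = weights,
                 scheme = scheme, standardized = standardize),
            class = "spatial_weights")
}

# spatial lag: (Wx)_i = sum_j w_ij x_j
spatial_lag <- function(W, x) {
  vapply(seq_len(W$n), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0) 0 else sum(W$weights[[i]] * x[nb])
  }, numeric(1))
}

sum_weights <- function(W) sum(vapply(W$weights, sum, numeric(1)))

# S1, S2 for the normality variance of Moran's I
moran_s1_s2 <- function(W) {
  n <- W$n
  wmat_row <- vapply(seq_len(n), function(i) sum(W$weights[[i]]), numeric(1))
  wmat_col <- numeric(n)
  for (i in seq_len(n))
    wmat_col[W$neighbors[[i]]] <- wmat_col[W$neighbors[[i]]] + W$weights[[i]]
  s1 <- 0
  for (i in seq_len(n)) {
    nb <- W$neighbors[[i]]; wi <- W$weights[[i]]
    wji <- vapply(seq_along(nb), function(k) {
      j <- nb[k]
      pos <- match(i, W$neighbors[[j]])
      if (is.na(pos)) 0 else W$weights[[j]][pos]
    }, numeric(1))
    s1 <- s1 + sum((wi + wji)^2)
  }
  s1 <- s1 / 2
  s2 <- sum((wmat_row + wmat_col)^2)
  list(s1 = s1, s2 = s2)
}

#' Global Moran's I
#'
#' `I = n / S0 * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the mean-deviated
#' values and `S0` the total weight. Inference both ways: a normality
#' z-score/p-value and a seeded permutation test (pseudo p-value one-sided in
#' the direction of the observed statistic).
#'
#' @param values numeric vector aligned with the weights (non-constant).
#' @param W a [build_weights()] object.
#' @param n_permutations permutations for the pseudo p-value (default 999).
#' @param seed integer seed for the permutation draw.
#' @return a `moran_result` list: `I`, `expected` (= -1/(n-1)), `z_norm`,
#'   `p_norm`, `p_perm`, `n`, `n_permutations`.
#' @export
global_morans_i <- function(values, W, n_permutations = 999, seed = 1) {
  n <- W$n
  if (length(values) != n) abort("values not aligned with weights")
  if (var(values) == 0) abort("constant field has undefined Moran's I")
  z <- values - mean(values)
  s0 <- sum_weights(W)
  stat <- function(z) n / s0 * sum(z * spatial_lag(W, z)) / sum(z^2)
  I <- stat(z)
  e_i <- -1 / (n - 1)
  ss <- moran_s1_s2(W)
  var_norm <- (n^2 * ss$s1 - n * ss$s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - e_i^2
  z_norm <- (I - e_i) / sqrt(var_norm)
  p_norm <- 2 * pnorm(-abs(z_norm))
  withr::local_seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(k) stat(z[sample.int(n)]), numeric(1))
  p_perm <- if (I >= e_i) (sum(perm >= I) + 1) / (n_permutations + 1)
            else (sum(perm <= I) + 1) / (n_permutations + 1)
  structure(list(I = I, expected = e_i, z_norm = z_norm, p_norm = p_norm,
                 p_perm = p_perm, perm_mean = mean(perm), n = n,
                 n_permutations = n_permutations),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<moran_result> I = %.4f (E[I] = %.4f), z = %.2f, p_norm = %.3g, p_perm = %.3g\n",
              x$I, x$expected, x$z_norm, x$p_norm, x$p_perm))
  invisible(x)
}

#' @method tidy moran_result
#' @export
tidy.moran_result <- function(x, ...) {
  tibble(I = x$I, expected = x$expected, z = x$z_norm,
         p_norm = x$p_norm, p_perm = x$p_perm, n = x$n)
}

#' Local Moran's I (LISA) with cluster labels
#'
#' Per-unit `I_i = z_i / m2 * sum_j w_ij z_j` (`m2 = sum z^2 / n`), with
#' conditional-permutation pseudo p-values (value at `i` held fixed,
#' neighbors drawn from the remaining units). Units significant at `alpha`
#' are labeled by the quadrant of (value, spatial lag) relative to the mean:
#' HH, LL, LH or HL; others are `ns`. Under row-standardized weights the sum
#' of the local statistics equals `S0` times the global I.
#'
#' @param values numeric vector aligned with `W` (non-constant).
#' @param W a [build_weights()] object.
#' @param n_permutations conditional permutations (default 999).
#' @param seed integer seed.
#' @param alpha significance level for labeling (default 0.05).
#' @return tibble with `unit`, `local_i`, `p_perm`, `cluster` (factor:
#'   HH, LL, LH, HL, ns).
#' @export
local_morans_i <- function(values, W, n_permutations = 999, seed = 1,
                           alpha = 0.05) {
  n <- W$n
  if (length(values) != n) abort("values not aligned with weights")
  if (var(values) == 0) abort("constant field has undefined Moran's I")
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(W, z)
  li <- z / m2 * lag
  withr::local_seed(seed)
  p <- numeric(n)
  for (i in seq_len(n)) {
    nb <- W$neighbors[[i]]; wi <- W$weights[[i]]
    k <- length(nb)
    if (k == 0) { p[i] <- NA_real_; next }
    pool <- z[-i]
    perm_lag <- vapply(seq_len(n_permutations), function(b) {
      sum(wi * pool[sample.int(n - 1, k)])
    }, numeric(1))
    perm_li <- z[i] / m2 * perm_lag
    p[i] <- if (li[i] >= 0) (sum(perm_li >= li[i]) + 1) / (n_permutations + 1)
            else (sum(perm_li <= li[i]) + 1) / (n_permutations + 1)
  }
  cluster <- rep("ns", n)
  sig <- !is.na(p) & p <= alpha
  cluster[sig & z > 0 & lag > 0] <- "HH"
  cluster[sig & z < 0 & lag < 0] <- "LL"
  cluster[sig & z < 0 & lag >= 0] <- "LH"
  cluster[sig & z > 0 & lag <= 0] <- "HL"
  tibble(unit = seq_len(n), local_i = li, p_perm = p,
         cluster = factor(cluster, levels = c("HH", "LL", "LH", "HL", "ns")))
}
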