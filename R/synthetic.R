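#' Class specification for the synthetic land-use generator
#'
#' One row per land-use class: its integer code, the target share of the
#' raster it should occupy, and a clumping parameter controlling patch
#' aggregation (0 gives salt-and-pepper noise, large values give few compact
#' patches).
#'
#' @param class_code integer class label.
#' @param target_fraction proportion of raster area in `[0, 1]`.
#' @param clumping non-negative scalar; the number of growth seeds for a class
#'   is roughly `target_cells / (1 + clumping)`.
#' @return a one-row tibble; bind rows to build a full specification.
#' @export
class_spec <- function(class_code, target_fraction, clumping = 0) {
  stopifnot(is.numeric(class_code), is.numeric(target_fraction),
            is.numeric(clumping), clumping >= 0)
  tibble(class_code = as.integer(class_code),
         target_fraction = target_fraction,
         clumping = clumping)
}

validate_class_specs <- function(specs) {
  if (!all(c("class_code", "target_fraction", "clumping") %in% names(specs)))
    abort("specs must have columns class_code, target_fraction, clumping")
  if (anyDuplicated(specs$class_code))
    abort("class codes must be unique")
  if (any(specs$target_fraction < 0 | specs$target_fraction > 1))
    abort("target fractions must lie in [0, 1]")
  if (abs(sum(specs$target_fraction) - 1) > 1e-9)
    abort("target fractions must sum to 1 (within 1e-9)")
  if (any(specs$clumping < 0)) abort("clumping must be non-negative")
  invisible(specs)
}

# largest-remainder apportionment of n cells to fractions
apportion_cells <- function(fractions, n) {
  raw <- fractions * n
  q <- floor(raw)
  rem <- n - sum(q)
  if (rem > 0) {
    idx <- order(raw - q, decreasing = TRUE)[seq_len(rem)]
    q[idx] <- q[idx] + 1
  }
  as.integer(q)
}

# rook neighbors of linear indices in an nr x nc grid (column-major)
rook_shift <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  list(
    up    = ifelse(r > 1L,  idx - 1L, NA_integer_),
    down  = ifelse(r < nr,  idx + 1L, NA_integer_),
    left  = ifelse(c > 1L,  idx - nr, NA_integer_),
    right = ifelse(c < nc,  idx + nr, NA_integer_)
  )
}

#' Generate a seeded synthetic categorical land-use raster
#'
#' Multi-source competitive region growing: each class receives an exact cell
#' quota (largest-remainder apportionment of its target fraction) and a number
#' of seed cells shrinking with `clumping`; regions then grow in rounds over a
#' fixed random priority field until every cell is claimed. With clumping 0
#' every cell is a seed and the result is an exact random partition
#' (salt-and-pepper); large clumping yields a few compact patches per class.
#'
#' @param n_rows,n_cols raster dimensions, each at least 8.
#' @param specs tibble of class specifications, see [class_spec()].
#' @param seed integer seed; the same seed reproduces the raster bit for bit.
#' @param cell_size,xll,yll georeferencing passed to [land_raster()].
#' @return a [land_raster] whose realized class fractions are within 0.05
#'   (in practice within 1/n) of each target fraction.
#' @export
generate_landuse_raster <- function(n_rows, n_cols, specs, seed,
                                    cell_size = 1000, xll = 0, yll = 0) {
  if (n_rows < 8 || n_cols < 8) abort("raster must be at least 8 x 8")
  validate_class_specs(specs)
  n <- n_rows * n_cols
  quota <- apportion_cells(specs$target_fraction, n)
  if (any(quota == 0 & specs$target_fraction > 0))
    abort("raster too small to realize every class (a positive-fraction class received 0 cells)")
  codes <- specs$class_code
  k <- length(codes)

  withr::local_seed(seed)
  priority <- runif(n)
  assigned <- integer(n)                       # 0 = unassigned, else class slot 1..k
  remaining <- quota

  # seeds: fewer seeds for clumpier classes
  n_seed <- pmax(1L, pmin(quota, as.integer(round(quota / (1 + specs$clumping)))))
  n_seed[quota == 0L] <- 0L
  seed_cells <- sample.int(n, sum(n_seed))
  slot_of_seed <- rep(seq_len(k), times = n_seed)
  assigned[seed_cells] <- slot_of_seed
  remaining <- remaining - n_seed

  while (any(assigned == 0L)) {
    un <- which(assigned == 0L)
    nb <- rook_shift(un, n_rows, n_cols)
    cand_cell <- integer(0); cand_slot <- integer(0); cand_pri <- numeric(0)
    for (s in nb) {
      ok <- !is.na(s) & assigned[ifelse(is.na(s), 1L, s)] > 0L
      ok[is.na(s)] <- FALSE
      if (!any(ok)) next
      slot <- assigned[s[ok]]
      live <- remaining[slot] > 0L
      if (!any(live)) next
      cand_cell <- c(cand_cell, un[ok][live])
      cand_slot <- c(cand_slot, slot[live])
      cand_pri  <- c(cand_pri, priority[s[ok]][live])
    }
    if (length(cand_cell) == 0L) {
      # deadlock: enclosed unassigned cells or exhausted neighbors; drop a new
      # seed for a class that still has quota
      slot <- which(remaining > 0L)[1]
      cell <- un[sample.int(length(un), 1L)]
      assigned[cell] <- slot
      remaining[slot] <- remaining[slot] - 1L
      next
    }
    # each unassigned cell claimed by the neighboring region of max priority
    ord <- order(cand_cell, -cand_pri)
    keep <- !duplicated(cand_cell[ord])
    cell <- cand_cell[ord][keep]; slot <- cand_slot[ord][keep]
    # enforce per-class quotas: keep the highest-priority claims
    drop_all <- integer(0)
    for (s in unique(slot)) {
      sel <- which(slot == s)
      n_keep <- min(remaining[s], length(sel))
      if (n_keep < length(sel)) {
        keep <- sel[order(priority[cell[sel]], decreasing = TRUE)][seq_len(n_keep)]
        drop_all <- c(drop_all, setdiff(sel, keep))
      }
      remaining[s] <- remaining[s] - n_keep
    }
    if (length(drop_all) > 0) {
      cell <- cell[-drop_all]; slot <- slot[-drop_all]
    }
    assigned[cell] <- slot
  }

  m <- matrix(codes[assigned], nrow = n_rows, ncol = n_cols)
  legend <- setNames(codes, if ("name" %in% names(specs)) specs$name
                     else paste0("class_", codes))
  land_raster(m, xll = xll, yll = yll, cell_size = cell_size, legend = legend)
}

#' Transition rule for epoch-to-epoch land-use change
#'
#' @param from_code,to_code class codes.
#' @param rate per-epoch conversion probability in `[0, 1]`.
#' @param adjacency_bias multiplier (>= 1) applied to `rate` when a rook
#'   neighbor already holds `to_code`; the product is clipped at 1.
#' @return one-row tibble.
#' @export
transition_rule <- function(from_code, to_code, rate, adjacency_bias = 1) {
  stopifnot(rate >= 0, rate <= 1, adjacency_bias >= 1)
  tibble(from_code = as.integer(from_code), to_code = as.integer(to_code),
         rate = rate, adjacency_bias = adjacency_bias)
}

#' Evolve a land-use raster one epoch under transition rules
#'
#' Rules are applied in order against the raster state at the start of each
#' rule; only cells holding `from_code` may change, independently with
#' probability `rate` (times `adjacency_bias`, clipped to 1, where a rook
#' neighbor already holds `to_code`). Dimensions and total cell count are
#' preserved.
#'
#' @param raster a [land_raster].
#' @param rules tibble of [transition_rule()] rows (possibly empty).
#' @param seed integer seed.
#' @return a new [land_raster].
#' @export
evolve_landuse <- function(raster, rules, seed) {
  codes <- as.integer(raster$legend)
  if (nrow(rules) > 0 &&
      !all(c(rules$from_code, rules$to_code) %in% codes))
    abort("transition rule references a class code absent from the raster legend")
  withr::local_seed(seed)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  for (i in seq_len(nrow(rules))) {
    from <- rules$from_code[i]; to <- rules$to_code[i]
    rate <- rules$rate[i]; bias <- rules$adjacency_bias[i]
    elig <- which(v == from)
    if (length(elig) == 0) next
    nb <- rook_shift(elig, nr, nc)
    has_to <- rep(FALSE, length(elig))
    for (s in nb) {
      ok <- !is.na(s)
      has_to[ok] <- has_to[ok] | (!is.na(v[s[ok]]) & v[s[ok]] == to)
    }
    p <- ifelse(has_to, pmin(1, rate * bias), rate)
    conv <- elig[runif(length(elig)) < p]
    v[conv] <- to
  }
  out <- raster
  out$values <- v
  out
}

#' Variogram field specification
#'
#' @param model_family `"spherical"` or `"exponential"`.
#' @param nugget,partial_sill variance components, both >= 0.
#' @param range_ correlation length (> 0); for the exponential family this is
#'   the practical range at which the variogram reaches 95% of the sill.
#' @return a `field_spec` list.
#' @export
field_spec <- function(model_family = c("spherical", "exponential"),
                       nugget, partial_sill, range_) {
  model_family <- match.arg(model_family)
  stopifnot(nugget >= 0, partial_sill >= 0, range_ > 0)
  structure(list(model_family = model_family, nugget = nugget,
                 partial_sill = partial_sill, range_ = range_),
            class = "field_spec")
}

# correlation function implied by the variogram family (practical-range
# convention for the exponential)
field_correlation <- function(h, family, range_) {
  switch(family,
    spherical = ifelse(h >= range_, 0,
                       1 - (1.5 * h / range_ - 0.5 * (h / range_)^3)),
    exponential = exp(-3 * h / range_),
    abort(paste0("unknown model family: ", family))
  )
}

#' Simulate points from a Gaussian random field with a known variogram
#'
#' Locations are uniform on the extent; values are an exact zero-mean Gaussian
#' draw using a direct Cholesky factorization of the point covariance matrix
#' (`C(h) = partial_sill * rho(h)` off-diagonal, `nugget + partial_sill` on the
#' diagonal), so the theoretical variogram of the simulated process is exactly
#' the one specified. Intended for point sets up to a few thousand.
#'
#' @param n_points number of points, at least 30.
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @param spec a [field_spec()].
#' @param seed integer seed.
#' @return tibble with columns `x`, `y`, `value`.
#' @export
generate_autocorrelated_points <- function(n_points, extent, spec, seed) {
  if (n_points < 30) abort("n_points must be at least 30")
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    abort("degenerate extent; need c(xmin, xmax, ymin, ymax) with positive spans")
  stopifnot(inherits(spec, "field_spec"))
  withr::local_seed(seed)
  x <- runif(n_points, extent[1], extent[2])
  y <- runif(n_points, extent[3], extent[4])
  h <- as.matrix(dist(cbind(x, y)))
  sigma <- spec$partial_sill * field_correlation(h, spec$model_family, spec$range_)
  diag(sigma) <- spec$nugget + spec$partial_sill
  if (all(sigma == 0)) {
    value <- rep(0, n_points)
  } else {
    L <- chol(sigma + diag(1e-10 * max(diag(sigma)), n_points))
    value <- as.vector(t(L) %*% rnorm(n_points))
  }
  tibble(x = x, y = y, value = value)
}
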