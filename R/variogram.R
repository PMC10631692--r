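#' Theoretical variogram curve
#'
#' Spherical: `gamma(h) = C0 + C * (1.5 h/A - 0.5 (h/A)^3)` for `h <= A`, the
#' sill `C0 + C` beyond. Exponential: `gamma(h) = C0 + C * (1 - exp(-3h/A))`,
#' with `A` the practical range (95% of the sill), the convention common GIS
#' software reports.
#'
#' @param h distances (>= 0).
#' @param family `"spherical"` or `"exponential"`.
#' @param nugget,psill,range_ model parameters (C0, C, A).
#' @return semivariance values; `gamma(0) = C0`.
#' @export
variogram_curve <- function(h, family, nugget, psill, range_) {
  g <- nugget + psill * (1 - field_correlation(h, family, range_))
  g[h == 0] <- nugget
  g
}

#' Empirical semivariogram
#'
#' `gamma(h) = (1 / (2 N(h))) * sum (Z(x_i) - Z(x_j))^2` over point pairs
#' binned by separation distance. Pairs beyond `max_dist` are excluded; empty
#' bins are omitted.
#'
#' @param points tibble with `x`, `y`, `value`.
#' @param n_lags number of equal-width lag bins (default 12).
#' @param max_dist maximum pair separation (default: half the maximum
#'   pairwise distance).
#' @return tibble with `bin` (lag-bin index), `h` (mean pair distance in the
#'   bin), `gamma`, `n_pairs`; fewer than 30 points triggers a warning and an
#'   `unreliable` attribute. Bin width and max distance are kept as
#'   attributes so variograms on a common binning can be pooled.
#' @export
empirical_variogram <- function(points, n_lags = 12, max_dist = NULL) {
  unreliable <- FALSE
  if (nrow(points) < 30) {
    warn("fewer than 30 points: empirical variogram flagged unreliable")
    unreliable <- TRUE
  }
  d <- dist(cbind(points$x, points$y))
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist <= 0) abort("max_dist must be positive")
  dv <- as.vector(d)
  gv <- as.vector(dist(points$value))^2   # (Z_i - Z_j)^2
  keep <- dv <= max_dist & dv > 0
  dv <- dv[keep]; gv <- gv[keep]
  width <- max_dist / n_lags
  # left-open, right-closed bins: a pair exactly on a bin edge joins the
  # lower bin
  bin <- pmax(1L, as.integer(ceiling(dv / width - 1e-12)))
  out <- tibble(bin = bin, d = dv, g = gv) %>%
    group_by(.data$bin) %>%
    summarise(h = mean(.data$d),
              gamma = sum(.data$g) / (2 * n()),
              n_pairs = n(), .groups = "drop") %>%
    arrange(.data$bin) %>%
    select("bin", "h", "gamma", "n_pairs")
  attr(out, "unreliable") <- unreliable
  attr(out, "bin_width") <- width
  attr(out, "max_dist") <- max_dist
  class(out) <- c("empirical_variogram", class(out))
  out
}

#' Pool empirical variograms from replicate realizations
#'
#' Combines variograms computed on a common binning (same `n_lags` and
#' `max_dist`) by pair-count-weighted averaging per lag bin. Pooling
#' replicate realizations suppresses the large single-realization
#' fluctuation of the empirical variogram before model fitting.
#'
#' @param emps list of [empirical_variogram()] results with identical
#'   binning.
#' @return a pooled `empirical_variogram`.
#' @export
pool_empirical_variograms <- function(emps) {
  widths <- vapply(emps, function(e) attr(e, "bin_width"), numeric(1))
  if (length(unique(round(widths, 9))) != 1)
    abort("variograms must share a common binning to be pooled")
  out <- bind_rows(lapply(emps, as_tibble)) %>%
    group_by(.data$bin) %>%
    summarise(h = sum(.data$h * .data$n_pairs) / sum(.data$n_pairs),
              gamma = sum(.data$gamma * .data$n_pairs) / sum(.data$n_pairs),
              n_pairs = sum(.data$n_pairs), .groups = "drop") %>%
    arrange(.data$bin)
  attr(out, "bin_width") <- widths[1]
  attr(out, "max_dist") <- attr(emps[[1]], "max_dist")
  class(out) <- c("empirical_variogram", class(out))
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes `sum N(h) * (gamma_emp(h) - gamma_model(h))^2` over nugget,
#' partial sill and range with box constraints (L-BFGS-B) from 5 deterministic
#' starting points, keeping the best optimum.
#'
#' @param emp an [empirical_variogram()] with at least 4 bins.
#' @param family `"spherical"` or `"exponential"`.
#' @return a `variogram_model` list: `family`, `nugget`, `psill`, `sill`,
#'   `range_`, `nugget_sill_ratio` (fraction), `sse`, `converged`.
#' @export
fit_variogram_model <- function(emp, family = c("spherical", "exponential")) {
  family <- match.arg(family)
  if (nrow(emp) < 4) abort("need at least 4 usable variogram bins")
  h <- emp$h; g <- emp$gamma; w <- emp$n_pairs
  gmax <- max(g); hmax <- max(h)
  if (gmax <= 0) {
    return(new_variogram_model(family, 0, 0, hmax, sse = 0, converged = TRUE))
  }
  obj <- function(p) {
    sum(w * (g - variogram_curve(h, family, p[1], p[2], p[3]))^2)
  }
  lower <- c(0, 0, hmax * 1e-3)
  upper <- c(gmax * 2, gmax * 3, hmax * 10)
  starts <- list(
    c(0.05 * gmax, 0.95 * gmax, hmax / 3),
    c(0.25 * gmax, 0.75 * gmax, hmax / 2),
    c(0.5 * gmax, 0.5 * gmax, hmax),
    c(0, gmax, hmax / 5),
    c(0.1 * gmax, gmax, 2 * hmax)
  )
  fits <- lapply(starts, function(p0) {
    tryCatch(optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
             error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (length(fits) == 0)
    abort("variogram fit failed to converge from every starting point")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  new_variogram_model(family, best$par[1], best$par[2], best$par[3],
                      sse = best$value, converged = best$convergence == 0)
}

new_variogram_model <- function(family, nugget, psill, range_, sse = NA_real_,
                                converged = NA) {
  sill <- nugget + psill
  structure(
    list(family = family, nugget = nugget, psill = psill, sill = sill,
         range_ = range_,
         nugget_sill_ratio = if (sill > 0) nugget / sill else NA_real_,
         sse = sse, converged = converged),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, sill %.4g, range %.4g (nugget/sill %.1f%%)\n",
              x$family, x$nugget, x$sill, x$range_,
              100 * x$nugget_sill_ratio))
  invisible(x)
}

#' @method tidy variogram_model
#' @export
tidy.variogram_model <- function(x, ...) {
  tibble(family = x$family, nugget = x$nugget, psill = x$psill,
         sill = x$sill, range = x$range_,
         nugget_sill_pct = 100 * x$nugget_sill_ratio)
}

#' @method glance variogram_model
#' @export
glance.variogram_model <- function(x, ...) {
  tibble(sse = x$sse, converged = x$converged)
}

#' Nugget-to-sill ratio, in percent
#'
#' `100 * C0 / (C0 + C)`: the share of spatially unstructured (micro-scale
#' plus measurement) variance. Below 25% indicates strong spatial dependence.
#'
#' @param model a `variogram_model`, or a nugget value if `sill` is given.
#' @param sill optional; give `(nugget, sill)` directly as two numbers.
#' @return percentage in `[0, 100]`.
#' @export
nugget_sill_ratio <- function(model, sill = NULL) {
  if (inherits(model, "variogram_model")) {
    nugget <- model$nugget; sill <- model$sill
  } else {
    nugget <- model
  }
  if (is.null(sill) || sill <= 0) abort("sill must be positive")
  100 * nugget / sill
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system (semivariance form, with a Lagrange
#' multiplier enforcing that weights sum to 1) once for all targets using a
#' global neighborhood. With a zero-nugget model, prediction at a data
#' location reproduces the observed value exactly.
#'
#' @param model a `variogram_model`.
#' @param points tibble with `x`, `y`, `value` (duplicated locations are
#'   averaged with a warning).
#' @param targets tibble/data frame with `x`, `y` prediction locations.
#' @return tibble `x`, `y`, `pred`, `var` (kriging variance).
#' @export
ordinary_kriging <- function(model, points, targets) {
  if (nrow(points) < 3) abort("need at least 3 data points")
  key <- paste(points$x, points$y)
  if (anyDuplicated(key)) {
    warn("duplicate locations averaged before kriging")
    points <- points %>%
      group_by(.data$x, .data$y) %>%
      summarise(value = mean(.data$value), .groups = "drop")
  }
  n <- nrow(points)
  gm <- function(h) variogram_curve(h, model$family, model$nugget,
                                    model$psill, model$range_)
  G <- gm(as.matrix(dist(cbind(points$x, points$y))))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  tx <- targets$x; ty <- targets$y
  # distance from each data point to each target
  D0 <- sqrt(outer(points$x, tx, "-")^2 + outer(points$y, ty, "-")^2)
  B <- rbind(gm(D0), 1)
  lam <- solve(A, B)
  w <- lam[seq_len(n), , drop = FALSE]
  pred <- as.vector(crossprod(w, points$value))
  kvar <- colSums(lam * B)
  tibble(x = tx, y = ty, pred = pred, var = pmax(kvar, 0))
}
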