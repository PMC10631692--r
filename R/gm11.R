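#' Fit a GM(1,1) grey prediction model
#'
#' The classic first-order, one-variable grey model: the positive series
#' `x0` is accumulated once (`x1 = cumsum(x0)`), a background series
#' `z1(k) = alpha * x1(k) + (1 - alpha) * x1(k-1)` is formed, and the grey
#' differential equation `x0(k) + a * z1(k) = b` is solved for the
#' development coefficient `a` and grey input `b` by least squares over
#' `k = 2..n`. Fitted values come from the time-response function
#' `x1(t+1) = (x0(1) - b/a) * exp(-a t) + b/a` differenced back to the
#' original scale; the first fitted value is anchored at `x0(1)` exactly.
#'
#' @param series numeric vector of positive values, length >= 4.
#' @param alpha_bg background coefficient in (0, 1); 0.5 (adjacent mean) is
#'   the universal convention.
#' @return a `gm11` object: `a`, `b`, `alpha_bg`, `x0`, `fitted`, `quality`
#'   (see [fit_quality()]).
#' @export
fit_gm11 <- function(series, alpha_bg = 0.5) {
  n <- length(series)
  if (n < 4) abort("GM(1,1) needs at least 4 observations")
  if (any(series <= 0)) abort("GM(1,1) requires a strictly positive series")
  if (alpha_bg <= 0 || alpha_bg >= 1) abort("alpha_bg must lie in (0, 1)")
  x1 <- cumsum(series)
  z1 <- alpha_bg * x1[-1] + (1 - alpha_bg) * x1[-n]
  # least squares for x0(k) = -a z1(k) + b
  B <- cbind(-z1, 1)
  Y <- series[-1]
  ab <- qr.solve(B, Y)
  a <- ab[1]; b <- ab[2]
  fitted <- gm11_series(series[1], a, b, n)
  structure(
    list(a = unname(a), b = unname(b), alpha_bg = alpha_bg, x0 = series,
         fitted = fitted, quality = fit_quality(series, fitted)),
    class = "gm11"
  )
}

# original-scale series of length m from the time-response function
gm11_series <- function(x0_1, a, b, m) {
  t <- 0:(m - 1)
  if (abs(a) < 1e-12) {
    # a = 0 limit: accumulated series grows linearly, original scale constant b
    x1 <- x0_1 + b * t
  } else {
    x1 <- (x0_1 - b / a) * exp(-a * t) + b / a
  }
  c(x0_1, diff(x1))
}

#' Forecast from a fitted GM(1,1) model
#'
#' @param model a [fit_gm11()] object.
#' @param horizon number of steps beyond the observed series (>= 1).
#' @return numeric vector of `horizon` original-scale forecasts, continuous
#'   with the fitted series.
#' @export
predict_gm11 <- function(model, horizon) {
  if (horizon < 1) abort("horizon must be at least 1")
  n <- length(model$x0)
  full <- gm11_series(model$x0[1], model$a, model$b, n + horizon)
  tail(full, horizon)
}

#' Goodness of fit: RMSE and R-squared
#'
#' `RMSE = sqrt(mean((obs - fit)^2))`; `R^2 = 1 - SSres / SStot`. An RMSE of
#' 0 and an R^2 of 1 indicate a perfect fit.
#'
#' @param observed,fitted aligned numeric vectors, length >= 2.
#' @return tibble with `r_squared` (NA when the observed series is constant)
#'   and `rmse`.
#' @export
fit_quality <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2)
    abort("observed and fitted must be aligned vectors of length >= 2")
  res <- observed - fitted
  sstot <- sum((observed - mean(observed))^2)
  tibble(
    r_squared = if (sstot == 0) NA_real_ else 1 - sum(res^2) / sstot,
    rmse = sqrt(mean(res^2))
  )
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("<gm11> a = %.5f, b = %.5f (n = %d, R2 = %.4f, RMSE = %.4g)\n",
              x$a, x$b, length(x$x0), x$quality$r_squared, x$quality$rmse))
  invisible(x)
}

#' @method tidy gm11
#' @export
tidy.gm11 <- function(x, ...) {
  tibble(step = seq_along(x$x0), observed = x$x0, fitted = x$fitted,
         residual = x$x0 - x$fitted)
}

#' @method glance gm11
#' @export
glance.gm11 <- function(x, ...) {
  tibble(a = x$a, b = x$b, alpha_bg = x$alpha_bg, n = length(x$x0),
         r_squared = x$quality$r_squared, rmse = x$quality$rmse)
}

#' Forecast future risk grids per fishnet cell
#'
#' Fits an independent GM(1,1) to each cell's ERI series across epochs and
#' forecasts the requested horizons; forecast values are classified with the
#' given grade scheme. Cells with a non-positive ERI in any epoch are skipped
#' and reported.
#'
#' @param grids named list of `risk_grid`s on the same fishnet (>= 4 epochs,
#'   chronological).
#' @param horizons integer vector of steps beyond the last epoch (e.g.
#'   `1:2`).
#' @param scheme a [grade_scheme()] for classifying forecasts.
#' @return named list of forecast `risk_grid`s (one per horizon, named
#'   `"+1"`, `"+2"`, ...), each with `eri`, `grade`, `r_squared`, `rmse`;
#'   skipped cells are recorded in attribute `skipped_cells`.
#' @export
forecast_risk_grid <- function(grids, horizons = 1, scheme = grade_scheme()) {
  if (length(grids) < 4) abort("GM(1,1) forecasting needs at least 4 epochs")
  ids <- lapply(grids, function(g) g$cell_id)
  if (length(unique(ids)) != 1) abort("all epochs must share the same fishnet")
  eri_mat <- vapply(grids, function(g) g$eri, numeric(nrow(grids[[1]])))
  base <- grids[[length(grids)]]
  skipped <- which(apply(eri_mat, 1, function(x) any(x <= 0)))
  if (length(skipped) > 0)
    warn(sprintf("%d cell(s) with non-positive ERI skipped in forecasting",
                 length(skipped)))
  hmax <- max(horizons)
  fc <- matrix(NA_real_, nrow(eri_mat), hmax)
  qual <- matrix(NA_real_, nrow(eri_mat), 2)
  for (i in seq_len(nrow(eri_mat))) {
    if (i %in% skipped) next
    m <- fit_gm11(eri_mat[i, ])
    fc[i, ] <- predict_gm11(m, hmax)
    qual[i, ] <- c(m$quality$r_squared, m$quality$rmse)
  }
  out <- lapply(horizons, function(h) {
    g <- base
    g$eri <- fc[, h]
    keep <- !is.na(g$eri)
    g <- g[keep, ]
    g$eri <- pmin(pmax(g$eri, 0), scheme$upper)   # clamp into gradable range
    g$grade <- classify_grades(g$eri, scheme)
    g$r_squared <- qual[keep, 1]
    g$rmse <- qual[keep, 2]
    g$epoch <- paste0("+", h)
    for (a in c("cell_size_m", "origin", "boundary"))
      attr(g, a) <- attr(base, a)
    attr(g, "skipped_cells") <- skipped
    class(g) <- class(base)
    g
  })
  names(out) <- paste0("+", horizons)
  out
}
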