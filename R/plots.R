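grade_fill <- ggplot2::scale_fill_manual(
  values = c(I = "#1a9850", II = "#91cf60", III = "#fee08b",
             IV = "#fc8d59", V = "#d73027"),
  drop = FALSE, name = "grade"
)

#' Plot a risk grid
#'
#' Fishnet cells colored by security grade (if present) or by ERI.
#'
#' @param object a `risk_grid`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot risk_grid
#' @export
autoplot.risk_grid <- function(object, ...) {
  s <- attr(object, "cell_size_m")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x / 1000,
                                            y = .data$y / 1000))
  if (!is.null(object$grade)) {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$grade),
                                width = s / 1000, height = s / 1000) +
      grade_fill
  } else {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$eri),
                                width = s / 1000, height = s / 1000) +
      ggplot2::scale_fill_viridis_c(name = "ERI")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = paste0("Ecological risk, epoch ",
                                 object$epoch[1])) +
    ggplot2::theme_minimal()
}

#' Plot an empirical variogram, optionally with a fitted model
#'
#' @param object an [empirical_variogram()].
#' @param model optional `variogram_model` to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot empirical_variogram
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$h, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "pairs") +
    ggplot2::labs(x = "lag distance h", y = expression(gamma(h))) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    hh <- seq(0, max(object$h), length.out = 200)
    curve <- tibble(h = hh,
                    gamma = variogram_curve(hh, model$family, model$nugget,
                                            model$psill, model$range_))
    p <- p + ggplot2::geom_line(data = curve, color = "steelblue")
  }
  p
}

#' Plot a GM(1,1) fit
#'
#' Observed vs fitted series, with optional forecast steps appended.
#'
#' @param object a [fit_gm11()] model.
#' @param horizon forecast steps to append (default 0).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gm11
#' @export
autoplot.gm11 <- function(object, horizon = 0, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("observed", "fitted"), names_to = "series",
                        values_to = "value")
  if (horizon > 0) {
    fc <- predict_gm11(object, horizon)
    d <- bind_rows(d, tibble(step = length(object$x0) + seq_len(horizon),
                             observed = NA, fitted = NA, residual = NA,
                             series = "forecast", value = fc))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  color = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "step", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot grade-share evolution across epochs
#'
#' Stacked-bar chart of the per-epoch grade percentages from a pipeline
#' report.
#'
#' @param report a [run_pipeline()] report.
#' @return a ggplot.
#' @export
plot_grade_shares <- function(report) {
  ggplot2::ggplot(report$grade_proportions,
                  ggplot2::aes(x = .data$epoch, y = .data$pct,
                               fill = .data$grade)) +
    ggplot2::geom_col() + grade_fill +
    ggplot2::labs(x = NULL, y = "% of study area") +
    ggplot2::theme_minimal()
}
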