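#' Five-grade security classification scheme
#'
#' Grade I is the lowest risk (highest security), grade V the highest risk.
#' The default fixed breakpoints are 0.042, 0.049, 0.056 and 0.06 with an
#' upper bound of 1; intervals are left-closed, right-open, the last interval
#' closed, so a value exactly on a breakpoint takes the higher grade.
#'
#' @param breaks strictly increasing numeric vector of the four inner
#'   breakpoints.
#' @param upper upper bound of grade V (default 1).
#' @param provenance `"fixed-table"` or `"jenks"`.
#' @return a `grade_scheme` list.
#' @export
grade_scheme <- function(breaks = c(0.042, 0.049, 0.056, 0.06), upper = 1,
                         provenance = "fixed-table") {
  if (length(breaks) != 4 || any(diff(breaks) <= 0))
    abort("need 4 strictly increasing inner breakpoints")
  if (upper <= breaks[4]) abort("upper bound must exceed the last breakpoint")
  structure(list(breaks = breaks, upper = upper, provenance = provenance),
            class = "grade_scheme")
}

grade_levels <- c("I", "II", "III", "IV", "V")

#' Classify risk values into security grades
#'
#' @param values finite numeric risk values in `[0, upper]`.
#' @param scheme a [grade_scheme()].
#' @return ordered factor with levels I < II < III < IV < V.
#' @export
classify_grades <- function(values, scheme = grade_scheme()) {
  if (any(!is.finite(values))) abort("values must be finite")
  if (any(values < 0 | values > scheme$upper))
    abort(sprintf("values must lie in [0, %g]", scheme$upper))
  idx <- findInterval(values, c(0, scheme$breaks), rightmost.closed = FALSE)
  factor(grade_levels[idx], levels = grade_levels, ordered = TRUE)
}

#' Jenks natural-breaks classification (exact dynamic programming)
#'
#' Fisher's optimal 1-D partition minimizing total within-class sum of
#' squared deviations; exhaustive, so optimal (not the heuristic refinement
#' some GIS tools use).
#'
#' @param values numeric vector.
#' @param k number of classes (default 5).
#' @return a [grade_scheme()] whose 4 inner breakpoints are midpoints between
#'   adjacent class extremes, `provenance = "jenks"`.
#' @export
jenks_scheme <- function(values, k = 5) {
  x <- sort(values)
  n <- length(x)
  if (n < k) abort("need at least k values")
  # cost[i, j]: SSD of x[i..j]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) dp[1, j] <- ssd(1, j)
  for (m in 2:k) {
    for (j in m:n) {
      for (i in m:j) {
        cost <- dp[m - 1, i - 1] + ssd(i, j)
        if (cost < dp[m, j]) { dp[m, j] <- cost; back[m, j] <- i }
      }
    }
  }
  # recover class start indices
  starts <- integer(k); j <- n
  for (m in k:2) { starts[m] <- back[m, j]; j <- starts[m] - 1L }
  starts[1] <- 1L
  brk <- vapply(2:k, function(m) (x[starts[m] - 1] + x[starts[m]]) / 2,
                numeric(1))
  grade_scheme(breaks = brk, upper = max(x[n], 1), provenance = "jenks")
}

#' Per-cell ecological risk index over a fishnet
#'
#' For each fishnet cell `k`, `ERI_k = sum_i (A_ki / A_k) * R_i`, the
#' class-area-weighted mean of the class loss indices over the raster cells
#' whose centers fall in the fishnet cell (`A_k` = the cell's non-nodata
#' area). The value is attached to the cell center.
#'
#' @param net a [build_fishnet()] grid.
#' @param raster a [land_raster] covering the same coordinates.
#' @param loss named numeric vector mapping every raster class code to its
#'   loss index `R_i`.
#' @param epoch optional epoch label stored in the result.
#' @return a `risk_grid`: the fishnet tibble plus `eri`; cells containing no
#'   raster cells are dropped with a warning.
#' @export
compute_eri <- function(net, raster, loss, epoch = NA_character_) {
  codes <- sort(unique(as.vector(raster$values[!is.na(raster$values)])))
  if (!all(as.character(codes) %in% names(loss)))
    abort("every raster class needs a loss index R")
  s <- attr(net, "cell_size_m")
  org <- attr(net, "origin")
  pts <- raster_points(raster) %>% filter(!is.na(.data$code))
  pts <- pts %>%
    mutate(grid_col = floor((.data$x - org[1]) / s) + 1L,
           grid_row = floor((.data$y - org[2]) / s) + 1L)
  tallies <- pts %>%
    count(.data$grid_row, .data$grid_col, .data$code) %>%
    group_by(.data$grid_row, .data$grid_col) %>%
    summarise(eri = sum(.data$n / sum(.data$n) *
                          loss[as.character(.data$code)]),
              n_cells = sum(.data$n), .groups = "drop")
  out <- net %>% left_join(tallies, by = c("grid_row", "grid_col"))
  empty <- is.na(out$eri)
  if (any(empty)) {
    warn(sprintf("%d fishnet cell(s) contain no raster data and were dropped",
                 sum(empty)))
    out <- out[!empty, ]
  }
  out$epoch <- epoch
  for (a in c("cell_size_m", "origin", "boundary"))
    attr(out, a) <- attr(net, a)
  class(out) <- c("risk_grid", "fishnet", class(tibble()))
  out
}

#' Grade shares of the study area
#'
#' Area-weighted percentage of the study area in each security grade;
#' percentages sum to 100.
#'
#' @param grades factor of grades (levels I..V).
#' @param areas areas aligned with `grades` (any unit).
#' @return tibble with `grade`, `area`, `pct` — one row per grade (zeros
#'   included).
#' @export
grade_area_proportions <- function(grades, areas) {
  stopifnot(length(grades) == length(areas))
  tibble(grade = factor(grades, levels = grade_levels, ordered = TRUE),
         area = areas) %>%
    group_by(.data$grade, .drop = FALSE) %>%
    summarise(area = sum(.data$area), .groups = "drop") %>%
    mutate(pct = 100 * .data$area / sum(.data$area))
}

#' Grade transition matrix between two epochs
#'
#' Accumulates each cell's in-boundary area into a 5 x 5 matrix from its
#' grade at epoch A to its grade at epoch B; marginals reproduce each epoch's
#' grade areas exactly.
#'
#' @param grid_a,grid_b `risk_grid`s on the same fishnet, each with a
#'   `grade` column (see [classify_grades()]).
#' @param unit divide areas by this factor (default 1e6: m^2 -> km^2).
#' @return 5 x 5 numeric matrix (rows = epoch-A grade, cols = epoch-B grade).
#' @export
grade_transition_matrix <- function(grid_a, grid_b, unit = 1e6) {
  if (!identical(grid_a$cell_id, grid_b$cell_id))
    abort("grids must share the same fishnet cells")
  if (is.null(grid_a$grade) || is.null(grid_b$grade))
    abort("grids must carry a grade column")
  m <- matrix(0, 5, 5, dimnames = list(grade_levels, grade_levels))
  ga <- as.integer(factor(grid_a$grade, levels = grade_levels))
  gb <- as.integer(factor(grid_b$grade, levels = grade_levels))
  for (i in seq_along(ga))
    m[ga[i], gb[i]] <- m[ga[i], gb[i]] + grid_a$area[i] / unit
  m
}
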