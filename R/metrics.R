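#' Disturbance-index weights
#'
#' Weights of the linear disturbance index `E = a*C + b*S + c*D` over
#' fragmentation, separation and fractal dimension. They must sum to 1; the
#' defaults (0.5, 0.3, 0.2) weight fragmentation heaviest, then separation.
#'
#' @param a,b,c non-negative weights summing to 1.
#' @return named numeric vector `c(a =, b =, c =)`.
#' @export
disturbance_weights <- function(a = 0.5, b = 0.3, c = 0.2) {
  if (a < 0 || b < 0 || c < 0) abort("weights must be non-negative")
  if (abs(a + b + c - 1) > 1e-9) abort("weights must sum to 1 (within 1e-9)")
  c(a = a, b = b, c = c)
}

#' Default per-class vulnerability weights
#'
#' Expert-scored sensitivity of each land-use class to external disturbance,
#' in `[0, 1]`: built-up 0.05, forest 0.10, cultivated 0.14, water 0.19,
#' tea garden 0.24, rubber 0.28. Rubber and tea plantations score highest
#' because monoculture stands are the most fragile landscape under
#' disturbance; built-up land scores lowest.
#'
#' @param codes named integer vector mapping the six class names
#'   (`forest`, `rubber`, `tea`, `cultivated`, `builtup`, `water`) to the
#'   codes used in the raster legend.
#' @return named numeric vector: names are class codes, values are F in
#'   `[0, 1]`.
#' @export
default_vulnerability <- function(codes = c(forest = 1L, rubber = 2L, tea = 3L,
                                            cultivated = 4L, builtup = 5L,
                                            water = 6L)) {
  f <- c(forest = 0.10, rubber = 0.28, tea = 0.24,
         cultivated = 0.14, builtup = 0.05, water = 0.19)
  missing <- setdiff(names(codes), names(f))
  if (length(missing) > 0)
    abort(paste0("no default vulnerability for class: ",
                 paste(missing, collapse = ", ")))
  setNames(f[names(codes)], as.character(codes))
}

validate_vulnerability <- function(v) {
  if (any(v < 0 | v > 1)) abort("vulnerability weights must lie in [0, 1]")
  invisible(v)
}

#' Per-class landscape structure metrics
#'
#' From a patch inventory, computes for each class `i` with `n_i` patches and
#' area `A_i` (study area `A`, all in the reporting unit):
#' fragmentation `C_i = n_i / A_i`; separation
#' `S_i = (1/2) * sqrt(n_i / A) * (A / A_i)`; and fractal dimension `D_i`, the
#' patch mean of `2 * ln(P_j/4) / ln(A_j)` with perimeter and area in cell
#' units (single-cell patches are assigned D = 1, the value of a square).
#'
#' @param patches patch tibble from [label_patches()].
#' @param cell_area_unit area of one raster cell in the reporting unit
#'   (default: cell area in 1e4 hm^2 = 1e8 m^2, derived from the `cell_size`
#'   attribute carried by `patches`).
#' @return tibble with one row per class: `class_code`, `area` (reporting
#'   unit), `n_patches`, `C`, `S`, `D`.
#' @export
class_structure_metrics <- function(patches, cell_area_unit = NULL) {
  if (nrow(patches) == 0) abort("empty patch set")
  if (is.null(cell_area_unit)) {
    cs <- attr(patches, "cell_size")
    if (is.null(cs)) abort("patches carries no cell_size; give cell_area_unit")
    cell_area_unit <- cs^2 / 1e8   # m^2 -> 1e4 hm^2
  }
  frac_dim <- function(cells, per) {
    d <- ifelse(cells == 1, 1, 2 * log(per / 4) / log(cells))
    mean(d)
  }
  per_class <- patches %>%
    group_by(.data$class_code) %>%
    summarise(
      n_patches = n(),
      cells = sum(.data$cell_count),
      D = frac_dim(.data$cell_count, .data$perimeter),
      .groups = "drop"
    )
  A_total <- sum(per_class$cells) * cell_area_unit
  per_class %>%
    mutate(
      area = .data$cells * cell_area_unit,
      C = .data$n_patches / .data$area,
      S = 0.5 * sqrt(.data$n_patches / A_total) * (A_total / .data$area)
    ) %>%
    select("class_code", "area", "n_patches", "C", "S", "D")
}

#' Landscape disturbance index
#'
#' `E = a*C + b*S + c*D`: a weighted linear combination of fragmentation,
#' separation and fractal dimension expressing how disturbed a class's
#' spatial structure is.
#'
#' @param C,S,D landscape fragmentation, separation, and fractal-dimension
#'   indices (vectorized, all non-negative).
#' @param weights from [disturbance_weights()].
#' @return numeric vector E.
#' @export
disturbance_index <- function(C, S, D, weights = disturbance_weights()) {
  if (any(C < 0) || any(S < 0) || any(D < 0))
    abort("C, S, D must be non-negative")
  weights <- disturbance_weights(weights[["a"]], weights[["b"]], weights[["c"]])
  weights[["a"]] * C + weights[["b"]] * S + weights[["c"]] * D
}

#' Landscape loss index
#'
#' `R = E * F`: expected structural loss of a class under disturbance, the
#' product of its disturbance index and vulnerability weight.
#'
#' @param E disturbance index (>= 0, vectorized).
#' @param F_i vulnerability weight in `[0, 1]` (vectorized).
#' @return numeric vector R.
#' @export
loss_index <- function(E, F_i) {
  if (any(E < 0)) abort("E must be non-negative")
  if (any(F_i < 0 | F_i > 1)) abort("F must lie in [0, 1]")
  E * F_i
}

#' Per-epoch, per-class metrics table
#'
#' Runs patch labeling and structure metrics on each epoch's raster and
#' assembles the full index table (area, C, S, D, E, F, R), one row per
#' epoch and class.
#'
#' @param rasters named list of [land_raster] objects (names = epoch labels);
#'   all must share the same legend and dimensions.
#' @param weights disturbance weights, see [disturbance_weights()].
#' @param vulnerability named numeric vector mapping class codes to F values.
#' @return tibble with columns `epoch`, `class_code`, `class_name`, `area`,
#'   `n_patches`, `C`, `S`, `D`, `E`, `F`, `R`.
#' @export
metrics_table <- function(rasters, weights = disturbance_weights(),
                          vulnerability) {
  stopifnot(length(rasters) >= 1)
  legends <- lapply(rasters, function(r) sort(as.integer(r$legend)))
  if (length(unique(legends)) != 1)
    abort("all epochs must share the same class legend")
  dims <- lapply(rasters, dim)
  if (length(unique(dims)) != 1)
    abort("all epochs must share the same grid")
  validate_vulnerability(vulnerability)
  epochs <- names(rasters)
  if (is.null(epochs)) epochs <- as.character(seq_along(rasters))
  legend <- rasters[[1]]$legend
  purrr::map2_dfr(rasters, epochs, function(r, ep) {
    m <- class_structure_metrics(label_patches(r))
    absent <- setdiff(as.integer(legend), m$class_code)
    if (length(absent) > 0)
      warn(paste0("epoch ", ep, ": class(es) with zero area excluded: ",
                  paste(absent, collapse = ", ")))
    m$epoch <- ep
    m
  }) %>%
    mutate(
      class_name = names(legend)[match(.data$class_code, as.integer(legend))],
      E = disturbance_index(.data$C, .data$S, .data$D, weights),
      F = unname(vulnerability[as.character(.data$class_code)]),
      R = loss_index(.data$E, .data$F)
    ) %>%
    select("epoch", "class_code", "class_name", "area", "n_patches",
           "C", "S", "D", "E", "F", "R")
}
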