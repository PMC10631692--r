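#' Degrees-to-km conversion constant
#'
#' Crude equirectangular conversion from geographic degrees to plane km
#' (length of one degree of a great circle).
#' @export
DEG_TO_KM <- 111.11

#' Area-weighted center of gravity of a security grade
#'
#' Weighted mean of patch (or cell) centroid coordinates, weights = areas.
#'
#' @param points tibble with `x`, `y`, `weight` (patch centroids and areas).
#' @return one-row tibble `x`, `y`, `total_weight`; zero total weight returns
#'   a one-row tibble of NAs (absent grade marker).
#' @export
security_centroid <- function(points) {
  w <- sum(points$weight)
  if (nrow(points) == 0 || w <= 0)
    return(tibble(x = NA_real_, y = NA_real_, total_weight = 0))
  tibble(x = sum(points$x * points$weight) / w,
         y = sum(points$y * points$weight) / w,
         total_weight = w)
}

#' Gravity-center transfer distance
#'
#' Euclidean displacement between two epoch centroids. Degree coordinates are
#' converted to plane km with the constant `c = 111.11` km/degree:
#' `d = c * sqrt(dX^2 + dY^2)`; km coordinates are used as-is.
#'
#' @param p_m,p_n points with `x`, `y` (epoch m and n centroids).
#' @param coords_in_degrees TRUE if both points are in geographic degrees.
#' @return distance in km.
#' @export
transfer_distance <- function(p_m, p_n, coords_in_degrees = FALSE) {
  dx <- p_n$x - p_m$x; dy <- p_n$y - p_m$y
  d <- sqrt(dx^2 + dy^2)
  if (coords_in_degrees) DEG_TO_KM * d else d
}

eight_winds <- c("north", "northeast", "east", "southeast",
                 "south", "southwest", "west", "northwest")

#' Gravity-center transfer bearing and compass direction
#'
#' The operative angle is a compass bearing measured clockwise from north
#' (`atan2(dx, dy)`), mapped to the 8-wind rose by 45-degree sectors centered
#' on the principal directions. The raw quadrant-free `arctan(dy/dx)` term is
#' reported alongside for transparency; it is sign-ambiguous and is not used
#' for labeling.
#'
#' @param p_m,p_n points with `x`, `y`.
#' @return one-row tibble `bearing_deg` (in `[0, 360)`), `direction`,
#'   `raw_arctan_deg`; zero displacement yields NAs (undefined angle).
#' @export
transfer_angle <- function(p_m, p_n) {
  dx <- p_n$x - p_m$x; dy <- p_n$y - p_m$y
  if (dx == 0 && dy == 0)
    return(tibble(bearing_deg = NA_real_, direction = NA_character_,
                  raw_arctan_deg = NA_real_))
  bearing <- (atan2(dx, dy) * 180 / pi) %% 360
  sector <- (floor((bearing + 22.5) / 45) %% 8) + 1
  raw <- if (dx == 0) 90 else atan(dy / dx) * 180 / pi
  tibble(bearing_deg = bearing, direction = eight_winds[sector],
         raw_arctan_deg = raw)
}

#' Gravity-center migration track across epochs
#'
#' Computes per-grade, per-epoch area-weighted centroids from graded risk
#' grids and summarizes each consecutive epoch pair's shift: displacement
#' components, distance, bearing and 8-wind direction.
#'
#' @param grids named list of graded `risk_grid`s (names = epoch labels, in
#'   chronological order), each with `x`, `y`, `area`, `grade`.
#' @param coords_in_degrees are the grid coordinates geographic degrees?
#'   Default FALSE (projected meters; displacements are reported in km).
#' @return tibble with `grade`, `period`, `dx_km`, `dy_km`, `distance_km`,
#'   `bearing_deg`, `direction`.
#' @export
gravity_track <- function(grids, coords_in_degrees = FALSE) {
  epochs <- names(grids)
  cents <- purrr::map2_dfr(grids, epochs, function(g, ep) {
    as_tibble(g) %>%
      group_by(.data$grade, .drop = FALSE) %>%
      summarise(total_weight = sum(.data$area),
                x = sum(.data$x * .data$area) / sum(.data$area),
                y = sum(.data$y * .data$area) / sum(.data$area),
                .groups = "drop") %>%
      mutate(epoch = ep,
             x = ifelse(.data$total_weight > 0, .data$x, NA_real_),
             y = ifelse(.data$total_weight > 0, .data$y, NA_real_)) %>%
      select("grade", "epoch", "x", "y", "total_weight")
  })
  scale_km <- if (coords_in_degrees) DEG_TO_KM else 1 / 1000
  out <- list()
  for (g in levels(cents$grade)) {
    cg <- cents %>% filter(.data$grade == g)
    for (i in seq_len(nrow(cg) - 1)) {
      a <- cg[i, ]; b <- cg[i + 1, ]
      if (is.na(a$x) || is.na(b$x)) next
      ang <- transfer_angle(a, b)
      out[[length(out) + 1]] <- tibble(
        grade = g,
        period = paste0(a$epoch, "~", b$epoch),
        dx_km = (b$x - a$x) * scale_km,
        dy_km = (b$y - a$y) * scale_km,
        distance_km = transfer_distance(a, b, coords_in_degrees) *
          if (coords_in_degrees) 1 else 1 / 1000,
        bearing_deg = ang$bearing_deg,
        direction = ang$direction
      )
    }
  }
  bind_rows(out)
}
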