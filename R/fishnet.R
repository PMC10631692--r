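#' Polygon area by the shoelace formula
#'
#' @param poly two-column matrix or data frame of vertex `x`, `y` (ring may be
#'   open or closed).
#' @return non-negative area in squared input units.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly[, 1:2])
  storage.mode(poly) <- "double"
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman: clip a polygon to an axis-aligned rectangle. The clip
# window is convex, so the result is exact for any simple subject polygon
# (degenerate sliver edges can appear but carry zero area).
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  poly <- as.matrix(poly[, 1:2])
  storage.mode(poly) <- "double"
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  pts <- clip_edge(pts, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  pts <- clip_edge(pts, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  pts <- clip_edge(pts, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  pts
}

#' Build a fishnet evaluation grid over a study-area boundary
#'
#' Tiles the boundary's bounding box with square cells of side `cell_km`,
#' anchored at the lower-left corner of the bounding box, and retains every
#' cell whose in-boundary (clipped) area is at least `min_area_frac` of the
#' full cell area. All geometry is planar; coordinates are meters in a
#' projected CRS.
#'
#' @param boundary two-column matrix/data frame of polygon vertices (meters).
#' @param cell_km cell side length in km (> 0).
#' @param min_area_frac cells with a smaller in-boundary area fraction are
#'   dropped (default 0.01).
#' @return a `fishnet`: tibble with `cell_id`, `grid_row`, `grid_col`,
#'   `x`, `y` (cell center), `cell_area` and `area` (clipped, m^2); grid
#'   metadata in attributes.
#' @export
build_fishnet <- function(boundary, cell_km, min_area_frac = 0.01) {
  if (cell_km <= 0) abort("cell_km must be positive")
  boundary <- as.matrix(boundary[, 1:2])
  if (nrow(boundary) < 3 || polygon_area(boundary) <= 0)
    abort("boundary must be a valid polygon with positive area")
  s <- cell_km * 1000
  xmin <- min(boundary[, 1]); ymin <- min(boundary[, 2])
  xmax <- max(boundary[, 1]); ymax <- max(boundary[, 2])
  ncx <- ceiling((xmax - xmin) / s - 1e-9)
  ncy <- ceiling((ymax - ymin) / s - 1e-9)
  grid <- tidyr::expand_grid(grid_row = seq_len(ncy), grid_col = seq_len(ncx))
  cells <- purrr::pmap_dfr(grid, function(grid_row, grid_col) {
    x0 <- xmin + (grid_col - 1) * s; y0 <- ymin + (grid_row - 1) * s
    clipped <- clip_polygon_rect(boundary, x0, x0 + s, y0, y0 + s)
    tibble(grid_row = grid_row, grid_col = grid_col,
           x = x0 + s / 2, y = y0 + s / 2,
           cell_area = s^2, area = polygon_area(clipped))
  })
  net <- cells %>%
    filter(.data$area >= min_area_frac * .data$cell_area) %>%
    mutate(cell_id = dplyr::row_number()) %>%
    select("cell_id", "grid_row", "grid_col", "x", "y", "cell_area", "area")
  attr(net, "cell_size_m") <- s
  attr(net, "origin") <- c(xmin, ymin)
  attr(net, "boundary") <- boundary
  class(net) <- c("fishnet", class(net))
  net
}

#' Read / write a polygon boundary as GeoJSON
#'
#' Reads the first Polygon geometry found in a GeoJSON file (Feature,
#' FeatureCollection, or bare geometry); writes a single-Feature
#' FeatureCollection.
#'
#' @param path file path.
#' @param boundary two-column matrix/data frame of vertices.
#' @return `read_boundary_geojson` returns a tibble with `x`, `y`;
#'   `write_boundary_geojson` returns `path` invisibly.
#' @export
read_boundary_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- NULL
  if (identical(gj$type, "FeatureCollection")) geom <- gj$features[[1]]$geometry
  else if (identical(gj$type, "Feature")) geom <- gj$geometry
  else geom <- gj
  if (!identical(geom$type, "Polygon"))
    abort("expected a Polygon geometry")
  ring <- geom$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  # drop a closing vertex identical to the first
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  tibble(x = m[, 1], y = m[, 2])
}

#' @rdname read_boundary_geojson
#' @export
write_boundary_geojson <- function(boundary, path) {
  b <- as.matrix(boundary[, 1:2])
  ring <- lapply(seq_len(nrow(b)), function(i) c(b[i, 1], b[i, 2]))
  ring <- c(ring, ring[1])
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(name = "study_area"),
      geometry = list(type = "Polygon", coordinates = list(ring))
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
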