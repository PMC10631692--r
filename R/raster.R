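#' Categorical land-use raster
#'
#' A minimal in-memory container for a single-band categorical raster: an
#' integer matrix of class codes plus georeferencing metadata (lower-left
#' origin, square cell size) and a class legend. Row 1 of the matrix is the
#' *top* row of the map, matching the on-disk row order of ESRI ASCII grids.
#'
#' @param values integer matrix of class codes (NA = nodata).
#' @param xll,yll coordinates of the lower-left corner of the grid, in the
#'   units of `cell_size` (a projected CRS in meters is assumed).
#' @param cell_size side length of a (square) cell, meters.
#' @param legend named integer vector mapping class names to codes, e.g.
#'   `c(forest = 1, rubber = 2)`. Defaults to unnamed codes found in `values`.
#' @param nodata integer code written to file for NA cells.
#'
#' @return A `land_raster` object.
#' @export
land_raster <- function(values, xll = 0, yll = 0, cell_size = 1000,
                        legend = NULL, nodata = -9999L) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  storage.mode(values) <- "integer"
  if (is.null(legend)) {
    codes <- sort(unique(as.vector(values[!is.na(values)])))
    legend <- if (length(codes) == 0) setNames(integer(0), character(0))
              else setNames(codes, paste0("class_", codes))
  }
  structure(
    list(values = values, xll = xll, yll = yll, cell_size = cell_size,
         legend = legend, nodata = as.integer(nodata)),
    class = "land_raster"
  )
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster> %d x %d cells, cell %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll))
  fr <- class_fractions(x)
  cat("classes:", paste(sprintf("%s=%d (%.1f%%)", names(x$legend), x$legend,
                                100 * fr[as.character(x$legend)]),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

#' Realized class fractions of a raster
#'
#' @param raster a [land_raster].
#' @return named numeric vector of per-code fractions of non-nodata cells;
#'   names are class codes.
#' @export
class_fractions <- function(raster) {
  v <- as.vector(raster$values)
  v <- v[!is.na(v)]
  tab <- table(factor(v, levels = sort(unique(as.integer(raster$legend)))))
  out <- as.numeric(tab) / length(v)
  names(out) <- names(tab)
  out
}

#' Cell-center coordinates of every raster cell
#'
#' @param raster a [land_raster].
#' @return tibble with `row`, `col`, `x`, `y`, `code` (NA for nodata cells).
#' @export
raster_points <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cell_size
  # matrix row 1 is the top of the map
  tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = raster$xll + (rep(seq_len(nc), each = nr) - 0.5) * cs,
    y = raster$yll + (nr - rep(seq_len(nr), times = nc) + 0.5) * cs,
    code = as.vector(raster$values)
  )
}

#' Read / write ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of cell values, top row first.
#'
#' @param raster a [land_raster].
#' @param path file path.
#' @param legend optional named integer vector to attach on read.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [land_raster].
#' @export
write_ascii_grid <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %d", raster$nodata)
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, legend = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  nodata <- as.integer(val[["nodata_value"]])
  body <- lines[6 + seq_len(nr)]
  m <- matrix(as.integer(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_integer_
  land_raster(m, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
              cell_size = val[["cellsize"]], legend = legend, nodata = nodata)
}
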