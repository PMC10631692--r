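#' Label patches (rook-connected components) of a categorical raster
#'
#' A patch is a maximal set of same-class cells connected horizontally or
#' vertically (4-connectivity). Perimeter is counted in cell-edge units as the
#' number of exposed edges, i.e. edges facing a different class, nodata, or the
#' raster boundary.
#'
#' @param raster a [land_raster].
#' @return tibble with one row per patch: `patch_id`, `class_code`,
#'   `cell_count`, `perimeter` (cell edges), plus the raster's `cell_size`
#'   carried as an attribute `cell_size`.
#' @export
label_patches <- function(raster) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- which(!is.na(v))
  if (length(idx) == 0) abort("raster has no non-nodata cells")

  # edges between rook-adjacent same-class cells
  r <- (idx - 1L) %% nr + 1L
  cdx <- (idx - 1L) %/% nr + 1L
  down <- idx[r < nr]; down2 <- down + 1L
  right <- idx[cdx < nc]; right2 <- right + nr
  keep_d <- !is.na(v[down2]) & v[down] == v[down2]
  keep_r <- !is.na(v[right2]) & v[right] == v[right2]
  edges <- rbind(cbind(down[keep_d], down2[keep_d]),
                 cbind(right[keep_r], right2[keep_r]))

  # components over all non-nodata cells (isolated cells are singleton patches)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx))
  )
  comp <- igraph::components(g)
  lab <- integer(nr * nc)
  lab[as.integer(igraph::V(g)$name)] <- comp$membership

  # exposed edges per cell = 4 - number of same-class rook neighbors
  tab <- tabulate(c(edges[, 1], edges[, 2]), nbins = nr * nc)
  exposed <- 4L - tab
  per_patch <- tibble(
    patch_id = lab[idx],
    class_code = v[idx],
    exposed = exposed[idx]
  ) %>%
    group_by(.data$patch_id, .data$class_code) %>%
    summarise(cell_count = n(), perimeter = sum(.data$exposed),
              .groups = "drop") %>%
    arrange(.data$class_code, .data$patch_id)
  attr(per_patch, "cell_size") <- raster$cell_size
  per_patch
}
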