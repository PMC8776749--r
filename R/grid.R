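#' Gridded raster layer
#'
#' A minimal north-up raster layer: a numeric matrix (row 1 = northernmost
#' row) with `NA` marking no-data (ocean, ice), plus a lon/lat georeference.
#' The canonical global grid is 2160 x 4320 cells of 1/12 degree (5
#' arcminutes), extent -180..180 / -90..90; synthetic miniature worlds use
#' coarser cells through the same code paths.
#'
#' @param values Numeric matrix, `NA` = no-data. Values are per-cell
#'   quantities: 1000 ha (area layers), 1000 tonnes (production) or t/ha
#'   (yield).
#' @param west,north Western and northern edge of the grid, decimal degrees.
#' @param cellsize Cell size in decimal degrees (1/12 for canonical grids).
#' @return An object of class `crop_grid`.
#' @export
crop_grid <- function(values, west = -180, north = 90, cellsize = 1 / 12) {
  stopifnot(is.matrix(values), is.numeric(values) || all(is.na(values)))
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) stop("grid values must be >= 0")
  structure(list(values = values, west = west, north = north,
                 cellsize = cellsize),
            class = "crop_grid")
}

#' @export
print.crop_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<crop_grid> %d x %d cells of %.6g deg, origin (%.6g W, %.6g N)\n",
    d[1], d[2], x$cellsize, x$west, x$north))
  cat(sprintf("  data cells: %d, sum = %.6g\n",
              sum(!is.na(x$values)), sum(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.crop_grid <- function(x) dim(x$values)

same_geo <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$west, a$north, a$cellsize),
                     c(b$west, b$north, b$cellsize)))
}

#' @param x A `crop_grid`.
#' @param ... Unused.
#' @return `as_tibble()`: one row per cell with `cell_row`, `cell_col`,
#'   `lon`, `lat` (cell centers) and `value`; no-data cells are dropped.
#' @rdname crop_grid
#' @importFrom tibble as_tibble
#' @export
as_tibble.crop_grid <- function(x, ...) {
  d <- dim(x$values)
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  dimnames(idx) <- NULL
  tibble::tibble(
    cell_row = idx[, 1],
    cell_col = idx[, 2],
    lon = cell_center_lon(idx[, 2], x),
    lat = cell_center_lat(idx[, 1], x),
    value = x$values[idx]
  )
}

#' Cell-center coordinates
#' @param row,col Cell indices (1-based; row 1 is the northernmost row).
#' @param grid A `crop_grid` (only its georeference is used).
#' @return Decimal degrees.
#' @export
cell_center_lat <- function(row, grid) grid$north - (row - 0.5) * grid$cellsize

#' @rdname cell_center_lat
#' @export
cell_center_lon <- function(col, grid) grid$west + (col - 0.5) * grid$cellsize

# Authalic sphere radius (m): the sphere with the WGS84 ellipsoid's surface
# area, appropriate for per-cell area on an equal-angle grid.
AUTHALIC_RADIUS_M <- 6371007.2

#' Grid-cell area by row
#'
#' Spherical band area of one cell: `R^2 * dlambda * (sin(phi_N) - sin(phi_S))`
#' on the authalic sphere (R = 6,371,007.2 m), returned in 1000 ha
#' (1e7 m^2). Area depends on latitude only, decreases monotonically from
#' equator to pole and is symmetric about the equator.
#'
#' @param row Integer vector of row indices.
#' @param grid A `crop_grid` supplying the georeference.
#' @return Numeric vector of cell areas in 1000 ha.
#' @export
cell_area <- function(row, grid) {
  nr <- nrow(grid$values)
  stopifnot(all(row >= 1L), all(row <= nr))
  lat_n <- (grid$north - (row - 1) * grid$cellsize) * pi / 180
  lat_s <- (grid$north - row * grid$cellsize) * pi / 180
  dlon <- grid$cellsize * pi / 180
  AUTHALIC_RADIUS_M^2 * dlon * (sin(lat_n) - sin(lat_s)) / 1e7
}

#' Per-cell area layer
#' @param grid A `crop_grid`.
#' @return A `crop_grid` whose values are cell areas (1000 ha) for every
#'   cell, including no-data cells of `grid`.
#' @export
cell_area_grid <- function(grid) {
  d <- dim(grid$values)
  area_row <- cell_area(seq_len(d[1]), grid)
  crop_grid(matrix(area_row, d[1], d[2]),
            west = grid$west, north = grid$north, cellsize = grid$cellsize)
}
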