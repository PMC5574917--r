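#' Lattice geometry shared by all gridded fields
#'
#' A `grid_spec` records the geometry of a regular latitude-longitude lattice:
#' the number of rows (latitude) and columns (longitude), the cell size in
#' degrees, and the coordinates of the centre of cell (1, 1). By convention
#' row 1 is the northernmost row and column 1 the westernmost column, so the
#' centre of cell (i, j) lies at latitude `lat0 - (i-1)*cell_deg` and
#' longitude `lon0 + (j-1)*cell_deg`. The lattice is periodic in longitude
#' (columns wrap across the antimeridian) but not in latitude.
#'
#' The satellite products the model was designed around use a 720 x 1440
#' global lattice of 0.25 degree cells; any `n_rows * cell_deg <= 180` with
#' `n_cols * cell_deg == 360` is accepted.
#'
#' @param n_rows,n_cols Integer lattice dimensions (latitude x longitude).
#' @param cell_deg Cell size in degrees.
#' @param lat0,lon0 Coordinates of the centre of cell (1, 1). Defaults place
#'   the grid to cover latitudes from 90 southwards and longitudes from -180
#'   eastwards, the common satellite-product layout.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(720, 1440, 0.25)
#' grid_spec(32, 64, 5.625)
#' @export
grid_spec <- function(n_rows, n_cols, cell_deg,
                      lat0 = 90 - cell_deg / 2,
                      lon0 = -180 + cell_deg / 2) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_deg > 0)
  if (abs(n_cols * cell_deg - 360) > 1e-9) {
    stop("grid must cover 360 degrees of longitude (n_cols * cell_deg == 360)",
         call. = FALSE)
  }
  if (n_rows * cell_deg > 180 + 1e-9) {
    stop("grid exceeds 180 degrees of latitude", call. = FALSE)
  }
  lat_last <- lat0 - (n_rows - 1) * cell_deg
  if (lat0 > 90 || lat_last < -90) {
    stop("cell-centre latitudes must lie in [-90, 90]", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_deg = cell_deg, lat0 = lat0, lon0 = lon0),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg; cell (1,1) centre (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_deg, x$lat0, x$lon0))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gdeg", x$n_rows, x$n_cols, x$cell_deg)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Cell-centre coordinates
#'
#' @param grid A [grid_spec()].
#' @param cell Integer vector `c(row, col)`, or a 2-column matrix of cells.
#' @return A numeric vector `c(lat, lon)` in degrees, or a 2-column matrix
#'   when `cell` is a matrix.
#' @export
cell_centre <- function(grid, cell) {
  if (is.matrix(cell)) {
    cbind(lat = grid$lat0 - (cell[, 1] - 1) * grid$cell_deg,
          lon = wrap_lon(grid$lon0 + (cell[, 2] - 1) * grid$cell_deg))
  } else {
    c(lat = grid$lat0 - (cell[1] - 1) * grid$cell_deg,
      lon = wrap_lon(grid$lon0 + (cell[2] - 1) * grid$cell_deg))
  }
}

# wrap degrees longitude into (-180, 180]
wrap_lon <- function(lon) {
  out <- (lon + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

# wrap a column index into 1..n_cols
wrap_col <- function(j, n_cols) ((j - 1L) %% n_cols) + 1L

in_grid <- function(grid, cell) {
  cell[1] >= 1 && cell[1] <= grid$n_rows &&
    cell[2] >= 1 && cell[2] <= grid$n_cols
}

#' The 8 lattice neighbours of a cell
#'
#' Neighbour columns wrap across the antimeridian; rows beyond the first or
#' last latitude row are reported with `in_bounds = FALSE` and are never
#' legal moves.
#'
#' @param grid A [grid_spec()].
#' @param cell Integer `c(row, col)`.
#' @return A list with `cells` (8 x 2 integer matrix, columns wrapped) and
#'   `in_bounds` (logical length 8).
#' @export
neighbours8 <- function(grid, cell) {
  di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  rows <- cell[1] + di
  cols <- wrap_col(cell[2] + dj, grid$n_cols)
  list(cells = cbind(row = rows, col = cols),
       in_bounds = rows >= 1L & rows <= grid$n_rows)
}

is_adjacent <- function(grid, a, b) {
  di <- abs(a[1] - b[1])
  djraw <- abs(a[2] - b[2])
  dj <- min(djraw, grid$n_cols - djraw)
  (di <= 1 && dj <= 1) && !(di == 0 && dj == 0)
}

EARTH_RADIUS_KM <- 6371

# haversine between coordinate vectors (degrees); vectorised
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  h <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(sqrt(h), 1))
}

#' Great-circle distance between two lattice cells
#'
#' Haversine distance between cell centres on a sphere of radius 6371 km.
#' This distance is the `r` of the resource-attraction sum, so the kilometre
#' unit is part of the package's potential convention (it sets the scale of
#' the resource potential and hence the meaning of the wind weight `a`).
#'
#' @param grid A [grid_spec()].
#' @param cell_a,cell_b Integer cells `c(row, col)`.
#' @return Distance in km; symmetric, zero only for identical cells.
#' @examples
#' g <- grid_spec(180, 360, 1)
#' great_circle_distance(g, c(90, 1), c(90, 2)) # ~111.19 km on the equator
#' @export
great_circle_distance <- function(grid, cell_a, cell_b) {
  stopifnot(in_grid(grid, cell_a), in_grid(grid, cell_b))
  p <- cell_centre(grid, cell_a)
  q <- cell_centre(grid, cell_b)
  unname(haversine_km(p[1], p[2], q[1], q[2]))
}

# distances (km) from one point to every cell centre of the grid, exploiting
# the separable lattice structure: one haversine term per row and one per
# column instead of one per cell.
dist_to_all_latlon <- function(grid, plat, plon) {
  rad <- pi / 180
  lat <- grid$lat0 - (seq_len(grid$n_rows) - 1) * grid$cell_deg
  lon <- grid$lon0 + (seq_len(grid$n_cols) - 1) * grid$cell_deg
  sin2_dlat <- sin((lat - plat) * rad / 2)^2            # per row
  sin2_dlon <- sin((lon - plon) * rad / 2)^2            # per col
  coslat <- cos(lat * rad)
  h <- outer(coslat * cos(plat * rad), sin2_dlon) + sin2_dlat
  2 * EARTH_RADIUS_KM * asin(pmin(sqrt(h), 1))
}

dist_to_all_cells <- function(grid, cell) {
  p <- cell_centre(grid, cell)
  dist_to_all_latlon(grid, p[1], p[2])
}
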