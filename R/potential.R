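#' Model parameters
#'
#' The model has two free parameters. `a` weights the wind component of the
#' potential relative to the resource attraction (dimensionless under this
#' package's unit convention: resource potential in mg m^-3 per km, wind
#' potential in m^2 s^-2). `kT` is the Boltzmann temperature controlling
#' movement randomness (beta = 1/kT): low `kT` gives near-greedy descent of
#' the potential, high `kT` gives a nearly uniform random walk. `airspeed`
#' is the bird's typical airspeed in km/h, 60 by default; `speed_floor_frac`
#' floors the ground speed at that fraction of airspeed so steps into strong
#' headwind still terminate.
#'
#' @param a Wind weighting, `>= 0`.
#' @param kT Movement temperature, `> 0`. `kT = 0` is rejected; use a tiny
#'   positive value for the greedy limit.
#' @param airspeed Typical airspeed, km/h, `> 0`.
#' @param speed_floor_frac Minimum ground speed as a fraction of airspeed.
#' @return An object of class `model_params`.
#' @examples
#' model_params(a = 0.005, kT = 0.1) # the reference parameterisation
#' @export
model_params <- function(a, kT, airspeed = 60, speed_floor_frac = 0.1) {
  stopifnot(is.numeric(a), length(a) == 1, a >= 0,
            is.numeric(kT), length(kT) == 1, kT > 0,
            is.numeric(airspeed), length(airspeed) == 1, airspeed > 0,
            speed_floor_frac > 0, speed_floor_frac <= 1)
  structure(list(a = a, kT = kT, airspeed = airspeed,
                 speed_floor_frac = speed_floor_frac),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> a = %g, kT = %g, airspeed = %g km/h\n",
              x$a, x$kT, x$airspeed))
  invisible(x)
}

#' Resource-attraction potential at a cell
#'
#' Each unit of resource concentration acts like a unit of charge or mass
#' producing a potential that decays as -1/r, so the potential at cell
#' (i, j) is
#' \deqn{\phi_{ij} = -\sum_{(k,l) \ne (i,j)} C_{kl} / r_{ij,kl}}
#' with the sum over every cell carrying resource and `r` the great-circle
#' distance between cell centres in km. The field must already be masked to
#' ocean ([apply_ocean_mask()]): positive values on land are an error, since
#' land resource (inland lakes) must be excluded from the sum. Cells with
#' zero or missing concentration contribute nothing. Always `<= 0`; more
#' nearby resource makes it more negative (more attractive).
#'
#' @param field A masked [scalar_field()].
#' @param mask The [ocean_mask()] used for masking.
#' @param target Integer cell `c(row, col)`.
#' @return The scalar potential (mg m^-3 km^-1 in this package's units).
#' @export
resource_potential <- function(field, mask, target) {
  stopifnot(inherits(field, "scalar_field"), inherits(mask, "ocean_mask"))
  if (!same_grid(field$grid, mask$grid)) stop("grid mismatch", call. = FALSE)
  if (!in_grid(field$grid, target)) stop("target outside grid", call. = FALSE)
  land_resource <- field$values > 0 & !mask$is_ocean
  if (any(land_resource, na.rm = TRUE)) {
    stop("field has resource on land; apply_ocean_mask() first", call. = FALSE)
  }
  phi_direct(field$grid, field$values, target)
}

# vectorised -sum(C/r) skipping the self-term and zero/NA cells
phi_direct <- function(grid, values, target) {
  sel <- which(!is.na(values) & values > 0)
  self <- (target[2] - 1L) * grid$n_rows + target[1]
  sel <- sel[sel != self]
  if (length(sel) == 0) return(0)
  r <- dist_to_all_cells(grid, target)[sel]
  -sum(values[sel] / r)
}

#' Unit displacement vector between neighbouring cells on the sphere
#'
#' The wind potential needs the dot product of the wind vector with the
#' displacement of a candidate move. On a sphere the zonal extent of one
#' cell shrinks with latitude, so the displacement is built in the spherical
#' surface geometry — zonal component proportional to `dlon * cos(lat)`
#' (at the mean latitude of the two cells), meridional proportional to
#' `dlat` — then normalised to unit length. A diagonal move is therefore
#' not at 45 degrees except on the equator.
#'
#' @param grid A [grid_spec()].
#' @param centre Integer cell `c(row, col)`, the current position.
#' @param neighbour One of the 8 cells adjacent to `centre` (longitude
#'   wrapped).
#' @return Unit vector `c(zonal, meridional)`.
#' @export
spherical_displacement <- function(grid, centre, neighbour) {
  if (!is_adjacent(grid, centre, neighbour)) {
    stop("cells are not lattice-adjacent", call. = FALSE)
  }
  p <- cell_centre(grid, centre)
  q <- cell_centre(grid, neighbour)
  dlon <- wrap_lon_delta(q[2] - p[2])
  dlat <- q[1] - p[1]
  zon <- dlon * cos((p[1] + q[1]) / 2 * pi / 180)
  v <- unname(c(zon, dlat))
  v / sqrt(sum(v^2))
}

# shortest signed longitude difference in degrees
wrap_lon_delta <- function(d) ((d + 180) %% 360) - 180

# unit displacement vectors to all 8 neighbours of any cell in a given row
# (they depend only on the row, not the column); same construction as
# spherical_displacement, vectorised and memoisable per row
neighbour_displacements <- function(grid, row) {
  di <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  lat_c <- grid$lat0 - (row - 1) * grid$cell_deg
  lat_n <- grid$lat0 - (row - 1 + di) * grid$cell_deg
  dlat <- lat_n - lat_c
  zon <- dj * grid$cell_deg * cos((lat_c + lat_n) / 2 * pi / 180)
  n <- sqrt(zon^2 + dlat^2)
  cbind(zon / n, dlat / n)
}

row_displacements <- function(grid, row, cache) {
  if (is.null(cache)) return(neighbour_displacements(grid, row))
  key <- paste0("dx|", row)
  got <- cache[[key]]
  if (is.null(got)) {
    got <- neighbour_displacements(grid, row)
    cache[[key]] <- got
  }
  got
}

#' Wind component of the potential for one candidate move
#'
#' Wind is rotational, so no global wind potential exists; instead the wind
#' at the current cell tilts the landscape locally. Because aerodynamic drag
#' grows with the square of the relative air speed, the work saved (or
#' spent) moving with (or against) the wind is taken as
#' \deqn{\chi_{ij} = -|w_{xy}| \, (w_{xy} \cdot \hat{dx})}
#' with `w` the wind vector at the *current* cell (m/s) and `dx` the unit
#' spherical displacement of the move. Downwind moves are downhill
#' (negative), upwind moves uphill, crosswind moves free — tailwind support
#' without dynamic-soaring energetics.
#'
#' @param wind A [wind_field()].
#' @param centre Current cell `c(row, col)`; the wind is sampled here.
#' @param neighbour Candidate adjacent cell.
#' @param grid A [grid_spec()].
#' @return The scalar tilt (m^2 s^-2 in this package's units).
#' @export
wind_potential <- function(wind, centre, neighbour, grid) {
  dx <- spherical_displacement(grid, centre, neighbour)
  w <- c(wind$u[centre[1], centre[2]], wind$v[centre[1], centre[2]])
  -sqrt(sum(w^2)) * sum(w * dx)
}

#' Memoisation store for resource potentials
#'
#' The resource potential of a cell depends only on the (monthly) resource
#' field, not on the bird or the parameters, and the global -1/r sum is the
#' expensive part of a step. A cache computed on demand and keyed by
#' (cell, month) can therefore be shared across the birds of an ensemble
#' and across every (a, kT) pair of a sweep without changing any value.
#'
#' @return An empty cache to pass to [local_potential()] and the simulation
#'   drivers.
#' @export
potential_cache <- function() new.env(parent = emptyenv())

phi_cached <- function(env, cell, cache) {
  if (is.null(cache)) return(phi_direct(env$grid, env$resource$values, cell))
  key <- paste0(cell[1], ",", cell[2], ",", env$month)
  got <- cache[[key]]
  if (is.null(got)) {
    got <- phi_direct(env$grid, env$resource$values, cell)
    cache[[key]] <- got
  }
  got
}

#' Potential landscape around the current cell
#'
#' Evaluates, for each of the 8 neighbours of `centre`, the resource
#' potential `phi`, the wind tilt `chi`, and their combination
#' \deqn{\Psi_{ij} = \phi_{ij} + a\,\chi_{ij},}
#' together with a `permitted` flag: a neighbour is a legal destination only
#' if it is ocean and within the latitude bounds of the grid. Land
#' neighbours keep their computed potential but can never be moved into.
#'
#' @param env A [monthly_environment()].
#' @param centre Current cell `c(row, col)`; must be ocean.
#' @param params A [model_params()].
#' @param cache Optional [potential_cache()].
#' @return An object of class `local_potential`: list with `centre`,
#'   `neighbour_cells` (8 x 2), `phi`, `chi`, `psi` (length-8 numerics) and
#'   `permitted` (length-8 logical).
#' @export
local_potential <- function(env, centre, params, cache = NULL) {
  stopifnot(inherits(env, "monthly_environment"),
            inherits(params, "model_params"))
  if (!in_grid(env$grid, centre)) stop("centre outside grid", call. = FALSE)
  if (!env$mask$is_ocean[centre[1], centre[2]]) {
    stop("centre cell is on land", call. = FALSE)
  }
  nb <- neighbours8(env$grid, centre)
  phi <- rep(NA_real_, 8)
  permitted <- nb$in_bounds
  w <- c(env$wind$u[centre[1], centre[2]], env$wind$v[centre[1], centre[2]])
  wmag <- sqrt(sum(w^2))
  for (k in which(nb$in_bounds)) {
    cell <- nb$cells[k, ]
    permitted[k] <- env$mask$is_ocean[cell[1], cell[2]]
    phi[k] <- phi_cached(env, cell, cache)
  }
  dx <- row_displacements(env$grid, centre[1], cache)
  chi <- -wmag * (w[1] * dx[, 1] + w[2] * dx[, 2])
  chi[!nb$in_bounds] <- NA_real_
  structure(list(centre = centre, neighbour_cells = nb$cells,
                 phi = phi, chi = chi, psi = phi + params$a * chi,
                 permitted = permitted),
            class = "local_potential")
}
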