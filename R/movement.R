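#' State of one simulated bird
#'
#' @param cell Integer cell `c(row, col)`; must be ocean throughout a run.
#' @param clock Elapsed simulation time in hours since the start of the run.
#' @param month Current calendar month index.
#' @return An object of class `bird_state`.
#' @export
bird_state <- function(cell, clock = 0, month = 4L) {
  structure(list(cell = as.integer(cell), clock = clock,
                 month = as.integer(month)),
            class = "bird_state")
}

#' Maxwell-Boltzmann move probabilities
#'
#' Treats the 8 candidate destinations as energy states with energies
#' `psi` and assigns
#' \deqn{P(i,j) = e^{-\Psi_{ij}/kT} / \sum_{(k,l)} e^{-\Psi_{kl}/kT}}
#' over the *permitted* neighbours only: land and out-of-latitude neighbours
#' get exactly 0, and staying put is excluded by construction (the current
#' cell is not a candidate). Weights are computed after subtracting the
#' minimum permitted `psi` — a shift the distribution is exactly invariant
#' under — so the result stays finite for arbitrarily large potential
#' magnitudes.
#'
#' @param local A [local_potential()].
#' @param kT Temperature, `> 0`.
#' @return An object of class `move_distribution`: list with
#'   `neighbour_cells` (8 x 2) and `probabilities` (length 8, summing to 1).
#' @export
move_probabilities <- function(local, kT) {
  stopifnot(inherits(local, "local_potential"), kT > 0)
  ok <- local$permitted
  if (!any(ok)) {
    stop("dead end: no permitted neighbour (bird enclosed by land)",
         call. = FALSE)
  }
  p <- numeric(8)
  psi <- local$psi[ok]
  w <- exp(-(psi - min(psi)) / kT)
  p[ok] <- w / sum(w)
  structure(list(neighbour_cells = local$neighbour_cells, probabilities = p),
            class = "move_distribution")
}

#' Sample the next cell from a move distribution
#'
#' One draw from the categorical distribution over the 8 neighbours, using
#' R's current RNG stream; deterministic given the stream state (the
#' simulation drivers seed one stream per bird).
#'
#' @param dist A [move_distribution][move_probabilities()].
#' @return Integer cell `c(row, col)` of the chosen neighbour.
#' @export
sample_move <- function(dist) {
  stopifnot(inherits(dist, "move_distribution"))
  k <- sample.int(8L, 1L, prob = dist$probabilities)
  dist$neighbour_cells[k, ]
}

#' Duration of one step
#'
#' The clock advances by the time taken to fly the great-circle length of
#' the move at the bird's ground speed: a typical airspeed plus the tailwind
#' component of the wind at the departure cell (the same dot product
#' `w . dx` that defines the wind potential, converted from m/s to km/h).
#' Tailwind shortens the step, headwind lengthens it; the ground speed is
#' floored at `speed_floor_frac * airspeed` so a step into strong headwind
#' still terminates.
#'
#' @param grid A [grid_spec()].
#' @param centre,chosen Departure cell and adjacent destination cell.
#' @param wind A [wind_field()]; sampled at `centre`.
#' @param airspeed Airspeed in km/h.
#' @param speed_floor_frac Minimum ground speed as a fraction of airspeed.
#' @return Step duration in hours.
#' @export
step_duration <- function(grid, centre, chosen, wind, airspeed = 60,
                          speed_floor_frac = 0.1) {
  dx <- spherical_displacement(grid, centre, chosen)   # errors if not adjacent
  w <- c(wind$u[centre[1], centre[2]], wind$v[centre[1], centre[2]])
  tail_ms <- sum(w * dx)
  ground <- max(airspeed + 3.6 * tail_ms, speed_floor_frac * airspeed)
  great_circle_distance(grid, centre, chosen) / ground
}

# hours in each calendar month (non-leap year, 24 h/day)
MONTH_HOURS <- c(744, 672, 744, 720, 744, 720, 744, 744, 720, 744, 720, 744)

#' Advance a bird by one step
#'
#' One iteration of the simulation loop: evaluate the local potential
#' landscape, draw the next cell from its Boltzmann move distribution,
#' increment the clock by the step duration, and roll the month index
#' forward when the clock crosses `month_end` (the simulator switches to
#' the next month's environment at that point).
#'
#' @param state A [bird_state()] on an ocean cell of `env`.
#' @param env The [monthly_environment()] for `state$month`.
#' @param params A [model_params()].
#' @param cache Optional [potential_cache()].
#' @param month_end Clock value (hours) at which the current month ends.
#' @return The updated `bird_state`.
#' @export
advance <- function(state, env, params, cache = NULL, month_end = Inf) {
  lp <- local_potential(env, state$cell, params, cache)
  dist <- move_probabilities(lp, params$kT)
  nxt <- sample_move(dist)
  dur <- step_duration(env$grid, state$cell, nxt, env$wind,
                       params$airspeed, params$speed_floor_frac)
  clock <- state$clock + dur
  month <- state$month
  if (clock >= month_end) month <- month %% 12L + 1L
  bird_state(nxt, clock, month)
}
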