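#' Breeding colonies
#'
#' `colony()` builds a one-row colony record; `albatross_colonies()` returns
#' the five black-browed albatross breeding colonies with published
#' non-breeding tracking data, the reference starting points for the model.
#' Other colonies of interest (Campbell Island, the Crozet Islands, Islas
#' Diego de Almagro) can be supplied via `colony()` with user coordinates.
#'
#' @param name Colony label.
#' @param lat,lon Colony coordinates in degrees (`|lat| <= 90`,
#'   `|lon| <= 180`).
#' @return A one-row tibble (or five-row for `albatross_colonies()`) with
#'   columns `name`, `lat`, `lon`.
#' @export
colony <- function(name, lat, lon) {
  stopifnot(abs(lat) <= 90, abs(lon) <= 180)
  tibble::tibble(name = name, lat = lat, lon = lon)
}

#' @rdname colony
#' @export
albatross_colonies <- function() {
  tibble::tribble(
    ~name,                 ~lat,  ~lon,
    "Islas Diego Ramirez", -56.5, -68.7,
    "Falkland Islands",    -51.0, -61.1,
    "Iles Kerguelen",      -49.4,  70.0,
    "Macquarie Island",    -54.5, 158.9,
    "South Georgia",       -54.2, -36.5
  )
}

#' Nearest ocean cell to a colony
#'
#' Colonies sit on islands, so the cell containing the colony coordinates
#' is often land; trajectories start from the ocean cell whose centre is
#' closest (great-circle) to the colony. Exact distance ties are broken by
#' the smallest row, then the smallest column.
#'
#' @param colony A one-row colony record ([colony()]).
#' @param mask An [ocean_mask()].
#' @return Integer cell `c(row, col)`.
#' @export
snap_to_ocean <- function(colony, mask) {
  stopifnot(inherits(mask, "ocean_mask"))
  d <- dist_to_all_latlon(mask$grid, colony$lat[1], colony$lon[1])
  d[!mask$is_ocean] <- Inf
  best <- which(d == min(d), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  c(row = best[1, 1], col = best[1, 2])
}

#' Simulate one bird
#'
#' Runs a single bird from the ocean cell nearest its colony through
#' `duration_months` calendar months (default the April-July non-breeding
#' window), one Boltzmann step at a time. The environment switches to the
#' next month's fields when the clock crosses a calendar month boundary
#' (24 h days), and the run ends with the first step whose completion time
#' reaches the total duration — the final partial step is executed, not
#' truncated. Deterministic for a fixed `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param colony A one-row colony record ([colony()]).
#' @param params A [model_params()].
#' @param envs Named list of [monthly_environment()]s keyed by month index
#'   (as produced by [synth_environment()]); must cover the simulated
#'   window.
#' @param start_month First simulated month (default 4, April).
#' @param duration_months Number of months to simulate (default 4).
#' @param seed Integer seed for this bird's stream.
#' @param cache Optional shared [potential_cache()].
#' @param bird_id Identifier recorded in the trajectory.
#' @return A `flyway_trajectory`: the step table is a tibble with columns
#'   `step`, `row`, `col`, `lat`, `lon`, `clock_h`, `month`.
#' @export
simulate_bird <- function(colony, params, envs, start_month = 4L,
                          duration_months = 4L, seed = 1L, cache = NULL,
                          bird_id = 1L) {
  stopifnot(inherits(params, "model_params"), duration_months >= 0)
  months <- ((start_month - 1L + seq_len(duration_months) - 1L) %% 12L) + 1L
  missing_m <- setdiff(as.character(months), names(envs))
  if (length(missing_m)) {
    stop("envs missing month(s): ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  env0 <- envs[[as.character(start_month)]] %||% envs[[1]]
  start <- snap_to_ocean(colony, env0$mask)
  boundaries <- cumsum(MONTH_HOURS[months])
  total_h <- if (duration_months == 0) 0 else boundaries[duration_months]

  cells <- list(start)
  clocks <- 0
  month_rec <- as.integer(start_month)
  state <- bird_state(start, 0, start_month)
  idx <- 1L
  with_preserved_seed(seed, {
    while (state$clock < total_h) {
      env <- envs[[as.character(months[idx])]]
      state <- advance(state, env, params, cache,
                       month_end = boundaries[idx])
      if (state$month != months[idx] && idx < duration_months) idx <- idx + 1L
      cells[[length(cells) + 1L]] <- state$cell
      clocks <- c(clocks, state$clock)
      month_rec <- c(month_rec, months[min(idx, duration_months)])
    }
  })
  cm <- do.call(rbind, cells)
  ll <- cell_centre(env0$grid, cm)
  steps <- tibble::tibble(
    step = seq_along(clocks) - 1L,
    row = as.integer(cm[, 1]), col = as.integer(cm[, 2]),
    lat = ll[, 1], lon = ll[, 2],
    clock_h = clocks, month = as.integer(month_rec)
  )
  structure(list(bird_id = bird_id, colony = colony, params = params,
                 seed = seed, grid = env0$grid, steps = steps),
            class = "flyway_trajectory")
}

#' @export
print.flyway_trajectory <- function(x, ...) {
  cat(sprintf("<flyway_trajectory> bird %s from %s: %d steps, %.0f h (a = %g, kT = %g)\n",
              format(x$bird_id), x$colony$name[1], nrow(x$steps) - 1L,
              max(x$steps$clock_h), x$params$a, x$params$kT))
  invisible(x)
}

#' Simulate a colony ensemble
#'
#' Runs `n_birds` independent birds (default 16, the ensemble size used to
#' sample a population's migration pathways) from one colony under one
#' parameter pair, with per-bird seeds `base_seed + 1, ..., base_seed +
#' n_birds` so results are reproducible and independent of execution order.
#' Visit counts and final positions are aggregated into occupancy and
#' endpoint density grids.
#'
#' @inheritParams simulate_bird
#' @param n_birds Number of birds.
#' @param base_seed Ensemble seed; bird `b` uses `base_seed + b`.
#' @return A `flyway_ensemble`: trajectories plus `occupancy` and
#'   `endpoints` count matrices.
#' @export
simulate_ensemble <- function(colony, params, envs, n_birds = 16L,
                              base_seed = 1L, start_month = 4L,
                              duration_months = 4L, cache = NULL) {
  stopifnot(n_birds >= 1)
  if (is.null(cache)) cache <- potential_cache()
  grid <- envs[[1]]$grid
  trajectories <- lapply(seq_len(n_birds), function(b) {
    simulate_bird(colony, params, envs, start_month, duration_months,
                  seed = base_seed + b, cache = cache, bird_id = b)
  })
  occupancy <- matrix(0L, grid$n_rows, grid$n_cols)
  endpoints <- matrix(0L, grid$n_rows, grid$n_cols)
  for (tr in trajectories) {
    s <- tr$steps
    for (k in seq_len(nrow(s))) {
      occupancy[s$row[k], s$col[k]] <- occupancy[s$row[k], s$col[k]] + 1L
    }
    last <- nrow(s)
    endpoints[s$row[last], s$col[last]] <-
      endpoints[s$row[last], s$col[last]] + 1L
  }
  structure(list(colony = colony, params = params, base_seed = base_seed,
                 grid = grid, trajectories = trajectories,
                 occupancy = occupancy, endpoints = endpoints),
            class = "flyway_ensemble")
}

#' @export
print.flyway_ensemble <- function(x, ...) {
  cat(sprintf("<flyway_ensemble> %d birds from %s (a = %g, kT = %g); %d steps total\n",
              length(x$trajectories), x$colony$name[1], x$params$a,
              x$params$kT, sum(x$occupancy) - length(x$trajectories)))
  invisible(x)
}

#' Sweep the (a, kT) parameter plane
#'
#' Runs one ensemble per (a, kT) pair over the default 8 x 4 = 32-pair
#' exploration grid (`a` in 0.001..0.008 by 0.001, `kT` in 0.05..0.2 by
#' 0.05) or any user grids. Pair `p` (1-based, `a` varying fastest) seeds
#' its ensemble with `base_seed + p * 1e6`, so extending the grids never
#' perturbs existing runs. The resource-potential cache is shared across
#' the whole sweep (the resource potential does not depend on `a` or `kT`).
#'
#' @inheritParams simulate_ensemble
#' @param a_values,kT_values Parameter grids.
#' @param airspeed Airspeed passed to every [model_params()].
#' @return A `flyway_sweep` tibble with columns `pair`, `a`, `kT`,
#'   `ensemble` (list of `flyway_ensemble`).
#' @export
sweep_parameters <- function(colony, a_values = seq(0.001, 0.008, by = 0.001),
                             kT_values = seq(0.05, 0.2, by = 0.05),
                             envs, n_birds = 16L, base_seed = 1L,
                             start_month = 4L, duration_months = 4L,
                             airspeed = 60) {
  stopifnot(length(a_values) >= 1, length(kT_values) >= 1)
  pairs <- expand.grid(a = a_values, kT = kT_values,
                       KEEP.OUT.ATTRS = FALSE)
  cache <- potential_cache()
  ensembles <- purrr::map(seq_len(nrow(pairs)), function(p) {
    simulate_ensemble(colony, model_params(pairs$a[p], pairs$kT[p], airspeed),
                      envs, n_birds = n_birds,
                      base_seed = base_seed + p * 1000000L,
                      start_month = start_month,
                      duration_months = duration_months, cache = cache)
  })
  out <- tibble::tibble(pair = seq_len(nrow(pairs)), a = pairs$a,
                        kT = pairs$kT, ensemble = ensembles)
  class(out) <- c("flyway_sweep", class(out))
  out
}

#' East/west split of an ensemble's endpoints
#'
#' Fraction of birds whose final position lies east versus west of a
#' meridian (by default the meridian of the ensemble's start cell), using
#' the shortest-arc convention; a bird ending exactly on the meridian
#' counts as east. A compact summary of the characteristic population
#' splits (e.g. a majority migrating downwind while a smaller fraction
#' heads the other way).
#'
#' @param result A [flyway_ensemble][simulate_ensemble()].
#' @param meridian Reference longitude in degrees; default the start cell's.
#' @return A tibble with `fraction_east`, `fraction_west`, `n_birds`,
#'   `meridian`.
#' @export
directional_split <- function(result, meridian = NULL) {
  stopifnot(inherits(result, "flyway_ensemble"))
  if (is.null(meridian)) {
    start <- result$trajectories[[1]]$steps
    meridian <- start$lon[1]
  }
  finals <- vapply(result$trajectories,
                   function(tr) tr$steps$lon[nrow(tr$steps)], numeric(1))
  east <- wrap_lon_delta(finals - meridian) >= 0
  tibble::tibble(fraction_east = mean(east), fraction_west = mean(!east),
                 n_birds = length(finals), meridian = meridian)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
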