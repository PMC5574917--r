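#' Brute-force resource-potential oracle
#'
#' Reference implementation of the -1/r attraction sum: an explicit double
#' loop over every lattice cell, one pairwise great-circle call per term, no
#' caching and no vectorised shortcut. Ground truth for
#' [resource_potential()] on grids small enough to afford O(cells) work per
#' evaluation (intended for grids up to 64 x 128).
#'
#' @param field A masked [scalar_field()].
#' @param mask An [ocean_mask()].
#' @param target Integer cell `c(row, col)`.
#' @return The potential, same convention as [resource_potential()].
#' @export
oracle_resource_potential <- function(field, mask, target) {
  grid <- field$grid
  acc <- 0
  for (k in seq_len(grid$n_rows)) {
    for (l in seq_len(grid$n_cols)) {
      if (k == target[1] && l == target[2]) next
      c_kl <- field$values[k, l]
      if (is.na(c_kl) || c_kl == 0) next
      acc <- acc - c_kl / great_circle_distance(grid, target, c(k, l))
    }
  }
  acc
}

#' Overflow-safe Boltzmann probability oracle
#'
#' Independent evaluation of the move probabilities via the pairwise-ratio
#' form \eqn{P(i) = 1 / \sum_k e^{(\Psi_i - \Psi_k)/kT}} over permitted
#' states, which is algebraically identical to the Boltzmann quotient but
#' never forms the raw exponentials: an overflowing denominator yields an
#' exact 0 probability, so the oracle stays correct for arbitrarily large
#' potential magnitudes. Used to validate the min-shifted production path
#' in [move_probabilities()].
#'
#' @param psi Numeric length-8 potentials.
#' @param permitted Logical length-8.
#' @param kT Temperature, `> 0`.
#' @return Length-8 probabilities; exactly 0 on not-permitted entries.
#' @export
oracle_boltzmann <- function(psi, permitted, kT) {
  stopifnot(length(psi) == 8, length(permitted) == 8, kT > 0)
  p <- numeric(8)
  idx <- which(permitted)
  for (i in idx) {
    p[i] <- 1 / sum(exp((psi[i] - psi[idx]) / kT))
  }
  p
}

#' Run the randomized property suite
#'
#' Executes the package's cross-module invariants on randomized small
#' instances (grids up to 32 x 64) and aggregates one report row per
#' property: oracle agreement for the resource potential and the Boltzmann
#' probabilities, the wind-potential contracts (perpendicular moves free,
#' antisymmetry of opposing moves, quadratic scaling in wind speed), mask
#' idempotence, move-distribution normalization, the greedy and
#' high-temperature limits, and trajectory legality. Failures are reported,
#' not raised. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_potential_cases,n_boltzmann_cases,n_wind_cases Numbers of
#'   randomized cases per oracle comparison.
#' @return A tibble with columns `operation`, `max_abs_error`,
#'   `max_rel_error`, `n_cases`, `tolerance`, `passed`.
#' @export
run_property_suite <- function(seed = 1L, n_potential_cases = 50L,
                               n_boltzmann_cases = 500L,
                               n_wind_cases = 200L) {
  reports <- list()
  with_preserved_seed(seed, {
    grid <- grid_spec(16, 32, 11.25)
    envs <- synth_environment("ring_world", grid, seed = seed + 1L)
    env <- envs[[1]]

    # resource potential vs direct double loop
    rel <- abs_ <- numeric(n_potential_cases)
    ocean_cells <- which(env$mask$is_ocean, arr.ind = TRUE)
    for (i in seq_len(n_potential_cases)) {
      cell <- ocean_cells[sample.int(nrow(ocean_cells), 1), ]
      got <- resource_potential(env$resource, env$mask, cell)
      want <- oracle_resource_potential(env$resource, env$mask, cell)
      abs_[i] <- abs(got - want)
      rel[i] <- abs_[i] / max(abs(want), .Machine$double.xmin)
    }
    reports$resource_potential <- report_row(
      "resource_potential vs direct sum", max(abs_), max(rel),
      n_potential_cases, tol = 1e-9, passed = max(rel) <= 1e-9)

    # Boltzmann probabilities vs pairwise-ratio oracle
    err <- numeric(n_boltzmann_cases)
    for (i in seq_len(n_boltzmann_cases)) {
      scale <- 10^stats::runif(1, -2, 6)
      psi <- stats::rnorm(8) * scale
      permitted <- stats::runif(8) < 0.7
      if (!any(permitted)) permitted[sample.int(8, 1)] <- TRUE
      kT <- stats::runif(1, 0.05, 2)
      lp <- fake_local_potential(psi, permitted)
      got <- move_probabilities(lp, kT)$probabilities
      want <- oracle_boltzmann(psi, permitted, kT)
      err[i] <- max(abs(got - want))
    }
    reports$boltzmann <- report_row(
      "move_probabilities vs pairwise-ratio oracle", max(err), NA_real_,
      n_boltzmann_cases, tol = 1e-12, passed = max(err) <= 1e-12)

    # wind-potential contracts
    werr <- numeric(n_wind_cases)
    g2 <- grid_spec(32, 64, 5.625)
    for (i in seq_len(n_wind_cases)) {
      centre <- c(sample(2:(g2$n_rows - 1), 1), sample.int(g2$n_cols, 1))
      u <- stats::rnorm(1, 0, 10); v <- stats::rnorm(1, 0, 10)
      wf <- wind_field(g2, 4L, matrix(u, g2$n_rows, g2$n_cols),
                       matrix(v, g2$n_rows, g2$n_cols))
      east <- c(centre[1], wrap_col(centre[2] + 1L, g2$n_cols))
      west <- c(centre[1], wrap_col(centre[2] - 1L, g2$n_cols))
      north <- c(centre[1] - 1L, centre[2])
      south <- c(centre[1] + 1L, centre[2])
      chi_e <- wind_potential(wf, centre, east, g2)
      chi_w <- wind_potential(wf, centre, west, g2)
      chi_n <- wind_potential(wf, centre, north, g2)
      chi_s <- wind_potential(wf, centre, south, g2)
      # perpendicular: purely zonal wind, meridional move
      wz <- wind_field(g2, 4L, matrix(u, g2$n_rows, g2$n_cols),
                       matrix(0, g2$n_rows, g2$n_cols))
      perp <- abs(wind_potential(wz, centre, north, g2))
      s <- stats::runif(1, 0.1, 3)
      ws <- wind_field(g2, 4L, matrix(s * u, g2$n_rows, g2$n_cols),
                       matrix(s * v, g2$n_rows, g2$n_cols))
      scale_err <- abs(wind_potential(ws, centre, east, g2) - s^2 * chi_e)
      werr[i] <- max(abs(chi_e + chi_w), abs(chi_n + chi_s), perp,
                     scale_err / max(abs(chi_e) * s^2, 1e-300))
    }
    reports$wind <- report_row(
      "wind potential: antisymmetry, perpendicular, |w|^2 scaling",
      max(werr), NA_real_, n_wind_cases, tol = 1e-9,
      passed = max(werr) <= 1e-9)

    # masking idempotence
    once <- apply_ocean_mask(env$resource, env$mask)
    twice <- apply_ocean_mask(once, env$mask)
    mask_err <- max(abs(once$values - twice$values))
    reports$mask <- report_row("ocean mask idempotence", mask_err, NA_real_,
                               1L, tol = 0, passed = mask_err == 0)

    # normalization + legality on a short run
    pars <- model_params(a = 0.003, kT = 0.1)
    cache <- potential_cache()
    col <- colony("probe", -50, 0)
    tr <- simulate_bird(col, pars, envs, duration_months = 1L,
                        seed = seed + 2L, cache = cache)
    legal <- trajectory_legal(tr, env$mask)
    reports$legality <- report_row("trajectory legality", as.numeric(!legal),
                                   NA_real_, nrow(tr$steps), tol = 0,
                                   passed = legal)

    # greedy and hot limits on a random landscape
    psi <- stats::rnorm(8)
    lp <- fake_local_potential(psi, rep(TRUE, 8))
    greedy <- move_probabilities(lp, 1e-9)$probabilities
    hot <- move_probabilities(lp, 1e9)$probabilities
    lim_err <- max(abs(greedy[which.min(psi)] - 1),
                   max(abs(hot - 1 / 8)))
    reports$limits <- report_row("greedy and hot temperature limits",
                                 lim_err, NA_real_, 2L, tol = 1e-6,
                                 passed = lim_err <= 1e-6)
  })
  dplyr::bind_rows(reports)
}

report_row <- function(operation, max_abs, max_rel, n, tol, passed) {
  tibble::tibble(operation = operation, max_abs_error = max_abs,
                 max_rel_error = max_rel, n_cases = as.integer(n),
                 tolerance = tol, passed = passed)
}

# assemble a local_potential from raw psi values (for probability tests)
fake_local_potential <- function(psi, permitted) {
  grid <- grid_spec(16, 32, 11.25)
  nb <- neighbours8(grid, c(8L, 16L))
  structure(list(centre = c(8L, 16L), neighbour_cells = nb$cells,
                 phi = psi, chi = numeric(8), psi = psi,
                 permitted = permitted),
            class = "local_potential")
}

# every visited cell ocean, consecutive cells adjacent, clock increasing
trajectory_legal <- function(tr, mask) {
  s <- tr$steps
  ocean_ok <- all(mask$is_ocean[cbind(s$row, s$col)])
  adj_ok <- all(vapply(seq_len(nrow(s) - 1), function(k) {
    is_adjacent(tr$grid, c(s$row[k], s$col[k]), c(s$row[k + 1], s$col[k + 1]))
  }, logical(1)))
  clock_ok <- all(diff(s$clock_h) > 0)
  ocean_ok && adj_ok && clock_ok
}

#' Write a validation report
#'
#' Runs [run_property_suite()] and writes the report tibble as JSON.
#'
#' @param path Output JSON file.
#' @param seed Integer seed.
#' @return The report tibble, invisibly.
#' @export
write_validation_report <- function(path, seed = 1L) {
  rep <- run_property_suite(seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(rep)
}
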