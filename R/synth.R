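#' Generate synthetic monthly environments
#'
#' Builds self-contained test worlds with the same structure as the real
#' satellite inputs (non-negative patchy resource fields masked to ocean,
#' smooth wind fields with dominant westerly flow, one slice per month):
#'
#' * `point_source` — a single resource cell of amplitude `amplitude` at
#'   `cell`, zero wind, all-ocean mask. The entire attraction of the world
#'   concentrated at one point; the cleanest landscape for drift tests.
#' * `two_patch` — two identical Gaussian resource patches placed
#'   symmetrically `offset_cols` columns east and west of `cell`, optional
#'   uniform wind. Mirror-symmetric about the meridian of `cell`.
#' * `uniform_wind` — spatially uniform resource (`resource`) and uniform
#'   wind (`u`, `v`); isolates the wind term.
#' * `zonal_jet` — a Gaussian-in-latitude westerly jet (`u_max`, `lat_jet`,
#'   `width_deg`) over a patchy lognormal resource field; the cartoon of the
#'   Southern Ocean.
#' * `ring_world` — ocean restricted to a latitude band (`lat_min`,
#'   `lat_max`, land elsewhere) with patchy resource and a zonal jet inside
#'   the band; exercises land exclusion.
#'
#' Patchy resource fields are iid lognormal draws (median ~1 mg m^-3, the
#' order of real ocean chlorophyll) smoothed with a 3 x 3 box filter, drawn
#' fresh per month. Generation is deterministic for a fixed `seed` and does
#' not disturb the caller's RNG state.
#'
#' @param kind One of `"point_source"`, `"two_patch"`, `"uniform_wind"`,
#'   `"zonal_jet"`, `"ring_world"`.
#' @param grid A [grid_spec()].
#' @param params Named list of generator parameters (see above); unset
#'   entries take the defaults.
#' @param seed Integer RNG seed.
#' @param months Integer vector of month indices; default April-July, the
#'   non-breeding window the simulator targets.
#' @return A named list of [monthly_environment()] objects, one per month.
#' @examples
#' g <- grid_spec(16, 32, 11.25)
#' envs <- synth_environment("uniform_wind", g, list(u = 10), seed = 1)
#' names(envs)
#' @export
synth_environment <- function(kind, grid, params = list(), seed = 1L,
                              months = 4:7) {
  kinds <- c("point_source", "two_patch", "uniform_wind", "zonal_jet",
             "ring_world")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    stop("unknown synthetic environment kind: ",
         paste(deparse(kind), collapse = ""), call. = FALSE)
  }
  p <- utils::modifyList(synth_defaults(kind, grid), params)
  with_preserved_seed(seed, {
    envs <- lapply(months, function(m) synth_month(kind, grid, p, m))
  })
  names(envs) <- as.character(months)
  envs
}

synth_defaults <- function(kind, grid) {
  centre <- c(round(grid$n_rows / 2), round(grid$n_cols / 2))
  switch(kind,
    point_source = list(cell = centre, amplitude = 2000),
    two_patch = list(cell = centre, offset_cols = round(grid$n_cols / 4),
                     sigma = 1.5, mass = 2000, u = 0, v = 0),
    uniform_wind = list(resource = 1, u = 10, v = 0),
    zonal_jet = list(u_max = 10, lat_jet = -50, width_deg = 15,
                     meanlog = 0, sdlog = 1),
    ring_world = list(lat_min = -65, lat_max = -30, u_max = 10,
                      lat_jet = -47.5, width_deg = 10, meanlog = 0, sdlog = 1)
  )
}

synth_month <- function(kind, grid, p, month) {
  nr <- grid$n_rows; nc <- grid$n_cols
  zero <- matrix(0, nr, nc)
  ocean_all <- ocean_mask(grid, matrix(TRUE, nr, nc))
  lat <- grid$lat0 - (seq_len(nr) - 1) * grid$cell_deg

  if (kind == "point_source") {
    vals <- zero
    vals[p$cell[1], p$cell[2]] <- p$amplitude
    res <- scalar_field(grid, month, vals)
    wnd <- wind_field(grid, month, zero, zero)
    return(monthly_environment(res, wnd, ocean_all))
  }
  if (kind == "two_patch") {
    east <- c(p$cell[1], wrap_col(p$cell[2] + p$offset_cols, nc))
    west <- c(p$cell[1], wrap_col(p$cell[2] - p$offset_cols, nc))
    vals <- gauss_patch(nr, nc, east, p$sigma, p$mass) +
      gauss_patch(nr, nc, west, p$sigma, p$mass)
    res <- scalar_field(grid, month, vals)
    wnd <- wind_field(grid, month, zero + p$u, zero + p$v)
    return(monthly_environment(res, wnd, ocean_all))
  }
  if (kind == "uniform_wind") {
    res <- scalar_field(grid, month, zero + p$resource)
    wnd <- wind_field(grid, month, zero + p$u, zero + p$v)
    return(monthly_environment(res, wnd, ocean_all))
  }
  if (kind == "zonal_jet") {
    res <- scalar_field(grid, month, patchy_field(nr, nc, p$meanlog, p$sdlog))
    u <- matrix(p$u_max * exp(-((lat - p$lat_jet) / p$width_deg)^2), nr, nc)
    wnd <- wind_field(grid, month, u, zero)
    return(monthly_environment(res, wnd, ocean_all))
  }
  # ring_world
  band <- lat >= p$lat_min & lat <= p$lat_max
  mask <- ocean_mask(grid, matrix(band, nr, nc))
  vals <- patchy_field(nr, nc, p$meanlog, p$sdlog)
  res <- apply_ocean_mask(scalar_field(grid, month, vals), mask)
  u <- matrix(p$u_max * exp(-((lat - p$lat_jet) / p$width_deg)^2), nr, nc)
  wnd <- wind_field(grid, month, u, zero)
  monthly_environment(res, wnd, mask)
}

# lognormal noise smoothed with a 3x3 box filter (longitude-wrapped)
patchy_field <- function(nr, nc, meanlog, sdlog) {
  raw <- matrix(stats::rlnorm(nr * nc, meanlog, sdlog), nr, nc)
  shift <- function(m, di, dj) {
    rows <- pmin(pmax(seq_len(nr) + di, 1), nr)       # clamp at lat edges
    cols <- wrap_col(seq_len(nc) + dj, nc)
    m[rows, cols, drop = FALSE]
  }
  acc <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) acc <- acc + shift(raw, di, dj)
  acc / 9
}

# symmetric Gaussian bump in lattice-index metric (exact mirror symmetry)
gauss_patch <- function(nr, nc, cell, sigma, mass) {
  di <- seq_len(nr) - cell[1]
  djraw <- abs(seq_len(nc) - cell[2])
  dj <- pmin(djraw, nc - djraw)
  mass * exp(-(outer(di^2, dj^2, `+`)) / (2 * sigma^2))
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
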