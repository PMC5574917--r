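test_that("resource potential reproduces single- and two-source closed forms", {
  g <- equator_grid()                     # row 2 centres on the equator
  m <- all_ocean(g)
  target <- c(2L, 1L)

  expect_equal(resource_potential(zero_field(g), m, target), 0)

  # single source: phi = -C/r with r from an independent haversine
  f1 <- point_field(g, list(list(cell = c(2L, 2L), value = 10)))
  r <- 2 * 6371 * asin(sin(15 * pi / 360))      # 15 deg of equatorial longitude
  expect_equal(resource_potential(f1, m, target), -10 / r, tolerance = 1e-12)

  # two sources straddling the target symmetrically: twice the single value
  f2 <- point_field(g, list(list(cell = c(2L, 2L), value = 10),
                            list(cell = c(2L, 24L), value = 10)))
  expect_equal(resource_potential(f2, m, target),
               2 * resource_potential(f1, m, target), tolerance = 1e-12)

  # more nearby resource => strictly more negative everywhere else
  bumped <- point_field(g, list(list(cell = c(2L, 2L), value = 10),
                                list(cell = c(3L, 10L), value = 1)))
  expect_lt(resource_potential(bumped, m, target),
            resource_potential(f1, m, target))
})

test_that("resource potential rejects unmasked land resource", {
  g <- test_grid()
  is_ocean <- const_matrix(g, TRUE); is_ocean[4, 4] <- FALSE
  m <- ocean_mask(g, is_ocean)
  f <- point_field(g, list(list(cell = c(4L, 4L), value = 2)))
  expect_error(resource_potential(f, m, c(8L, 8L)), "apply_ocean_mask")
  masked <- apply_ocean_mask(f, m)
  expect_equal(resource_potential(masked, m, c(8L, 8L)), 0)
})

test_that("production potential matches the brute-force oracle", {
  g <- test_grid()
  envs <- synth_environment("ring_world", g, seed = 21)
  env <- envs[[1]]
  set.seed(22)
  oc <- which(env$mask$is_ocean, arr.ind = TRUE)
  for (i in 1:20) {
    cell <- oc[sample.int(nrow(oc), 1), ]
    got <- resource_potential(env$resource, env$mask, cell)
    want <- oracle_resource_potential(env$resource, env$mask, cell)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("spherical displacement shrinks zonal components with latitude", {
  g <- grid_spec(32, 64, 5.625)
  centre <- c(16L, 10L)
  # due north: (0, 1) at any latitude; due south: (0, -1)
  expect_equal(spherical_displacement(g, centre, c(15L, 10L)), c(0, 1))
  expect_equal(spherical_displacement(g, centre, c(17L, 10L)), c(0, -1))

  geq <- equator_grid()
  expect_equal(spherical_displacement(geq, c(2L, 5L), c(2L, 6L)), c(1, 0))
  expect_equal(spherical_displacement(geq, c(2L, 5L), c(2L, 4L)), c(-1, 0))

  # northeast at ~60S: zonal magnitude < meridional (cos factor ~0.5)
  row60s <- which(abs((g$lat0 - (seq_len(32) - 1) * g$cell_deg) + 59.0625) < 1e-9)
  v <- spherical_displacement(g, c(row60s, 10L), c(row60s - 1L, 11L))
  expect_lt(abs(v[1]), abs(v[2]))
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  # matches the direct construction at the mean latitude
  lat_bar <- (g$lat0 - (row60s - 1) * g$cell_deg + g$lat0 - (row60s - 2) * g$cell_deg) / 2
  raw <- c(g$cell_deg * cos(lat_bar * pi / 180), g$cell_deg)
  expect_equal(v, raw / sqrt(sum(raw^2)), tolerance = 1e-12)

  expect_error(spherical_displacement(g, centre, c(16L, 13L)), "adjacent")
})

test_that("displacement wraps across the antimeridian", {
  g <- test_grid()
  v <- spherical_displacement(g, c(8L, g$n_cols), c(8L, 1L))
  expect_equal(v[1], 1, tolerance = 1e-12)    # eastward, not a 348-degree jump
  expect_gt(v[1], 0)
})

test_that("wind potential rewards downwind, is free crosswind", {
  g <- equator_grid()
  w <- uniform_wind_field(g, 10, 0)
  centre <- c(2L, 5L)
  expect_equal(wind_potential(w, centre, c(2L, 6L), g), -100)  # downwind
  expect_equal(wind_potential(w, centre, c(2L, 4L), g), 100)   # upwind
  expect_identical(wind_potential(w, centre, c(1L, 5L), g), 0) # crosswind
  expect_identical(wind_potential(w, centre, c(3L, 5L), g), 0)

  # antisymmetry and |w|^2 scaling on random winds
  set.seed(31)
  for (i in 1:25) {
    u <- rnorm(1, 0, 10); v <- rnorm(1, 0, 10); s <- runif(1, 0.2, 3)
    wf <- uniform_wind_field(g, u, v)
    ws <- uniform_wind_field(g, s * u, s * v)
    east <- wind_potential(wf, centre, c(2L, 6L), g)
    west <- wind_potential(wf, centre, c(2L, 4L), g)
    north <- wind_potential(wf, centre, c(1L, 5L), g)
    south <- wind_potential(wf, centre, c(3L, 5L), g)
    expect_equal(east, -west)
    expect_equal(north, -south)
    expect_equal(wind_potential(ws, centre, c(2L, 6L), g), s^2 * east,
                 tolerance = 1e-12)
  }
})

test_that("local potential combines terms and flags land", {
  g <- test_grid()
  envs <- synth_environment("ring_world", g, seed = 41)
  env <- envs[[1]]
  centre <- which(env$mask$is_ocean, arr.ind = TRUE)[10, ]

  p0 <- model_params(a = 0, kT = 0.1)
  lp0 <- local_potential(env, centre, p0)
  expect_equal(lp0$psi, lp0$phi)                    # a = 0: wind term vanishes

  pa <- model_params(a = 0.004, kT = 0.1)
  lpa <- local_potential(env, centre, pa)
  expect_equal(lpa$psi, lpa$phi + 0.004 * lpa$chi)  # exact by construction
  expect_equal(lpa$phi, lp0$phi)

  # permitted tracks the ocean mask
  nb <- neighbours8(g, centre)
  for (k in 1:8) {
    want <- nb$in_bounds[k] &&
      env$mask$is_ocean[nb$cells[k, 1], nb$cells[k, 2]]
    expect_identical(lpa$permitted[k], want)
  }

  land_cell <- which(!env$mask$is_ocean, arr.ind = TRUE)[1, ]
  expect_error(local_potential(env, land_cell, pa), "land")

  # zero wind: psi equals phi for any a
  calm <- monthly_environment(env$resource, uniform_wind_field(g, 0, 0),
                              env$mask)
  lpc <- local_potential(calm, centre, model_params(a = 5, kT = 1))
  expect_equal(lpc$psi, lpc$phi)
})

test_that("uniform resource plus eastward wind minimises psi due east", {
  g <- grid_spec(32, 64, 5.625)
  env <- synth_environment("uniform_wind", g, list(u = 10, v = 0),
                           seed = 1)[[1]]
  centre <- c(16L, 30L)
  lp <- local_potential(env, centre, model_params(a = 0.05, kT = 0.1))
  east_k <- which(lp$neighbour_cells[, 1] == centre[1] &
                    lp$neighbour_cells[, 2] == centre[2] + 1L)
  expect_equal(which.min(lp$psi), east_k)
})

test_that("local potential chi agrees with wind_potential per neighbour", {
  g <- test_grid()
  set.seed(55)
  u <- matrix(rnorm(g$n_rows * g$n_cols, 0, 8), g$n_rows, g$n_cols)
  v <- matrix(rnorm(g$n_rows * g$n_cols, 0, 8), g$n_rows, g$n_cols)
  env <- monthly_environment(scalar_field(g, 4L, const_matrix(g, 1)),
                             wind_field(g, 4L, u, v), all_ocean(g))
  pars <- model_params(a = 1, kT = 0.1)
  for (centre in list(c(2L, 1L), c(8L, 16L), c(15L, 32L))) {
    lp <- local_potential(env, centre, pars, potential_cache())
    for (k in which(lp$permitted)) {
      expect_equal(lp$chi[k],
                   wind_potential(env$wind, centre, lp$neighbour_cells[k, ], g),
                   tolerance = 1e-12)
    }
  }
})

test_that("the potential cache is transparent and shared safely", {
  g <- test_grid()
  env <- synth_environment("ring_world", g, seed = 51)[[1]]
  pars <- model_params(a = 0.003, kT = 0.1)
  cache <- potential_cache()
  oc <- which(env$mask$is_ocean, arr.ind = TRUE)
  for (i in c(3, 17, 3, 40, 17)) {          # repeats hit the memo
    cell <- oc[i, ]
    expect_identical(local_potential(env, cell, pars, cache)$phi,
                     local_potential(env, cell, pars, NULL)$phi)
  }
  expect_gt(length(ls(cache)), 0)
})

test_that("model parameters are validated", {
  expect_error(model_params(a = -0.1, kT = 0.1))
  expect_error(model_params(a = 0.005, kT = 0))      # kT = 0 rejected
  expect_error(model_params(a = 0.005, kT = 0.1, airspeed = -1))
  p <- model_params(a = 0.005, kT = 0.1)
  expect_equal(p$airspeed, 60)
})
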