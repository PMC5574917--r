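test_that("colonies snap to the nearest ocean cell deterministically", {
  g <- test_grid()
  m <- all_ocean(g)
  centre <- cell_centre(g, c(8L, 16L))
  col <- colony("on-centre", centre[1], centre[2])
  expect_equal(unname(snap_to_ocean(col, m)), c(8, 16))

  # one-cell island: exhaustive scan oracle with the (row, col) tie rule
  island <- const_matrix(g, TRUE); island[8, 16] <- FALSE
  mi <- ocean_mask(g, island)
  got <- snap_to_ocean(col, mi)
  d <- flywaysim:::dist_to_all_latlon(g, centre[1], centre[2])
  d[!island] <- Inf
  cand <- which(d == min(d), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(cand[1, ]))
  expect_true(island[got[1], got[2]])

  expect_error(colony("bad", -95, 0))
})

test_that("a zero-duration run is just the start cell", {
  g <- test_grid()
  envs <- synth_environment("uniform_wind", g, seed = 1)
  tr <- simulate_bird(colony("x", -50, 0), model_params(0, 0.1), envs,
                      duration_months = 0, seed = 1)
  expect_equal(nrow(tr$steps), 1)
  expect_equal(tr$steps$clock_h, 0)
})

test_that("trajectories are reproducible and legal", {
  g <- test_grid()
  envs <- synth_environment("ring_world", g, seed = 8)
  col <- colony("probe", -50, 30)
  pars <- model_params(a = 0.003, kT = 0.1)
  t1 <- simulate_bird(col, pars, envs, duration_months = 2, seed = 42)
  t2 <- simulate_bird(col, pars, envs, duration_months = 2, seed = 42)
  expect_identical(t1$steps, t2$steps)
  t3 <- simulate_bird(col, pars, envs, duration_months = 2, seed = 43)
  expect_false(identical(t1$steps, t3$steps))

  expect_legal_trajectory(t1, envs[[1]]$mask)
  # the run ends with the first step at or past the total duration
  total <- sum(c(720, 744)[1:2])            # April + May
  n <- nrow(t1$steps)
  expect_gte(t1$steps$clock_h[n], total)
  expect_lt(t1$steps$clock_h[n - 1], total)
  # months recorded in order, switching at the April boundary
  expect_equal(sort(unique(t1$steps$month)), c(4, 5))
  expect_equal(t1$steps$month[t1$steps$clock_h < 720][1], 4)
})

test_that("ensembles aggregate trajectories, occupancy and endpoints", {
  g <- test_grid()
  envs <- synth_environment("ring_world", g, seed = 8)
  col <- colony("probe", -50, 30)
  pars <- model_params(a = 0.003, kT = 0.1)
  ens <- simulate_ensemble(col, pars, envs, n_birds = 5, base_seed = 100,
                           duration_months = 1)

  # bird b uses seed base_seed + b; a lone bird reproduces ensemble member 1
  solo <- simulate_bird(col, pars, envs, duration_months = 1, seed = 101)
  expect_identical(ens$trajectories[[1]]$steps, solo$steps)

  # occupancy conservation: every step visits one cell, plus the starts
  total_steps <- sum(vapply(ens$trajectories,
                            function(tr) nrow(tr$steps) - 1L, integer(1)))
  expect_equal(sum(ens$occupancy), total_steps + 5)
  expect_equal(sum(ens$endpoints), 5)
  expect_true(all(ens$occupancy >= ens$endpoints))

  ens2 <- simulate_ensemble(col, pars, envs, n_birds = 5, base_seed = 100,
                            duration_months = 1)
  expect_identical(tidy(ens), tidy(ens2))
  expect_identical(ens$occupancy, ens2$occupancy)
})

test_that("parameter sweeps cover the requested grid with stable seeding", {
  g <- test_grid()
  envs <- synth_environment("ring_world", g, seed = 8)
  col <- colony("probe", -50, 30)
  sw <- sweep_parameters(col, a_values = c(0.001, 0.002),
                         kT_values = c(0.05, 0.1), envs = envs,
                         n_birds = 2, base_seed = 7, duration_months = 1)
  expect_s3_class(sw, "flyway_sweep")
  expect_equal(nrow(sw), 4)
  expect_equal(sw$a, c(0.001, 0.002, 0.001, 0.002))   # a varies fastest
  expect_equal(sw$kT, c(0.05, 0.05, 0.1, 0.1))
  expect_equal(vapply(sw$ensemble, function(e) as.numeric(e$base_seed),
                      numeric(1)),
               7 + (1:4) * 1e6)

  # extending a grid leaves the shared pairs untouched
  sw1 <- sweep_parameters(col, a_values = 0.001, kT_values = c(0.05, 0.1),
                          envs = envs, n_birds = 2, base_seed = 7,
                          duration_months = 1)
  expect_equal(nrow(sw1), 2)
  expect_identical(tidy(sw1$ensemble[[1]]), tidy(sw$ensemble[[1]]))

  gl <- glance(sw)
  expect_equal(nrow(gl), 4)
  expect_true(all(gl$n_birds == 2))
})

test_that("directional split counts on-meridian endpoints as east", {
  g <- test_grid()
  envs <- synth_environment("uniform_wind", g, seed = 1)
  col <- colony("x", -50, 0)
  ens0 <- simulate_ensemble(col, model_params(0, 0.1), envs, n_birds = 3,
                            base_seed = 1, duration_months = 0)
  split <- directional_split(ens0)        # all endpoints at the start cell
  expect_equal(split$fraction_east, 1)
  expect_equal(split$fraction_west, 0)
  expect_equal(split$fraction_east + split$fraction_west, 1)
})

test_that("tidiers expose one row per step and sensible summaries", {
  g <- test_grid()
  envs <- synth_environment("ring_world", g, seed = 8)
  ens <- simulate_ensemble(colony("probe", -50, 30),
                           model_params(0.003, 0.1), envs,
                           n_birds = 3, base_seed = 9, duration_months = 1)
  tb <- tidy(ens)
  expect_equal(nrow(tb),
               sum(vapply(ens$trajectories, function(t) nrow(t$steps),
                          integer(1))))
  expect_setequal(unique(tb$bird_id), 1:3)
  expect_true(all(c("lat", "lon", "clock_h", "month") %in% names(tb)))

  gl <- glance(ens)
  expect_equal(gl$n_birds, 3)
  expect_equal(gl$fraction_east + gl$fraction_west, 1)
  expect_gte(gl$mean_displacement_km, 0)
})

test_that("trajectory and density writers round-trip", {
  g <- test_grid()
  envs <- synth_environment("ring_world", g, seed = 8)
  ens <- simulate_ensemble(colony("probe", -50, 30),
                           model_params(0.003, 0.1), envs,
                           n_birds = 2, base_seed = 9, duration_months = 1)
  dir <- tempfile()
  write_ensemble(ens, dir, geojson = TRUE)
  expect_true(all(file.exists(file.path(
    dir, c("trajectories.csv", "occupancy.csv", "endpoints.csv",
           "metadata.json", "trajectories.geojson")))))

  back <- utils::read.csv(file.path(dir, "trajectories.csv"))
  expect_equal(nrow(back), nrow(tidy(ens)))
  expect_equal(back$row, tidy(ens)$row)

  occ <- read_grid_csv(file.path(dir, "occupancy.csv"))
  expect_identical(occ$values, ens$occupancy + 0)     # stored as numeric

  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$params$a, 0.003)
  expect_equal(meta$n_birds, 2)
  expect_equal(meta$bird_seeds, 9 + 1:2)

  gj <- jsonlite::read_json(file.path(dir, "trajectories.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 2)
  first_pt <- gj$features[[1]]$geometry$coordinates
  while (is.list(first_pt[[1]])) first_pt <- first_pt[[1]]
  s1 <- ens$trajectories[[1]]$steps
  expect_equal(unlist(first_pt), c(s1$lon[1], s1$lat[1]))  # lon,lat order
})

test_that("the built-in colony table carries the five tracked populations", {
  ct <- albatross_colonies()
  expect_equal(nrow(ct), 5)
  expect_true(all(abs(ct$lat) <= 90) && all(abs(ct$lon) <= 180))
  fk <- ct[ct$name == "Falkland Islands", ]
  expect_equal(c(fk$lat, fk$lon), c(-51.0, -61.1))
  # on a coarse all-ocean grid the Falklands snap to the containing cell
  g <- test_grid()
  cell <- snap_to_ocean(fk, all_ocean(g))
  cc <- cell_centre(g, cell)
  expect_lte(abs(cc[1] - fk$lat), g$cell_deg / 2 + 1e-9)
  d <- abs(flywaysim:::wrap_lon_delta(cc[2] - fk$lon))
  expect_lte(d, g$cell_deg / 2 + 1e-9)
})
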