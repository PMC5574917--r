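# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# coarse global grid used by most tests
test_grid <- function() grid_spec(16, 32, 11.25)

# grid whose second row of cell centres sits exactly on the equator
equator_grid <- function() grid_spec(3, 24, 15, lat0 = 15)

all_ocean <- function(grid) {
  ocean_mask(grid, matrix(TRUE, grid$n_rows, grid$n_cols))
}

const_matrix <- function(grid, x) matrix(x, grid$n_rows, grid$n_cols)

uniform_wind_field <- function(grid, u, v, month = 4L) {
  wind_field(grid, month, const_matrix(grid, u), const_matrix(grid, v))
}

zero_field <- function(grid, month = 4L) {
  scalar_field(grid, month, const_matrix(grid, 0))
}

# scalar field with named point values: list(list(cell =, value =), ...)
point_field <- function(grid, points, month = 4L) {
  m <- const_matrix(grid, 0)
  for (p in points) m[p$cell[1], p$cell[2]] <- p$value
  scalar_field(grid, month, m)
}

# write a matrix in the CSV-grid dialect to a temp file, returning the path
write_tmp_grid <- function(values, grid, month = 4L) {
  path <- tempfile(fileext = ".csv")
  write_grid_csv(values, grid, month, path)
  path
}

# local_potential built directly from psi values (bypasses the environment)
raw_local_potential <- function(psi, permitted = rep(TRUE, 8),
                                grid = test_grid(), centre = c(8L, 16L)) {
  nb <- neighbours8(grid, centre)
  structure(list(centre = centre, neighbour_cells = nb$cells,
                 phi = psi, chi = numeric(8), psi = psi,
                 permitted = permitted),
            class = "local_potential")
}

expect_legal_trajectory <- function(tr, mask) {
  s <- tr$steps
  expect_true(all(mask$is_ocean[cbind(s$row, s$col)]))
  for (k in seq_len(nrow(s) - 1)) {
    expect_true(flywaysim:::is_adjacent(tr$grid,
                                        c(s$row[k], s$col[k]),
                                        c(s$row[k + 1], s$col[k + 1])))
  }
  expect_true(all(diff(s$clock_h) > 0))
}
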