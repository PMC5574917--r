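#' Read and write the CSV-grid dialect
#'
#' The package's plain-text gridded format: a header line
#' `#grid n_rows n_cols cell_deg lat0 lon0 month` followed by `n_rows`
#' comma-separated data rows (row 1 = northernmost), with `NA` for missing
#' cells. Values are written with 17 significant digits so a write/read
#' round trip is bit-exact.
#'
#' @param path File path.
#' @return `read_grid_csv()` returns a list with `grid` (a [grid_spec()]),
#'   `month` and `values` (numeric matrix).
#' @export
read_grid_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#grid")) {
    stop(path, ": missing '#grid' header line", call. = FALSE)
  }
  h <- as.numeric(strsplit(trimws(sub("^#grid", "", header)), "\\s+")[[1]])
  if (length(h) != 6 || anyNA(h)) {
    stop(path, ": malformed '#grid' header", call. = FALSE)
  }
  grid <- grid_spec(h[1], h[2], h[3], h[4], h[5])
  values <- as.matrix(utils::read.table(path, sep = ",", skip = 1,
                                        na.strings = "NA",
                                        colClasses = "numeric"))
  dimnames(values) <- NULL
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(path, ": data block does not match header dimensions", call. = FALSE)
  }
  list(grid = grid, month = as.integer(h[6]), values = values)
}

#' @rdname read_grid_csv
#' @param values Numeric matrix to write (`NA` allowed).
#' @param grid A [grid_spec()] matching `values`.
#' @param month Month index stored in the header.
#' @export
write_grid_csv <- function(values, grid, month, path) {
  check_dims(grid, values, "values")
  header <- sprintf("#grid %d %d %s %s %s %d",
                    grid$n_rows, grid$n_cols,
                    fmt17(grid$cell_deg), fmt17(grid$lat0), fmt17(grid$lon0),
                    as.integer(month))
  rows <- apply(values, 1, function(r) paste(fmt17(r), collapse = ","))
  writeLines(c(header, rows), path)
  invisible(path)
}

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Load a gridded resource field
#'
#' Reads one monthly scalar concentration field (chlorophyll-a, mg m^-3)
#' from a CSV-grid file and validates it against the expected lattice. No
#' silent reshaping: a dimension or geometry mismatch is an error, as is any
#' negative concentration (corrupt input). Missing cells come through as
#' `NA` and are resolved by [build_climatology()] and [apply_ocean_mask()].
#'
#' @param path CSV-grid file.
#' @param month Expected month index 1-12.
#' @param grid Expected [grid_spec()].
#' @return A [scalar_field()].
#' @export
load_scalar_field <- function(path, month, grid) {
  raw <- read_grid_csv(path)
  check_same_grid(raw$grid, grid, path)
  scalar_field(grid, month, raw$values)
}

#' Load a gridded wind field
#'
#' Reads the zonal and meridional components of one monthly wind field from
#' a pair of CSV-grid files. Both components are required; missing cells are
#' only acceptable when fields are averaged into a climatology
#' ([build_climatology()]), so `NA` cells here are an error.
#'
#' @param path Named character vector or list with elements `u` and `v`,
#'   each a CSV-grid file path.
#' @param month Expected month index 1-12.
#' @param grid Expected [grid_spec()].
#' @return A [wind_field()].
#' @export
load_wind_field <- function(path, month, grid) {
  comp <- read_wind_components(path, grid)
  if (anyNA(comp$u) || anyNA(comp$v)) {
    stop("wind field has missing cells; average multiple years with ",
         "build_climatology() to fill gaps", call. = FALSE)
  }
  wind_field(grid, month, comp$u, comp$v)
}

read_wind_components <- function(path, grid) {
  path <- as.list(path)
  if (is.null(path$u) || is.null(path$v)) {
    stop("wind input must provide both 'u' and 'v' components", call. = FALSE)
  }
  u <- read_grid_csv(path$u)
  v <- read_grid_csv(path$v)
  check_same_grid(u$grid, grid, path$u)
  check_same_grid(v$grid, grid, path$v)
  list(u = u$values, v = v$values)
}

check_same_grid <- function(got, want, path) {
  if (!same_grid(got, want)) {
    stop(path, ": file grid (", format(got), ") does not match expected grid (",
         format(want), ")", call. = FALSE)
  }
}

#' Build a monthly climatology from several years of data
#'
#' Averages one calendar month over multiple years, cell-wise and ignoring
#' missing values, so that transient gaps (cloud cover in ocean-colour data)
#' are filled while only year-on-year predictable patterns are retained.
#' For resource fields a cell missing in every year stays `NA` (it will be
#' excluded by masking). For wind fields the simulator needs a complete
#' vector field, so a cell missing in every year is filled from its nearest
#' non-missing cell, with a warning.
#'
#' @param paths For `type = "scalar"`, a character vector of yearly CSV-grid
#'   files for the same month. For `type = "wind"`, a list of yearly
#'   `c(u = , v = )` path pairs.
#' @param month Month index 1-12.
#' @param grid Expected [grid_spec()].
#' @param type `"scalar"` or `"wind"`.
#' @return A [scalar_field()] or [wind_field()].
#' @export
build_climatology <- function(paths, month, grid, type = c("scalar", "wind")) {
  type <- match.arg(type)
  if (length(paths) == 0) stop("empty file list", call. = FALSE)
  if (type == "scalar") {
    stacks <- lapply(paths, function(p) {
      raw <- read_grid_csv(p)
      check_same_grid(raw$grid, grid, p)
      if (any(raw$values < 0, na.rm = TRUE)) {
        stop(p, ": negative concentrations", call. = FALSE)
      }
      raw$values
    })
    scalar_field(grid, month, cellwise_mean(stacks))
  } else {
    comps <- lapply(paths, read_wind_components, grid = grid)
    u <- cellwise_mean(lapply(comps, `[[`, "u"))
    v <- cellwise_mean(lapply(comps, `[[`, "v"))
    if (anyNA(u) || anyNA(v)) {
      if (all(is.na(u)) || all(is.na(v))) {
        stop("wind climatology entirely missing", call. = FALSE)
      }
      warning("wind cells missing in all years; filled from nearest ",
              "non-missing cell", call. = FALSE)
      u <- nearest_fill(u, grid)
      v <- nearest_fill(v, grid)
    }
    wind_field(grid, month, u, v)
  }
}

cellwise_mean <- function(stack) {
  tot <- Reduce(`+`, lapply(stack, function(m) ifelse(is.na(m), 0, m)))
  n <- Reduce(`+`, lapply(stack, function(m) !is.na(m)))
  out <- tot / n          # 0/0 -> NaN where missing in all years
  out[n == 0] <- NA
  out
}

#' Read and write environment directories
#'
#' An environment directory holds one simulation-ready environment set in
#' the CSV-grid dialect: `mask.csv` plus `chl_<m>.csv`, `u_<m>.csv` and
#' `v_<m>.csv` for each month `m`. `write_environment()` lays one out from
#' a list of [monthly_environment()]s; `read_environment()` loads it back
#' (the grid is taken from the mask file).
#'
#' @param envs Named list of [monthly_environment()]s (names = month
#'   indices), as from [synth_environment()].
#' @param dir Directory path.
#' @return `read_environment()` returns the named environment list;
#'   `write_environment()` returns `dir` invisibly.
#' @export
write_environment <- function(envs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- envs[[1]]$grid
  write_grid_csv(envs[[1]]$mask$is_ocean + 0, grid, envs[[1]]$month,
                 file.path(dir, "mask.csv"))
  for (env in envs) {
    m <- env$month
    write_grid_csv(env$resource$values, grid, m,
                   file.path(dir, sprintf("chl_%d.csv", m)))
    write_grid_csv(env$wind$u, grid, m, file.path(dir, sprintf("u_%d.csv", m)))
    write_grid_csv(env$wind$v, grid, m, file.path(dir, sprintf("v_%d.csv", m)))
  }
  invisible(dir)
}

#' @rdname write_environment
#' @param months Month indices to load; by default every month with a
#'   `chl_<m>.csv` present.
#' @export
read_environment <- function(dir, months = NULL) {
  raw_mask <- read_grid_csv(file.path(dir, "mask.csv"))
  grid <- raw_mask$grid
  mask <- ocean_mask(grid, raw_mask$values)
  if (is.null(months)) {
    files <- list.files(dir, pattern = "^chl_\\d+\\.csv$")
    months <- sort(as.integer(gsub("[^0-9]", "", files)))
  }
  if (length(months) == 0) stop("no monthly fields in ", dir, call. = FALSE)
  envs <- lapply(months, function(m) {
    res <- load_scalar_field(file.path(dir, sprintf("chl_%d.csv", m)), m, grid)
    wnd <- load_wind_field(c(u = file.path(dir, sprintf("u_%d.csv", m)),
                             v = file.path(dir, sprintf("v_%d.csv", m))),
                           m, grid)
    monthly_environment(res, wnd, mask)
  })
  names(envs) <- as.character(months)
  envs
}

# replace each NA cell by the value of the great-circle-nearest non-NA cell
nearest_fill <- function(m, grid) {
  holes <- which(is.na(m), arr.ind = TRUE)
  for (k in seq_len(nrow(holes))) {
    d <- dist_to_all_cells(grid, holes[k, ])
    d[is.na(m)] <- Inf
    m[holes[k, 1], holes[k, 2]] <- m[which.min(d)]
  }
  m
}
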