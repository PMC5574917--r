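#' Write trajectories to CSV
#'
#' One row per step with columns `bird_id`, `step`, `clock_h`, `month`,
#' `row`, `col`, `lat`, `lon`.
#'
#' @param x A `flyway_trajectory` or `flyway_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  tb <- tidy(x)
  utils::write.csv(
    tb[, c("bird_id", "step", "clock_h", "month", "row", "col", "lat", "lon")],
    path, row.names = FALSE)
  invisible(path)
}

#' Write trajectories as GeoJSON LineStrings
#'
#' One `LineString` feature per bird, coordinates in (lon, lat) order.
#' Segments that cross the antimeridian are split into separate LineStrings
#' (a `MultiLineString`) so plotting software does not draw a line across
#' the whole map.
#'
#' @param x A `flyway_trajectory` or `flyway_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_geojson <- function(x, path) {
  trajs <- if (inherits(x, "flyway_ensemble")) x$trajectories else list(x)
  features <- lapply(trajs, function(tr) {
    s <- tr$steps
    # split where consecutive longitudes jump across the dateline
    brk <- which(abs(diff(s$lon)) > 180)
    bounds <- c(0, brk, nrow(s))
    lines <- lapply(seq_len(length(bounds) - 1), function(k) {
      idx <- (bounds[k] + 1):bounds[k + 1]
      unname(lapply(idx, function(i) c(s$lon[i], s$lat[i])))
    })
    lines <- lines[lengths(lines) > 1]
    geometry <- if (length(lines) == 1) {
      list(type = "LineString", coordinates = lines[[1]])
    } else {
      list(type = "MultiLineString", coordinates = lines)
    }
    list(type = "Feature",
         properties = list(bird_id = tr$bird_id, colony = tr$colony$name[1],
                           a = tr$params$a, kT = tr$params$kT,
                           seed = tr$seed),
         geometry = geometry)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ensemble outputs to a directory
#'
#' Writes `trajectories.csv`, the `occupancy.csv` and `endpoints.csv`
#' density grids (CSV-grid dialect), and a `metadata.json` sidecar
#' recording parameters, seeds, the grid convention and the package
#' version.
#'
#' @param result A [flyway_ensemble][simulate_ensemble()].
#' @param dir Output directory (created if needed).
#' @param geojson Also write `trajectories.geojson`?
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(result, dir, geojson = FALSE) {
  stopifnot(inherits(result, "flyway_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory_csv(result, file.path(dir, "trajectories.csv"))
  month <- result$trajectories[[1]]$steps$month[1]
  write_grid_csv(result$occupancy, result$grid, month,
                 file.path(dir, "occupancy.csv"))
  write_grid_csv(result$endpoints, result$grid, month,
                 file.path(dir, "endpoints.csv"))
  if (geojson) {
    write_trajectory_geojson(result, file.path(dir, "trajectories.geojson"))
  }
  meta <- list(
    colony = as.list(result$colony[1, ]),
    params = unclass(result$params),
    n_birds = length(result$trajectories),
    base_seed = result$base_seed,
    bird_seeds = vapply(result$trajectories,
                        function(tr) as.numeric(tr$seed), numeric(1)),
    grid = unclass(result$grid),
    grid_convention = "row 1 = northernmost; col 1 = westernmost; centres at lat0-(i-1)*cell_deg, lon0+(j-1)*cell_deg",
    distance_unit = "km (sphere radius 6371 km)",
    software = paste0("flywaysim ",
                      as.character(utils::packageVersion("flywaysim")))
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
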