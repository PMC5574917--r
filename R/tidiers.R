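#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy simulation results
#'
#' `tidy()` on a trajectory returns its step table with identifying columns
#' (bird, colony, a, kT, seed) prepended; on an ensemble it row-binds the
#' tidied trajectories; on a sweep it additionally carries the pair index.
#' `glance()` gives a one-row summary per object: run length, great-circle
#' displacement from start to end, and the east/west endpoint split for
#' ensembles.
#'
#' @param x A `flyway_trajectory`, `flyway_ensemble` or `flyway_sweep`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.flyway_trajectory <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(bird_id = x$bird_id, colony = x$colony$name[1],
                   a = x$params$a, kT = x$params$kT, seed = x$seed,
                   .rows = nrow(x$steps)),
    x$steps
  )
}

#' @rdname tidy.flyway_trajectory
#' @export
tidy.flyway_ensemble <- function(x, ...) {
  purrr::map_dfr(x$trajectories, tidy)
}

#' @rdname tidy.flyway_trajectory
#' @export
tidy.flyway_sweep <- function(x, ...) {
  purrr::map2_dfr(x$pair, x$ensemble,
                  function(p, e) dplyr::mutate(tidy(e), pair = p, .before = 1))
}

#' @rdname tidy.flyway_trajectory
#' @export
glance.flyway_trajectory <- function(x, ...) {
  s <- x$steps
  n <- nrow(s)
  tibble::tibble(
    bird_id = x$bird_id, colony = x$colony$name[1],
    a = x$params$a, kT = x$params$kT,
    n_steps = n - 1L, hours = s$clock_h[n],
    displacement_km = haversine_km(s$lat[1], s$lon[1], s$lat[n], s$lon[n]),
    end_lat = s$lat[n], end_lon = s$lon[n]
  )
}

#' @rdname tidy.flyway_trajectory
#' @export
glance.flyway_ensemble <- function(x, ...) {
  birds <- purrr::map_dfr(x$trajectories, glance)
  split <- directional_split(x)
  tibble::tibble(
    colony = x$colony$name[1], a = x$params$a, kT = x$params$kT,
    n_birds = length(x$trajectories),
    total_steps = sum(birds$n_steps),
    mean_displacement_km = mean(birds$displacement_km),
    fraction_east = split$fraction_east,
    fraction_west = split$fraction_west
  )
}

#' @rdname tidy.flyway_trajectory
#' @export
glance.flyway_sweep <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(pair = x$pair),
                   purrr::map_dfr(x$ensemble, glance))
}
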