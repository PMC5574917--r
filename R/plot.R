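#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gridded field
#'
#' Raster plot of a scalar field (log10 colour scale by default, the usual
#' way to display ocean chlorophyll), an ocean mask, or a wind field (arrow
#' glyphs subsampled to at most `max_arrows` cells).
#'
#' @param object A `scalar_field`, `ocean_mask` or `wind_field`.
#' @param log10 Colour by log10(value) for scalar fields?
#' @param max_arrows Upper bound on plotted wind arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_field <- function(object, log10 = TRUE, ...) {
  tb <- tidy(object)
  tb$fill <- if (log10) log10(pmax(tb$value, 1e-3)) else tb$value
  ggplot2::ggplot(tb, ggplot2::aes(.data$lon, .data$lat, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (log10) "log10 conc." else "conc.") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' @rdname autoplot.scalar_field
#' @export
autoplot.ocean_mask <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$is_ocean)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey30"),
                               name = "ocean") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' @rdname autoplot.scalar_field
#' @export
autoplot.wind_field <- function(object, max_arrows = 1024, ...) {
  tb <- tidy(object)
  stride <- ceiling(sqrt(nrow(tb) / max_arrows))
  tb <- dplyr::filter(tb, .data$row %% stride == 0, .data$col %% stride == 0)
  sc <- object$grid$cell_deg * stride / max(sqrt(tb$u^2 + tb$v^2), 1e-9)
  ggplot2::ggplot(tb, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$lon + sc * .data$u,
                   yend = .data$lat + sc * .data$v),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.03, "inches")),
      linewidth = 0.2) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Plot simulated trajectories and densities
#'
#' A trajectory is drawn as its path over the lattice (dateline-crossing
#' segments dropped rather than wrapped); an ensemble as its occupancy
#' density raster with endpoint cells overlaid.
#'
#' @param object A `flyway_trajectory` or `flyway_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flyway_trajectory <- function(object, ...) {
  tb <- tidy(object)
  tb$leg <- cumsum(c(0, abs(diff(tb$lon)) > 180))
  ggplot2::ggplot(tb, ggplot2::aes(.data$lon, .data$lat,
                                   group = .data$leg)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::geom_point(data = tb[c(1, nrow(tb)), ],
                        ggplot2::aes(colour = factor(.data$step == 0))) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick"),
                                 labels = c(`TRUE` = "start", `FALSE` = "end"),
                                 name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' @rdname autoplot.flyway_trajectory
#' @export
autoplot.flyway_ensemble <- function(object, ...) {
  occ <- field_tbl(object$grid, visits = as.vector(object$occupancy),
                   endpoints = as.vector(object$endpoints))
  ggplot2::ggplot(occ, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$visits + 1))) +
    ggplot2::geom_point(data = dplyr::filter(occ, .data$endpoints > 0),
                        ggplot2::aes(size = .data$endpoints),
                        colour = "firebrick", alpha = 0.7) +
    ggplot2::scale_fill_viridis_c(name = "log10 visits") +
    ggplot2::scale_size_area(max_size = 3, name = "endpoints") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = sprintf("%s: a = %g, kT = %g",
                                  object$colony$name[1], object$params$a,
                                  object$params$kT))
}
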