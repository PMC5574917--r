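#' Gridded monthly resource field
#'
#' A scalar concentration field (chlorophyll-a, mg m^-3) on a lattice.
#' Values must be non-negative where present; `NA` marks missing data (land
#' in raw satellite products, or residual cloud gaps after climatological
#' averaging). After [apply_ocean_mask()] every land cell holds exactly 0 so
#' that it contributes nothing to potential sums.
#'
#' @param grid A [grid_spec()].
#' @param month Month index 1-12.
#' @param values Numeric `n_rows x n_cols` matrix.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(grid, month, values) {
  check_month(month)
  check_dims(grid, values, "values")
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative concentrations: corrupt input", call. = FALSE)
  }
  if (any(is.infinite(values))) stop("non-finite concentrations", call. = FALSE)
  structure(list(grid = grid, month = as.integer(month), values = values,
                 masked = FALSE),
            class = "scalar_field")
}

#' Gridded monthly wind field
#'
#' Zonal (`u`, positive eastward) and meridional (`v`, positive northward)
#' wind components in m s^-1 on a lattice.
#'
#' @param grid A [grid_spec()].
#' @param month Month index 1-12.
#' @param u,v Numeric `n_rows x n_cols` matrices.
#' @return An object of class `wind_field`.
#' @export
wind_field <- function(grid, month, u, v) {
  check_month(month)
  check_dims(grid, u, "u")
  check_dims(grid, v, "v")
  structure(list(grid = grid, month = as.integer(month), u = u, v = v),
            class = "wind_field")
}

#' Binary ocean mask
#'
#' @param grid A [grid_spec()].
#' @param is_ocean Logical `n_rows x n_cols` matrix; `TRUE` on ocean.
#' @return An object of class `ocean_mask`.
#' @export
ocean_mask <- function(grid, is_ocean) {
  check_dims(grid, is_ocean, "is_ocean")
  if (is.numeric(is_ocean)) {
    if (!all(is_ocean %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
    is_ocean <- is_ocean == 1
  }
  if (anyNA(is_ocean)) stop("mask must not contain NA", call. = FALSE)
  if (!any(is_ocean)) stop("mask has no ocean cell", call. = FALSE)
  structure(list(grid = grid, is_ocean = is_ocean), class = "ocean_mask")
}

#' One month's complete environment
#'
#' Bundles a masked resource field, a wind field and the ocean mask on a
#' common grid; the unit consumed by the simulator for one calendar month.
#'
#' @param resource A [scalar_field()], already masked to ocean (it is
#'   masked here if not).
#' @param wind A [wind_field()] on the same grid and month.
#' @param mask An [ocean_mask()] on the same grid.
#' @return An object of class `monthly_environment`.
#' @export
monthly_environment <- function(resource, wind, mask) {
  stopifnot(inherits(resource, "scalar_field"), inherits(wind, "wind_field"),
            inherits(mask, "ocean_mask"))
  if (!same_grid(resource$grid, wind$grid) || !same_grid(resource$grid, mask$grid)) {
    stop("resource, wind and mask must share one grid", call. = FALSE)
  }
  if (resource$month != wind$month) {
    stop("resource and wind months differ", call. = FALSE)
  }
  if (anyNA(wind$u) || anyNA(wind$v)) {
    stop("wind field has missing cells; build a climatology first", call. = FALSE)
  }
  if (!isTRUE(resource$masked)) resource <- apply_ocean_mask(resource, mask)
  structure(list(grid = resource$grid, month = resource$month,
                 resource = resource, wind = wind, mask = mask),
            class = "monthly_environment")
}

#' Zero out resource values outside the ocean
#'
#' Satellite chlorophyll products include inland lakes (Lake Victoria and
#' similar) with very high concentrations that are inaccessible to seabirds.
#' Masking sets every non-ocean cell to exactly 0 so it is excluded from all
#' potential sums; ocean cells are unchanged (missing ocean cells stay `NA`).
#' Idempotent.
#'
#' @param field A [scalar_field()].
#' @param mask An [ocean_mask()] on the same grid.
#' @return The masked `scalar_field` (with `masked = TRUE`).
#' @export
apply_ocean_mask <- function(field, mask) {
  stopifnot(inherits(field, "scalar_field"), inherits(mask, "ocean_mask"))
  if (!same_grid(field$grid, mask$grid)) stop("grid mismatch", call. = FALSE)
  field$values[!mask$is_ocean] <- 0
  field$masked <- TRUE
  field
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> month %d on %s; range [%g, %g]%s%s\n",
              x$month, format(x$grid),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              if (anyNA(x$values)) sprintf("; %d NA", sum(is.na(x$values))) else "",
              if (isTRUE(x$masked)) "; masked" else ""))
  invisible(x)
}

#' @export
print.wind_field <- function(x, ...) {
  cat(sprintf("<wind_field> month %d on %s; |w| up to %.2f m/s\n",
              x$month, format(x$grid), sqrt(max(x$u^2 + x$v^2, na.rm = TRUE))))
  invisible(x)
}

#' @export
print.ocean_mask <- function(x, ...) {
  cat(sprintf("<ocean_mask> %s; %.1f%% ocean\n", format(x$grid),
              100 * mean(x$is_ocean)))
  invisible(x)
}

#' @export
print.monthly_environment <- function(x, ...) {
  cat(sprintf("<monthly_environment> month %d on %s\n", x$month, format(x$grid)))
  invisible(x)
}

#' Convert a gridded field to a tibble
#'
#' One row per cell with row/col indices, cell-centre coordinates and the
#' field's values; the long format used by the ggplot2 helpers.
#'
#' @param x A `scalar_field`, `wind_field` or `ocean_mask`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `lat`, `lon` and the field
#'   values (`value`, or `u`/`v`, or `is_ocean`).
#' @export
tidy.scalar_field <- function(x, ...) {
  field_tbl(x$grid, value = as.vector(x$values))
}

#' @rdname tidy.scalar_field
#' @export
tidy.wind_field <- function(x, ...) {
  field_tbl(x$grid, u = as.vector(x$u), v = as.vector(x$v))
}

#' @rdname tidy.scalar_field
#' @export
tidy.ocean_mask <- function(x, ...) {
  field_tbl(x$grid, is_ocean = as.vector(x$is_ocean))
}

field_tbl <- function(grid, ...) {
  idx <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  tibble::tibble(
    row = idx$row, col = idx$col,
    lat = grid$lat0 - (idx$row - 1) * grid$cell_deg,
    lon = wrap_lon(grid$lon0 + (idx$col - 1) * grid$cell_deg),
    ...
  )
}

check_month <- function(month) {
  if (length(month) != 1 || is.na(month) || month < 1 || month > 12 ||
      month != as.integer(month)) {
    stop("month must be a single integer in 1..12", call. = FALSE)
  }
}

check_dims <- function(grid, m, what) {
  if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols) {
    stop(sprintf("%s must be a %d x %d matrix matching the grid (got %s)",
                 what, grid$n_rows, grid$n_cols,
                 if (is.matrix(m)) paste(dim(m), collapse = " x ") else "non-matrix"),
         call. = FALSE)
  }
  invisible(TRUE)
}
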