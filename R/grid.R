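#' Regular longitude/latitude grid
#'
#' A minimal raster container: a numeric matrix of cell values on a regular
#' lon/lat grid. Rows index latitude, columns index longitude; both axes
#' are cell-centre coordinates and must be strictly increasing and evenly
#' spaced.
#'
#' @param lon,lat strictly increasing, evenly spaced cell-centre
#'   coordinates (decimal degrees).
#' @param values numeric matrix, `length(lat)` rows by `length(lon)`
#'   columns; `NA` marks missing/masked cells.
#' @return object of class `reef_grid`.
#' @export
reef_grid <- function(lon, lat, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    stop("values must be length(lat) x length(lon)")
  }
  check_axis <- function(x, nm) {
    if (length(x) > 1) {
      dx <- diff(x)
      if (any(dx <= 0) || max(dx) - min(dx) > 1e-8) {
        stop(nm, " axis must be strictly increasing and evenly spaced")
      }
    }
  }
  check_axis(lon, "lon"); check_axis(lat, "lat")
  structure(list(lon = lon, lat = lat, values = values),
            class = "reef_grid")
}

#' @export
print.reef_grid <- function(x, ...) {
  cat("reef_grid:", length(x$lat), "x", length(x$lon), "cells,",
      sum(is.na(x$values)), "missing\n")
  invisible(x)
}

#' Read/write a reef_grid as plain text
#'
#' The on-disk form is a CSV whose first row holds the longitude axis,
#' first column the latitude axis, and body the cell values (empty = NA).
#'
#' @param path file path.
#' @rdname grid_io
#' @export
read_grid_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  reef_grid(lon = as.numeric(m[1, -1]), lat = as.numeric(m[-1, 1]),
            values = matrix(as.numeric(m[-1, -1]), nrow = nrow(m) - 1))
}

#' @param grid a [reef_grid()].
#' @rdname grid_io
#' @export
write_grid_csv <- function(grid, path) {
  m <- rbind(c(NA, grid$lon), cbind(grid$lat, grid$values))
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' Mask ocean-colour pixels over shallow water
#'
#' A quality-control mask for satellite ocean-colour products (PAR, kdPAR)
#' near shore: a pixel is masked (set NA) when more than `frac` of its
#' footprint lies at depths of `depth_limit` or shallower. The bathymetry
#' grid must cover the same extent at the same or an integer-multiple finer
#' resolution; co-registration/resampling is the caller's job.
#'
#' @param ocean [reef_grid()] of ocean-colour values.
#' @param bathymetry [reef_grid()] of positive depths in metres.
#' @param frac maximum tolerated shallow-area fraction (default 0.05).
#' @param depth_limit shallow cut-off in metres (default 30).
#' @return `ocean` with offending pixels set to NA.
#' @export
mask_shallow_pixels <- function(ocean, bathymetry, frac = 0.05,
                                depth_limit = 30) {
  kx <- length(bathymetry$lon) / length(ocean$lon)
  ky <- length(bathymetry$lat) / length(ocean$lat)
  if (kx != round(kx) || ky != round(ky)) {
    stop("bathymetry grid is not an integer refinement of the ocean grid")
  }
  kx <- as.integer(kx); ky <- as.integer(ky)
  shallow <- bathymetry$values <= depth_limit
  out <- ocean$values
  for (i in seq_along(ocean$lat)) {
    for (j in seq_along(ocean$lon)) {
      block <- shallow[((i - 1) * ky + 1):(i * ky),
                       ((j - 1) * kx + 1):(j * kx), drop = FALSE]
      if (mean(block, na.rm = TRUE) > frac) out[i, j] <- NA
    }
  }
  reef_grid(ocean$lon, ocean$lat, out)
}

#' Extract a raster value at a point with an expanding search radius
#'
#' If the pixel containing the point is valid its value is returned. If it
#' is missing, the search expands outward until the first non-missing
#' pixel is reached (by great-circle distance to pixel centres); the result
#' is then the mean of every non-missing pixel within that radius. If no
#' valid pixel lies within `max_radius_km`, `NA` is returned.
#'
#' @param grid a [reef_grid()].
#' @param lon,lat query point (must lie within the grid extent, padded by
#'   half a cell).
#' @param max_radius_km search limit in km (8 by default; use 0.75 for wave
#'   products).
#' @return scalar value or `NA` when the search is exhausted.
#' @export
extract_nearest <- function(grid, lon, lat, max_radius_km = 8) {
  half_x <- if (length(grid$lon) > 1) diff(grid$lon[1:2]) / 2 else 0.5
  half_y <- if (length(grid$lat) > 1) diff(grid$lat[1:2]) / 2 else 0.5
  if (lon < min(grid$lon) - half_x || lon > max(grid$lon) + half_x ||
      lat < min(grid$lat) - half_y || lat > max(grid$lat) + half_y) {
    stop("point outside raster extent")
  }
  j <- which.min(abs(grid$lon - lon))
  i <- which.min(abs(grid$lat - lat))
  if (!is.na(grid$values[i, j])) return(grid$values[i, j])
  # expand.grid varies lon fastest; t(values) flattens in the same order
  centres <- expand.grid(lon = grid$lon, lat = grid$lat)
  vals <- as.vector(t(grid$values))
  dist_km <- geosphere::distHaversine(cbind(lon, lat),
                                      as.matrix(centres),
                                      r = 6371008.8) / 1000
  ok <- !is.na(vals) & dist_km <= max_radius_km
  if (!any(ok)) return(NA_real_)
  r_first <- min(dist_km[ok])
  mean(vals[ok & dist_km <= r_first + 1e-9])
}
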