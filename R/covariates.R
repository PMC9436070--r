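TRANSFORMS <- list(
  identity = list(f = function(x) x, inv = function(y) y),
  log1p    = list(f = function(x) log1p(x), inv = function(y) expm1(y)),
  sqrt     = list(f = function(x) sqrt(x), inv = function(y) y^2)
)

moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Fit a transform-and-standardize registry for driver variables
#'
#' Each variable gets a monotone transform (`identity`, `log1p` or `sqrt`)
#' followed by centring and scaling to mean 0, SD 1 over the analysis
#' cells. By default the transform is data-driven: non-negative variables
#' with moment skewness above `skew_limit` get `log1p`, everything else
#' `identity`; explicit per-variable `overrides` win. The fitted centre and
#' scale are recorded so model predictions can be mapped back to natural
#' units.
#'
#' @param data data frame of driver columns on their natural scales.
#' @param overrides named character vector, variable -> transform name.
#' @param skew_limit skewness above which `log1p` is chosen (default 1).
#' @return object of class `transform_registry`: data frame with columns
#'   `variable`, `transform`, `center`, `scale`.
#' @export
fit_registry <- function(data, overrides = character(), skew_limit = 1) {
  vars <- names(data)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    tr <- if (v %in% names(overrides)) {
      overrides[[v]]
    } else if (all(x >= 0, na.rm = TRUE) && moment_skewness(x) > skew_limit) {
      "log1p"
    } else "identity"
    if (!tr %in% names(TRANSFORMS)) stop("unknown transform: ", tr)
    tx <- TRANSFORMS[[tr]]$f(x)
    sc <- stats::sd(tx, na.rm = TRUE)
    if (!is.finite(sc) || sc == 0) {
      stop("variable ", v, " is constant; cannot standardize")
    }
    data.frame(variable = v, transform = tr,
               center = mean(tx, na.rm = TRUE), scale = sc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transform_registry", "data.frame")
  out
}

#' Apply (or invert) a fitted transform registry
#'
#' @param data data frame of natural-scale driver columns.
#' @param registry a [fit_registry()] result.
#' @return data frame of standardized columns (apply) or natural-scale
#'   columns (invert).
#' @export
apply_registry <- function(data, registry) {
  out <- data
  for (k in seq_len(nrow(registry))) {
    v <- registry$variable[k]
    if (!v %in% names(data)) stop("registry variable missing from data: ", v)
    tx <- TRANSFORMS[[registry$transform[k]]]$f(data[[v]])
    out[[v]] <- (tx - registry$center[k]) / registry$scale[k]
  }
  out
}

#' @param z data frame of standardized columns.
#' @rdname apply_registry
#' @export
invert_registry <- function(z, registry) {
  out <- z
  for (k in seq_len(nrow(registry))) {
    v <- registry$variable[k]
    y <- z[[v]] * registry$scale[k] + registry$center[k]
    out[[v]] <- TRANSFORMS[[registry$transform[k]]]$inv(y)
  }
  out
}

#' Assemble the matched, transformed, standardized driver matrix
#'
#' Joins per-cluster site indices and (optionally) raster extractions onto
#' the cluster cells, applies the analysis filters — deep cells excluded,
#' any cell with a missing driver dropped — then fits the transform
#' registry on the surviving cells and standardizes every driver column.
#'
#' @param cells cell table from [aggregate_cells()] (the cell's `mean_bs`
#'   becomes the `bs_score` driver when present).
#' @param site_indices data frame keyed by `cluster_id` with one column per
#'   site-level driver (e.g. `acute_dhw`, `urban_runoff`, ...).
#' @param rasters optional named list of [reef_grid()]s to extract at cell
#'   centroids; names become driver columns. `max_radius_km` may be a
#'   single value or named per raster (wave products conventionally 0.75).
#' @param overrides,skew_limit passed to [fit_registry()].
#' @param max_radius_km search limit(s) for [extract_nearest()].
#' @return list with `data` (cells + standardized driver columns),
#'   `registry` ([fit_registry()]), and `dropped` (data frame of cell keys
#'   with a `reason` such as `"depth_bin:deep"` or `"par:missing"`).
#' @export
build_driver_matrix <- function(cells, site_indices = NULL, rasters = list(),
                                overrides = character(), skew_limit = 1,
                                max_radius_km = 8) {
  d <- cells
  if (!is.null(site_indices)) {
    stopifnot("cluster_id" %in% names(site_indices))
    d <- merge(d, site_indices, by = "cluster_id", all.x = TRUE, sort = FALSE)
  }
  for (nm in names(rasters)) {
    r_km <- if (length(max_radius_km) > 1) max_radius_km[[nm]] else max_radius_km
    d[[nm]] <- vapply(seq_len(nrow(d)), function(i) {
      extract_nearest(rasters[[nm]], d$lon[i], d$lat[i], max_radius_km = r_km)
    }, numeric(1))
  }
  if ("mean_bs" %in% names(d) && !"bs_score" %in% names(d)) {
    d$bs_score <- d$mean_bs
  }
  meta <- c("cluster_id", "depth_bin", "n", "mean_pct_bleached",
            "se_pct_bleached", "mean_bs", "mean_depth_m", "lon", "lat",
            "island", "zone", "year", "weight")
  drivers <- setdiff(names(d), meta)
  if (length(drivers) == 0) stop("no driver columns found")

  dropped <- data.frame(cluster_id = integer(), depth_bin = character(),
                        reason = character())
  deep <- d$depth_bin == "deep"
  if (any(deep)) {
    dropped <- rbind(dropped, data.frame(
      cluster_id = d$cluster_id[deep], depth_bin = d$depth_bin[deep],
      reason = "depth_bin:deep"))
    d <- d[!deep, , drop = FALSE]
  }
  for (v in drivers) {
    bad <- is.na(d[[v]])
    if (any(bad)) {
      dropped <- rbind(dropped, data.frame(
        cluster_id = d$cluster_id[bad], depth_bin = d$depth_bin[bad],
        reason = paste0(v, ":missing")))
      d <- d[!bad, , drop = FALSE]
    }
  }
  if (nrow(d) < 30) {
    warning("only ", nrow(d), " cells survive filtering; model may be unstable")
  }
  registry <- fit_registry(d[drivers], overrides = overrides,
                           skew_limit = skew_limit)
  d[drivers] <- apply_registry(d[drivers], registry)
  list(data = d, registry = registry, drivers = drivers, dropped = dropped)
}
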