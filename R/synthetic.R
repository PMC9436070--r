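#' Default susceptibility score table for the synthetic community
#'
#' Five common Hawaiian reef-building taxa spanning the full 1 (least) to
#' 5 (most susceptible) score range, plus genus-level fallback entries.
#'
#' @return data frame with columns `taxon`, `rank`, `score`.
#' @export
default_score_table <- function() {
  data.frame(
    taxon = c("Porites lobata", "Porites lutea", "Montipora capitata",
              "Montipora patula", "Pocillopora meandrina",
              "Porites", "Montipora", "Pocillopora"),
    rank = c(rep("species", 5), rep("genus", 3)),
    score = c(1L, 2L, 3L, 4L, 5L, 1L, 3L, 5L)
  )
}

# linear natural-scale maps for each simulated driver: natural = center +
# scale * z. Linearity keeps the pipeline's re-standardization an exact
# inverse, so recovered coefficients are directly comparable to true_beta.
DRIVER_SCALES <- list(
  acute_dhw           = c(center = 5.5,  scale = 1.7),
  historical_dhw      = c(center = 7.0,  scale = 2.0),
  historical_bleached = c(center = 30,   scale = 9),
  urban_runoff        = c(center = 50,   scale = 15),
  sewage_effluent     = c(center = 40,   scale = 12),
  tourism             = c(center = 45,   scale = 15),
  par                 = c(center = 45,   scale = 5),
  kd_par              = c(center = 0.10, scale = 0.02),
  sst_variability     = c(center = 0.9,  scale = 0.2),
  wave_action         = c(center = 50,   scale = 14)
)

#' Simulation configuration with study-scale defaults
#'
#' Encodes the structure the analysis assumes: islands split into coastal
#' zones, clusters of surveys separated by more than 2 km (surveys within
#' a cluster under 1 km apart), cluster-by-depth-bin cells whose expected
#' square-root percent bleached follows a known linear model with two-way
#' interactions, heteroskedastic within-cluster replication, and a
#' correlated driver field.
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_islands,zones_per_island,clusters_per_zone layout counts.
#' @param surveys_per_cluster integer range (min, max) of surveys per cell.
#' @param depth_bins subset of `c("shallow", "mid", "deep")` each cluster
#'   hosts.
#' @param true_beta named coefficient vector on the square-root-percent
#'   scale for standardized drivers; names are `(Intercept)`, driver
#'   names, and `a:b` interaction labels.
#' @param noise_sd cell-level noise SD on the square-root-percent scale.
#' @param within_cluster_sd survey replication SD in percent units.
#' @param driver_cor pairwise correlation among the anthropogenic indices
#'   (urban run-off, sewage effluent, tourism).
#' @param sst_params list: `mean_sst`, `amplitude` (seasonal, deg C),
#'   `peak_doy`, `heatwave_onset` (Date), `peak_anomaly` (deg C),
#'   `duration_days`, `noise_sd`, `years`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_islands = 2,
                       zones_per_island = 3,
                       clusters_per_zone = 6,
                       surveys_per_cluster = c(2, 6),
                       depth_bins = c("shallow", "mid", "deep"),
                       true_beta = c(
                         "(Intercept)" = 4.5,
                         acute_dhw = 1.2,
                         bs_score = 0.8,
                         historical_bleached = 0.3,
                         urban_runoff = 0.45,
                         sewage_effluent = 0.3,
                         par = 0.35,
                         kd_par = -0.3,
                         tourism = 0.25,
                         "acute_dhw:bs_score" = 0.4,
                         "acute_dhw:urban_runoff" = 0.3,
                         "bs_score:par" = 0.2
                       ),
                       noise_sd = 0.5,
                       within_cluster_sd = 5,
                       driver_cor = 0.4,
                       sst_params = list(
                         mean_sst = 26, amplitude = 2, peak_doy = 263,
                         heatwave_onset = as.Date("2019-08-20"),
                         peak_anomaly = 2.0, duration_days = 45,
                         noise_sd = 0.15, years = 2010:2019
                       )) {
  stopifnot(noise_sd > 0, within_cluster_sd >= 0,
            all(depth_bins %in% c("shallow", "mid", "deep")),
            surveys_per_cluster[1] >= 1,
            "(Intercept)" %in% names(true_beta))
  cfg <- list(seed = as.integer(seed), n_islands = n_islands,
              zones_per_island = zones_per_island,
              clusters_per_zone = clusters_per_zone,
              surveys_per_cluster = surveys_per_cluster,
              depth_bins = depth_bins, true_beta = true_beta,
              noise_sd = noise_sd, within_cluster_sd = within_cluster_sd,
              driver_cor = driver_cor, sst_params = sst_params,
              score_table = default_score_table())
  class(cfg) <- "sim_config"
  cfg
}

# main-effect driver names implied by true_beta (bs_score is built from
# the taxon composition, everything else is drawn)
.config_drivers <- function(config) {
  terms <- setdiff(names(config$true_beta), "(Intercept)")
  unique(unlist(strsplit(terms, ":", fixed = TRUE)))
}

#' Generate a daily SST series for one island
#'
#' Sinusoidal seasonal cycle plus a configured rectangular heatwave
#' anomaly and Gaussian noise; at least five full years so a monthly
#' climatology is estimable.
#'
#' @param config a [sim_config()].
#' @param island_id island index (1-based) or name; shifts the island's
#'   mean temperature slightly and seeds its noise stream.
#' @return an [sst_series()].
#' @export
generate_sst <- function(config, island_id = 1) {
  p <- config$sst_params
  if (length(p$years) < 5) stop("need at least 5 simulated years")
  iid <- if (is.numeric(island_id)) island_id else
    which(island_names(config) == island_id)
  set.seed(config$seed * 1000L + iid)
  dates <- seq(as.Date(paste0(min(p$years), "-01-01")),
               as.Date(paste0(max(p$years), "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  sst <- p$mean_sst + 0.1 * (iid - 1) +
    p$amplitude * cos(2 * pi * (doy - p$peak_doy) / 365.25)
  ev <- dates >= p$heatwave_onset &
    dates < p$heatwave_onset + p$duration_days
  sst[ev] <- sst[ev] + p$peak_anomaly
  if (p$noise_sd > 0) sst <- sst + stats::rnorm(length(sst), 0, p$noise_sd)
  sst_series(island_names(config)[iid], dates, sst)
}

#' @rdname generate_sst
#' @export
island_names <- function(config) {
  paste0("island_", seq_len(config$n_islands))
}

# deterministic hex-ish cluster layout: rows of up to four clusters 3 km
# apart, alternate rows offset by half the spacing; zones 15 km apart in
# longitude and islands separated well beyond the zone span, so surveys
# jittered within +/-0.2 km of a centre are < 1 km apart inside a cluster
# and > 2 km from any other cluster
.cluster_layout <- function(config) {
  km_lat <- 1 / 111.195  # degrees per km (mean-radius haversine)
  lat0 <- 20.5
  km_lon <- km_lat / cos(lat0 * pi / 180)
  island_step <- (config$zones_per_island * 15 + 20) * km_lon
  rows <- list()
  cl <- 0L
  for (isl in seq_len(config$n_islands)) {
    for (zn in seq_len(config$zones_per_island)) {
      for (k in seq_len(config$clusters_per_zone)) {
        cl <- cl + 1L
        row <- (k - 1) %/% 4
        col <- (k - 1) %% 4
        rows[[cl]] <- data.frame(
          cluster_id = cl,
          island = island_names(config)[isl],
          zone = paste0("island_", isl, "_zone_", zn),
          lon = (isl - 1) * island_step + (zn - 1) * 15 * km_lon +
            (col + 0.5 * (row %% 2)) * 3 * km_lon,
          lat = lat0 + row * 3 * km_lat
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate survey tables with a known ground-truth model
#'
#' Draws per-cluster standardized drivers from a correlated Gaussian
#' field, maps them to natural scales linearly, computes each cell's
#' expected square-root percent bleached from `true_beta`, adds cell noise,
#' replicates surveys with within-cluster noise (clamped to 0-100 percent
#' after noise), and builds per-taxon covers so each survey's BS score
#' equals the cell's susceptibility driver exactly.
#'
#' @param config a [sim_config()].
#' @return list with `surveys` (one row per survey x taxon), `site_indices`
#'   (cluster-level natural-scale drivers), and `truth` (the ground truth:
#'   `true_beta`, the standardized cell design, natural drivers, expected
#'   square-root bleaching per cell).
#' @export
generate_surveys <- function(config) {
  set.seed(config$seed)
  layout <- .cluster_layout(config)
  n_cl <- nrow(layout)
  bins <- config$depth_bins
  cells <- merge(layout, data.frame(depth_bin = bins), by = NULL)
  cells <- cells[order(cells$cluster_id, cells$depth_bin), ]
  rownames(cells) <- NULL
  n_cells <- nrow(cells)

  drivers <- .config_drivers(config)
  drawn <- setdiff(drivers, "bs_score")
  # correlated anthropogenic block, everything else independent
  R <- diag(length(drawn))
  dimnames(R) <- list(drawn, drawn)
  anth <- intersect(c("urban_runoff", "sewage_effluent", "tourism"), drawn)
  R[anth, anth] <- config$driver_cor
  diag(R) <- 1
  z_cl <- matrix(stats::rnorm(n_cl * length(drawn)), n_cl) %*% chol(R)
  colnames(z_cl) <- drawn
  z <- z_cl[match(cells$cluster_id, layout$cluster_id), , drop = FALSE]
  if ("bs_score" %in% drivers) {
    z <- cbind(z, bs_score = stats::rnorm(n_cells))
  }
  # exact sample standardization so the pipeline's z-scores reproduce the
  # design (see the methods vignette)
  zs <- scale(z)
  z <- matrix(as.numeric(zs), n_cells, dimnames = list(NULL, colnames(z)))

  natural <- as.data.frame(z)
  for (v in setdiff(colnames(z), "bs_score")) {
    sc <- DRIVER_SCALES[[v]]
    natural[[v]] <- pmax(sc["center"] + sc["scale"] * z[, v], 0)
  }
  if ("bs_score" %in% colnames(z)) {
    natural$bs_score <- pmin(pmax(3 + 0.45 * z[, "bs_score"], 1), 5)
  }

  # expected sqrt-% bleached = design row . true_beta, exactly
  beta <- config$true_beta
  X <- matrix(1, n_cells, 1, dimnames = list(NULL, "(Intercept)"))
  for (t in setdiff(names(beta), "(Intercept)")) {
    p <- strsplit(t, ":", fixed = TRUE)[[1]]
    X <- cbind(X, apply(z[, p, drop = FALSE], 1, prod))
    colnames(X)[ncol(X)] <- t
  }
  mu <- as.numeric(X %*% beta[colnames(X)])
  cell_sqrt <- mu + stats::rnorm(n_cells, 0, config$noise_sd)
  cell_pct <- pmin(pmax(cell_sqrt, 0), 10)^2

  score_tab <- config$score_table
  sp_by_score <- stats::setNames(
    score_tab$taxon[score_tab$rank == "species"],
    score_tab$score[score_tab$rank == "species"])
  sv <- list(); sid <- 0L
  for (i in seq_len(n_cells)) {
    n_s <- sample(seq(config$surveys_per_cluster[1],
                      config$surveys_per_cluster[2]), 1)
    b <- natural$bs_score[i]
    lo <- min(floor(b), 4); frac <- b - lo
    rng <- switch(cells$depth_bin[i], shallow = c(1, 5),
                  mid = c(7, 17), deep = c(19, 29))
    for (j in seq_len(n_s)) {
      sid <- sid + 1L
      pct <- pmin(pmax(cell_pct[i] +
                         stats::rnorm(1, 0, config$within_cluster_sd), 0), 100)
      total <- stats::runif(1, 20, 60)
      cov_lo <- (1 - frac) * total
      cov_hi <- frac * total
      taxa <- data.frame(
        taxon = c(sp_by_score[[as.character(lo)]],
                  sp_by_score[[as.character(lo + 1)]]),
        score = c(lo, lo + 1),
        cover = c(cov_lo, cov_hi)
      )
      taxa <- taxa[taxa$cover > 0, , drop = FALSE]
      sv[[sid]] <- data.frame(
        survey_id = sid,
        island = cells$island[i], zone = cells$zone[i],
        cluster_true = cells$cluster_id[i],
        lon = cells$lon[i] + stats::runif(1, -0.0018, 0.0018),
        lat = cells$lat[i] + stats::runif(1, -0.0018, 0.0018),
        date = as.Date("2019-09-01") + sample(0:60, 1),
        year = 2019L,
        depth_m = stats::runif(1, rng[1], rng[2]),
        total_cover = total,
        pct_bleached = pct,
        taxon = taxa$taxon,
        cover = taxa$cover,
        taxon_pct_bleached = pmin(pct * taxa$score / b, 100)
      )
    }
  }
  surveys <- do.call(rbind, sv)
  rownames(surveys) <- NULL

  site_indices <- data.frame(cluster_id = layout$cluster_id)
  for (v in setdiff(colnames(z), "bs_score")) {
    site_indices[[v]] <- natural[[v]][match(layout$cluster_id,
                                            cells$cluster_id)]
  }
  truth <- list(true_beta = beta,
                cells = cbind(cells[c("cluster_id", "island", "zone",
                                      "depth_bin")],
                              as.data.frame(z),
                              natural_bs = natural$bs_score,
                              expected_sqrt = mu,
                              cell_pct = cell_pct),
                design = X)
  list(surveys = surveys, site_indices = site_indices, truth = truth)
}

#' Generate driver rasters and a correlated site-index table
#'
#' Produces smooth PAR, kdPAR, bathymetry and wave-action grids over the
#' survey region with configurable missing-data blocks (to exercise the
#' expanding-radius extraction), plus per-site anthropogenic indices with
#' a configurable pairwise correlation.
#'
#' @param config a [sim_config()].
#' @param n_sites number of rows in the site-index table.
#' @param na_frac fraction of raster cells set missing (default 0.15).
#' @param nx,ny grid resolution.
#' @return list with `grids` (named list of [reef_grid()]) and
#'   `site_indices` (data frame `site`, `urban_runoff`, `sewage_effluent`,
#'   `tourism`).
#' @export
generate_driver_fields <- function(config, n_sites = 100, na_frac = 0.15,
                                   nx = 40, ny = 30) {
  set.seed(config$seed + 7L)
  layout <- .cluster_layout(config)
  lon <- seq(min(layout$lon) - 0.1, max(layout$lon) + 0.1, length.out = nx)
  lat <- seq(min(layout$lat) - 0.1, max(layout$lat) + 0.1, length.out = ny)
  field <- function(base, amp) {
    v <- outer(lat, lon, function(la, lo) {
      base + amp * (sin(8 * lo) * cos(11 * la) + 0.3 * (la - mean(lat)))
    })
    v
  }
  add_na <- function(v) {
    if (na_frac > 0) {
      miss <- stats::runif(length(v)) < na_frac
      v[miss] <- NA
    }
    v
  }
  grids <- list(
    par = reef_grid(lon, lat, add_na(field(45, 4))),
    kd_par = reef_grid(lon, lat, add_na(pmax(field(0.1, 0.03), 0.01))),
    bathymetry = reef_grid(lon, lat, pmax(field(60, 35), 1)),
    wave_action = reef_grid(lon, lat, add_na(pmax(field(50, 20), 0)))
  )
  r <- config$driver_cor
  R <- matrix(r, 3, 3); diag(R) <- 1
  zz <- matrix(stats::rnorm(n_sites * 3), n_sites) %*% chol(R)
  site_indices <- data.frame(
    site = seq_len(n_sites),
    urban_runoff = 50 + 15 * zz[, 1],
    sewage_effluent = 40 + 12 * zz[, 2],
    tourism = 45 + 15 * zz[, 3]
  )
  list(grids = grids, site_indices = site_indices)
}

#' Generate a complete synthetic input bundle
#'
#' Surveys (with ground truth), per-island SST series, driver grids and
#' site indices, all determined by the configuration seed.
#'
#' @param config a [sim_config()] (or a seed, for defaults).
#' @return list with `config`, `surveys`, `site_indices`, `truth`, `sst`
#'   (named list of series), `fields` (see [generate_driver_fields()]),
#'   and `score_table`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  if (is.numeric(config)) config <- sim_config(seed = config)
  gs <- generate_surveys(config)
  sst <- lapply(seq_len(config$n_islands), function(i) {
    generate_sst(config, i)
  })
  names(sst) <- island_names(config)
  list(config = config, surveys = gs$surveys,
       site_indices = gs$site_indices, truth = gs$truth, sst = sst,
       fields = generate_driver_fields(config),
       score_table = config$score_table)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes `surveys.csv`, `site_indices.csv`, `sst.csv`, `score_table.csv`,
#' grid CSVs and `truth.json` under `dir`.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$surveys, file.path(dir, "surveys.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$site_indices, file.path(dir, "site_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$score_table, file.path(dir, "score_table.csv"),
                   row.names = FALSE)
  sst <- do.call(rbind, lapply(bundle$sst, function(s) {
    data.frame(island_id = attr(s, "island_id"), date = s$date, sst = s$sst)
  }))
  utils::write.csv(sst, file.path(dir, "sst.csv"), row.names = FALSE)
  for (nm in names(bundle$fields$grids)) {
    write_grid_csv(bundle$fields$grids[[nm]],
                   file.path(dir, paste0("grid_", nm, ".csv")))
  }
  jsonlite::write_json(
    list(true_beta = as.list(bundle$truth$true_beta),
         cells = bundle$truth$cells),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
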