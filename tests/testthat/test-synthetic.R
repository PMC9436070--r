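small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_islands = 1, zones_per_island = 2,
             clusters_per_zone = 4, depth_bins = c("shallow", "mid"), ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 9)
  expect_identical(generate_sst(cfg, 1), generate_sst(cfg, 1))
  expect_identical(generate_surveys(cfg), generate_surveys(cfg))
  expect_identical(generate_driver_fields(cfg), generate_driver_fields(cfg))
  # and sensitive to the seed
  expect_false(identical(generate_surveys(cfg)$surveys$pct_bleached,
                         generate_surveys(small_cfg(seed = 10))$surveys$pct_bleached))
})

test_that("SST generator: no anomaly means MMM equals the climatology maximum", {
  cfg <- small_cfg(sst_params = list(
    mean_sst = 26, amplitude = 1.5, peak_doy = 263,
    heatwave_onset = as.Date("2019-08-20"), peak_anomaly = 0,
    duration_days = 30, noise_sd = 0, years = 2014:2019))
  s <- generate_sst(cfg, 1)
  mmm <- compute_mmm(s, 2014:2018)
  yr <- as.integer(format(s$date, "%Y"))
  mo <- as.integer(format(s$date, "%m"))
  expect_equal(mmm, max(tapply(s$sst[yr <= 2018], mo[yr <= 2018], mean)))
  expect_equal(max(compute_dhw(s, mmm)$dhw), 0)  # seasonal wiggle < 1 degC
  expect_error(generate_sst(small_cfg(sst_params = modifyList(
    cfg$sst_params, list(years = 2019))), 1), "5 simulated years")
})

test_that("surveys respect bounds, cover accounting, and the BS construction", {
  cfg <- small_cfg(seed = 4)
  g <- generate_surveys(cfg)
  sv <- g$surveys
  expect_true(all(sv$pct_bleached >= 0 & sv$pct_bleached <= 100))
  expect_true(all(sv$cover >= 0))
  agg <- tapply(sv$cover, sv$survey_id, sum)
  tot <- tapply(sv$total_cover, sv$survey_id, function(x) x[1])
  expect_true(all(agg <= tot + 1e-9))

  # each survey's BS score equals the cell's susceptibility driver exactly
  st <- cfg$score_table
  per <- split(sv, sv$survey_id)
  truth_bs <- g$truth$cells$natural_bs
  for (s in per[seq(1, length(per), by = 7)]) {
    bs <- compute_bs(s[, c("taxon", "cover")], st, s$total_cover[1])
    cell <- which(g$truth$cells$cluster_id == s$cluster_true[1] &
                    g$truth$cells$depth_bin ==
                      as.character(assign_depth_bin(s$depth_m[1])))
    expect_equal(bs, truth_bs[cell], tolerance = 1e-9)
  }

  # expected sqrt-bleaching is exactly design %*% beta
  expect_equal(as.numeric(g$truth$design %*%
                            cfg$true_beta[colnames(g$truth$design)]),
               g$truth$cells$expected_sqrt, tolerance = 1e-12)
})

test_that("survey geometry honours the 1-km within / 2-km between contract", {
  g <- generate_surveys(small_cfg(seed = 6))
  sv <- g$surveys[!duplicated(g$surveys$survey_id), ]
  d <- haversine_km(sv$lon, sv$lat)
  same <- outer(sv$cluster_true, sv$cluster_true, "==")
  diag(d) <- NA
  expect_lt(max(d[same], na.rm = TRUE), 1)
  expect_gt(min(d[!same]), 2)
})

test_that("driver fields: NA handling and configured correlation", {
  cfg <- small_cfg(seed = 2)
  f0 <- generate_driver_fields(cfg, na_frac = 0)
  expect_false(anyNA(f0$grids$par$values))
  g <- f0$grids$par
  expect_equal(extract_nearest(g, g$lon[3], g$lat[3]), g$values[3, 3])

  # an all-missing raster reports missing everywhere it is searched
  g_na <- reef_grid(g$lon, g$lat, matrix(NA_real_, length(g$lat),
                                         length(g$lon)))
  expect_true(is.na(extract_nearest(g_na, g$lon[3], g$lat[3],
                                    max_radius_km = 10)))

  # configured correlation 0.8 recovered within +/- 0.1 at n = 500
  f <- generate_driver_fields(small_cfg(seed = 3, driver_cor = 0.8),
                              n_sites = 500)
  r <- cor(f$site_indices$urban_runoff, f$site_indices$tourism)
  expect_lt(abs(r - 0.8), 0.1)
})

test_that("degenerate replication (zero within-cluster noise) is rejected at weighting", {
  g <- generate_surveys(small_cfg(seed = 5, within_cluster_sd = 0))
  sv <- g$surveys[!duplicated(g$surveys$survey_id), ]
  cl <- cluster_surveys(sv)
  cells <- aggregate_cells(sv, cl)
  # all SEs are zero or missing, so no information-based weight exists
  expect_error(compute_weights(cells), "SE")
})

test_that("WLS on the true term set recovers coefficients (bias within 0.05)", {
  # 20 seeds at ~200 cells; the analysis-grade recovery contract
  terms <- setdiff(names(sim_config()$true_beta), "(Intercept)")
  est <- matrix(NA_real_, 20, length(terms) + 1)
  for (s in 1:20) {
    cfg <- sim_config(seed = 100 + s, n_islands = 2, zones_per_island = 3,
                      clusters_per_zone = 17, depth_bins = c("shallow", "mid"))
    b <- simulate_bundle(cfg)
    res <- run_pipeline(b)
    d <- res$drivers$data
    d$weight <- compute_weights(d)
    f <- as.formula(paste("sqrt(mean_pct_bleached) ~",
                          paste(terms, collapse = "+")))
    fit <- wls_fit(f, d, d$weight)
    est[s, ] <- fit$coefficients$estimate
  }
  truth <- sim_config()$true_beta
  bias <- colMeans(est) - truth[c("(Intercept)", terms)]
  expect_true(all(abs(bias) <= 0.05))
})
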