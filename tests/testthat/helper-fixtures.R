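# small in-code fixtures shared across tests

# constant-temperature daily series spanning whole years
flat_sst <- function(value = 26, years = 2015:2019, island = "isl") {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  sst_series(island, dates, rep(value, length(dates)))
}

# flat series with a rectangular anomaly of `anomaly` degC for `days` days
pulse_sst <- function(base = 26, anomaly = 2, days = 28,
                      onset = as.Date("2019-09-01"), years = 2015:2019) {
  s <- flat_sst(base, years)
  ev <- s$date >= onset & s$date < onset + days
  s$sst[ev] <- s$sst[ev] + anomaly
  s
}

toy_score_table <- function() {
  data.frame(
    taxon = c("A", "B", "C", "D", "E", "Porites"),
    rank = c(rep("species", 5), "genus"),
    score = c(1L, 2L, 3L, 4L, 5L, 1L)
  )
}

# survey points along one parallel, spaced `gaps_km` apart eastward
points_along_lat <- function(gaps_km, lat = 20) {
  km_per_deg <- 111.195 * cos(lat * pi / 180)
  data.frame(lon = cumsum(c(0, gaps_km)) / km_per_deg, lat = lat)
}

# cells table with given SEs (NA = single-survey cell)
cells_with_se <- function(se) {
  data.frame(cluster_id = seq_along(se), depth_bin = "shallow",
             n = ifelse(is.na(se), 1L, 5L), mean_pct_bleached = 20,
             se_pct_bleached = se)
}

# noiseless WLS fit with exact coefficients on standardized-style columns
exact_model <- function(beta, n = 60) {
  vars <- setdiff(names(beta), "(Intercept)")
  mains <- unique(unlist(strsplit(vars, ":", fixed = TRUE)))
  set.seed(42)
  d <- data.frame(row.names = seq_len(n))
  for (v in mains) d[[v]] <- rnorm(n)
  X <- matrix(1, n, 1)
  for (v in vars) {
    X <- cbind(X, apply(d[strsplit(v, ":", fixed = TRUE)[[1]]], 1, prod))
  }
  d$.y <- as.numeric(X %*% c(beta["(Intercept)"], beta[vars]))
  rhs <- if (length(vars) == 0) "1" else paste(vars, collapse = " + ")
  suppressWarnings(wls_fit(as.formula(paste(".y ~", rhs)), d, rep(1, n)))
}
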