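#' Assign a survey depth to its analysis bin
#'
#' Bins are half-open with zero in shallow: shallow (0-6 m], mid (6-18 m],
#' deep (18-30 m]. Depths outside 0-30 m are rejected.
#'
#' @param depth_m numeric depth(s) in metres.
#' @return factor with levels `shallow`, `mid`, `deep`.
#' @export
assign_depth_bin <- function(depth_m) {
  if (any(!is.finite(depth_m)) || any(depth_m < 0) || any(depth_m > 30)) {
    stop("depth outside the surveyed 0-30 m range")
  }
  cut(depth_m, breaks = c(-0.001, 6, 18, 30),
      labels = c("shallow", "mid", "deep"), right = TRUE)
}

#' Great-circle distance matrix between surveys (km)
#'
#' Haversine distance with mean Earth radius 6371.0088 km.
#'
#' @param lon,lat coordinate vectors in decimal degrees.
#' @return symmetric distance matrix in kilometres.
#' @export
haversine_km <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(abs(lat) > 90) || any(abs(lon) > 360)) {
    stop("invalid survey coordinates")
  }
  geosphere::distm(cbind(lon, lat), fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371008.8)
  }) / 1000
}

#' Cluster surveys within a kilometre of one another
#'
#' Agglomerative clustering with complete linkage on great-circle distance,
#' cut so that every within-cluster pairwise distance is at most
#' `threshold_km` (a cluster-diameter constraint: "within 1 km of one
#' another"). Ties between equally close merges are broken by the lowest
#' survey index, so assignment is deterministic.
#'
#' @param surveys data frame with columns `lon`, `lat`.
#' @param threshold_km cluster diameter limit in km (default 1).
#' @return integer cluster ids (1-based, ordered by first survey index).
#' @export
cluster_surveys <- function(surveys, threshold_km = 1.0) {
  n <- nrow(surveys)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  d <- haversine_km(surveys$lon, surveys$lat)
  # connected components under d <= threshold partition the problem exactly:
  # complete linkage never merges across a gap wider than the threshold
  comp <- stats::cutree(stats::hclust(stats::as.dist(d), "single"),
                        h = threshold_km)
  assign <- integer(n)
  next_id <- 0L
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    labs <- complete_linkage_cut(d[members, members, drop = FALSE],
                                 threshold_km)
    assign[members] <- labs + next_id
    next_id <- next_id + max(labs)
  }
  # relabel clusters by their first (lowest-index) survey
  first <- vapply(split(seq_len(n), assign), min, numeric(1))
  as.integer(factor(rank(first)[as.character(assign)]))
}

# deterministic complete-linkage agglomeration; ties between equally close
# merges go to the pair whose groups contain the lowest original indices
complete_linkage_cut <- function(d, h) {
  k <- nrow(d)
  if (k == 1) return(1L)
  groups <- as.list(seq_len(k))
  link <- d
  diag(link) <- Inf
  while (length(groups) > 1) {
    m <- min(link)
    if (m > h) break
    idx <- which(link == m, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    o <- order(idx[, 1], idx[, 2])
    bi <- idx[o[1], 1]; bj <- idx[o[1], 2]
    newrow <- pmax(link[bi, ], link[bj, ])
    link[bi, ] <- newrow
    link[, bi] <- newrow
    link[bi, bi] <- Inf
    link <- link[-bj, -bj, drop = FALSE]
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  labs <- integer(k)
  for (g in seq_along(groups)) labs[groups[[g]]] <- g
  labs
}

#' Aggregate surveys to cluster-by-depth-bin cells
#'
#' Within each spatial cluster, surveys in the same depth bin are combined
#' into a single cell carrying the mean percent bleached, its standard
#' error (sample SD / sqrt(n); missing when n = 1), the mean BS score, the
#' centroid, and the survey count.
#'
#' @param surveys data frame with columns `survey_id`, `lon`, `lat`,
#'   `depth_m`, `pct_bleached`, and optionally `island`, `zone`, `bs`,
#'   `year`.
#' @param clusters integer cluster ids from [cluster_surveys()].
#' @return data frame of cells with columns `cluster_id`, `depth_bin`,
#'   `n`, `mean_pct_bleached`, `se_pct_bleached`, `mean_bs`, `mean_depth_m`,
#'   `lon`, `lat` plus any of `island`, `zone`, `year` present.
#' @export
aggregate_cells <- function(surveys, clusters) {
  stopifnot(length(clusters) == nrow(surveys))
  surveys$cluster_id <- clusters
  surveys$depth_bin <- assign_depth_bin(surveys$depth_m)
  key <- interaction(surveys$cluster_id, surveys$depth_bin, drop = TRUE)
  parts <- split(surveys, key)
  out <- lapply(parts, function(g) {
    x <- g$pct_bleached
    cell <- data.frame(
      cluster_id = g$cluster_id[1],
      depth_bin = as.character(g$depth_bin[1]),
      n = nrow(g),
      mean_pct_bleached = mean(x),
      se_pct_bleached = if (nrow(g) > 1) stats::sd(x) / sqrt(nrow(g)) else NA_real_,
      mean_bs = if ("bs" %in% names(g)) mean(g$bs) else NA_real_,
      mean_depth_m = mean(g$depth_m),
      lon = mean(g$lon), lat = mean(g$lat)
    )
    for (extra in c("island", "zone", "year")) {
      if (extra %in% names(g)) cell[[extra]] <- g[[extra]][1]
    }
    cell
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cluster_id, out$depth_bin), , drop = FALSE]
}

#' Drop under-replicated zone-by-depth-bin combinations
#'
#' Any (zone, depth bin) with fewer than `min_cells` cluster cells is
#' removed entirely from the analysis set.
#'
#' @param cells cell table from [aggregate_cells()] with a `zone` column.
#' @param min_cells minimum cells per zone per depth bin (default 3).
#' @export
filter_zone_depth <- function(cells, min_cells = 3) {
  stopifnot("zone" %in% names(cells))
  key <- interaction(cells$zone, cells$depth_bin, drop = TRUE)
  counts <- table(key)
  keep <- counts[as.character(key)] >= min_cells
  cells[as.vector(keep), , drop = FALSE]
}

#' Analysis weights from inverse standard errors
#'
#' Raw weights are 1/SE of a cell's mean percent bleached. Raw weights
#' above their 95th percentile are capped at it; everything is then divided
#' by that percentile so weights lie in (0, 1]. Cells whose SE is missing
#' (n = 1) or zero receive the 5th percentile of the raw weights before
#' scaling. Percentiles use linear interpolation between order statistics.
#'
#' @param cells cell table with column `se_pct_bleached`.
#' @param cap,floor percentile probabilities for the cap and the
#'   missing-SE substitution (defaults 0.95 and 0.05).
#' @return numeric weights in (0, 1], one per cell.
#' @export
compute_weights <- function(cells, cap = 0.95, floor = 0.05) {
  se <- cells$se_pct_bleached
  missing <- is.na(se) | se <= 0
  if (all(missing)) stop("no cell has a defined positive SE")
  raw <- rep(NA_real_, length(se))
  raw[!missing] <- 1 / se[!missing]
  p95 <- stats::quantile(raw[!missing], cap, names = FALSE)  # type 7
  p05 <- stats::quantile(raw[!missing], floor, names = FALSE)
  raw[missing] <- p05
  raw[raw > p95] <- p95
  w <- raw / p95
  stopifnot(all(w > 0), all(w <= 1 + 1e-12))
  pmin(w, 1)
}
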