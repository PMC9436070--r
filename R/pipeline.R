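#' Read a synthetic (or real) input bundle from plain-text files
#'
#' Counterpart of [write_bundle()]: reads `surveys.csv`,
#' `site_indices.csv`, `score_table.csv`, `sst.csv` and any `grid_*.csv`
#' under `dir`.
#'
#' @param dir directory of input files.
#' @return list with `surveys`, `site_indices`, `score_table`, `sst`,
#'   `fields`.
#' @export
load_bundle <- function(dir) {
  surveys <- utils::read.csv(file.path(dir, "surveys.csv"))
  surveys$date <- as.Date(surveys$date)
  grids <- list()
  for (f in list.files(dir, pattern = "^grid_.*\\.csv$")) {
    grids[[sub("^grid_(.*)\\.csv$", "\\1", f)]] <-
      read_grid_csv(file.path(dir, f))
  }
  list(
    surveys = surveys,
    site_indices = utils::read.csv(file.path(dir, "site_indices.csv")),
    score_table = utils::read.csv(file.path(dir, "score_table.csv")),
    sst = read_sst_csv(file.path(dir, "sst.csv")),
    fields = list(grids = grids)
  )
}

#' Validate pipeline inputs
#'
#' Schema and consistency checks on a bundle; report-only. The run is
#' considered feasible iff the returned issue table is empty.
#'
#' @param bundle list with at least `surveys` and `score_table` (see
#'   [load_bundle()] / [simulate_bundle()]).
#' @return data frame with columns `issue`, `detail` (zero rows when
#'   everything checks out).
#' @export
validate_inputs <- function(bundle) {
  issues <- list()
  note <- function(issue, detail) {
    issues[[length(issues) + 1]] <<- data.frame(issue = issue,
                                                detail = detail)
  }
  s <- bundle$surveys
  need <- c("survey_id", "lon", "lat", "depth_m", "total_cover",
            "pct_bleached", "taxon", "cover")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols) > 0) {
    note("missing_columns", paste(missing_cols, collapse = ", "))
    return(do.call(rbind, issues))
  }
  for (v in c("lon", "lat", "depth_m", "total_cover", "pct_bleached",
              "cover")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(s[[v]]))))
    if (length(bad) > 0) {
      note("non_numeric", paste0(v, " at row(s) ",
                                 paste(utils::head(bad, 5), collapse = ",")))
    }
  }
  if (length(issues) > 0) return(do.call(rbind, issues))
  if (any(abs(s$lat) > 90 | abs(s$lon) > 360)) {
    note("bad_coordinates", "latitude/longitude out of range")
  }
  if (any(s$depth_m < 0 | s$depth_m > 30)) {
    note("bad_depth", "depth outside 0-30 m")
  }
  cover_sum <- tapply(s$cover, s$survey_id, sum)
  total <- tapply(s$total_cover, s$survey_id, function(x) x[1])
  over <- names(cover_sum)[cover_sum > total + 1e-6]
  if (length(over) > 0) {
    note("cover_inconsistent",
         paste("survey(s)", paste(utils::head(over, 5), collapse = ",")))
  }
  unresolved <- tryCatch({
    suppressMessages(resolve_scores(unique(s$taxon), bundle$score_table))
    character(0)
  }, error = function(e) conditionMessage(e))
  if (length(unresolved) > 0 && nzchar(unresolved[1])) {
    note("taxon_unscored", unresolved[1])
  }
  out <- if (length(issues) > 0) do.call(rbind, issues) else
    data.frame(issue = character(), detail = character())
  out
}

#' Score every survey: BS plus one row per survey
#'
#' Applies the synonym map, computes the BS score per survey via
#' [compute_bs()], and collapses the per-taxon table to one row per
#' survey. Surveys with zero live coral cover are excluded (with the
#' reason recorded).
#'
#' @param surveys per-survey-by-taxon table.
#' @param score_table see [resolve_scores()].
#' @param synonyms optional `from`/`to` synonym table.
#' @return list with `surveys` (one row per survey, with `bs`) and
#'   `excluded` (survey ids and reasons).
#' @export
score_surveys <- function(surveys, score_table, synonyms = NULL) {
  if (!is.null(synonyms) && nrow(synonyms) > 0) {
    surveys <- apply_synonyms(surveys, synonyms)
  }
  parts <- split(surveys, surveys$survey_id)
  excluded <- list()
  rows <- lapply(parts, function(g) {
    first <- g[1, setdiff(names(g), c("taxon", "cover", "score",
                                      "taxon_pct_bleached")), drop = FALSE]
    bs <- tryCatch(
      compute_bs(g[, c("taxon", "cover")], score_table, g$total_cover[1]),
      error = function(e) {
        excluded[[length(excluded) + 1]] <<- data.frame(
          survey_id = g$survey_id[1], reason = conditionMessage(e))
        NA_real_
      })
    first$bs <- bs
    first
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(surveys = out[!is.na(out$bs), , drop = FALSE],
       excluded = if (length(excluded) > 0) do.call(rbind, excluded) else
         data.frame(survey_id = integer(), reason = character()))
}

#' Run the full bleaching-drivers pipeline
#'
#' Executes, in order: thermal-stress metrics per island, survey
#' susceptibility scoring, spatial clustering/aggregation/weighting (plus
#' the weighted spatial ANOVA), covariate matching and standardization,
#' backward-BIC model selection, and scenario inference. When `out_dir`
#' is given, every stage writes CSV/JSON outputs and a manifest with input
#' hashes, the seed, and stage durations; an unchanged rerun reproduces
#' byte-identical outputs and, with `resume = TRUE`, completed runs are
#' not recomputed.
#'
#' @param bundle input bundle ([simulate_bundle()] or [load_bundle()]).
#' @param out_dir optional output directory.
#' @param cluster_km,min_cells,min_surveys_per_taxon analysis thresholds.
#' @param synonyms optional synonym table.
#' @param manageable,dhw_quantile scenario options (see
#'   [management_scenario()]).
#' @param overrides transform overrides for [build_driver_matrix()].
#' @param resume skip recomputation when the manifest matches.
#' @return list with each stage's results (`thermal`, `scores`, `cells`,
#'   `spatial_anova`, `drivers`, `model`, `perturbation`, `scenario`,
#'   `manifest`).
#' @export
run_pipeline <- function(bundle, out_dir = NULL, cluster_km = 1.0,
                         min_cells = 3, min_surveys_per_taxon = 6,
                         synonyms = NULL,
                         manageable = c("bs_score", "par", "sewage_effluent",
                                        "tourism", "urban_runoff"),
                         dhw_quantile = 0.95, overrides = character(),
                         resume = FALSE) {
  cfg_hash <- digest_inputs(bundle, cluster_km, min_cells,
                            min_surveys_per_taxon, dhw_quantile)
  if (resume && !is.null(out_dir) &&
      file.exists(file.path(out_dir, "manifest.json"))) {
    man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
    if (identical(man$config_hash, cfg_hash) &&
        isTRUE(man$completed)) {
      message("pipeline: resuming completed run in ", out_dir)
      return(invisible(c(readRDS_free_reload(out_dir), list(manifest = man))))
    }
  }
  issues <- validate_inputs(bundle)
  if (nrow(issues) > 0) {
    stop("ingest: invalid inputs — ", issues$issue[1], ": ",
         issues$detail[1])
  }
  stages <- list()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }

  # thermal: per-island MMM / DHW / event summary
  th <- clock({
    if (!is.null(bundle$sst)) {
      do.call(rbind, lapply(bundle$sst, function(series) {
        mmm <- compute_mmm(series)
        m <- compute_dhw(series, mmm)
        ev <- event_summary(m)
        data.frame(island = attr(series, "island_id"), mmm = mmm,
                   max_dhw = ev$max_dhw,
                   days_above_threshold = ev$days_above_threshold,
                   peak_date = ev$peak_date)
      }))
    } else NULL
  })
  stages$thermal <- th$secs

  # susceptibility: BS per survey + taxon summary
  sc <- clock(score_surveys(bundle$surveys, bundle$score_table, synonyms))
  scored <- sc$value$surveys
  taxon_tab <- if (all(c("island", "taxon_pct_bleached") %in%
                       names(bundle$surveys))) {
    taxon_bleaching_summary(bundle$surveys, min_surveys_per_taxon)
  } else NULL
  stages$susceptibility <- sc$secs

  # spatial: cluster, aggregate, filter, weight; spatial ANOVA by zone
  sp <- clock({
    cl <- cluster_surveys(scored, threshold_km = cluster_km)
    cells <- aggregate_cells(scored, cl)
    if ("zone" %in% names(cells)) {
      cells <- filter_zone_depth(cells, min_cells = min_cells)
    }
    cells$weight <- compute_weights(cells)
    cells
  })
  cells <- sp$value
  spatial_anova <- if ("zone" %in% names(cells) &&
                       length(unique(cells$zone)) > 1) {
    weighted_anova_oneway(sqrt(cells$mean_pct_bleached), cells$zone,
                          cells$weight)
  } else NULL
  stages$spatial <- sp$secs

  # covariates: match, transform, standardize on the analysis set
  cv <- clock(build_driver_matrix(cells, bundle$site_indices,
                                  overrides = overrides))
  drivers <- cv$value
  stages$covariates <- cv$secs

  # drivers model: weights recomputed on the analysis cells, then
  # backward-BIC selection from the full interaction candidate set
  md <- clock({
    d <- drivers$data
    d$weight <- compute_weights(d)
    stepwise_bic(sqrt(d$mean_pct_bleached), d[drivers$drivers], d$weight,
                 registry = drivers$registry)
  })
  model <- md$value
  stages$model <- md$secs

  # scenarios
  scn <- clock({
    d <- drivers$data
    list(perturbation = perturb_model(model),
         scenario = management_scenario(model, d[drivers$drivers],
                                        manageable = manageable,
                                        dhw_quantile = dhw_quantile))
  })
  stages$scenarios <- scn$secs

  manifest <- list(
    config_hash = cfg_hash,
    seed = if (!is.null(bundle$config)) bundle$config$seed else NA,
    stage_seconds = stages,
    n_surveys = nrow(scored),
    n_cells = nrow(cells),
    n_analysis_cells = nrow(drivers$data),
    n_dropped = nrow(drivers$dropped),
    selected_terms = model$terms,
    completed = TRUE
  )
  out <- list(thermal = th$value, scores = scored, taxon_summary = taxon_tab,
              cells = cells, spatial_anova = spatial_anova,
              drivers = drivers, model = model,
              perturbation = scn$value$perturbation,
              scenario = scn$value$scenario, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

# stable hash of the inputs that determine a run
digest_inputs <- function(bundle, ...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(surveys = bundle$surveys, site_indices = bundle$site_indices,
               score_table = bundle$score_table, opts = list(...)),
          tmp, version = 2)
  unname(tools::md5sum(tmp))
}

readRDS_free_reload <- function(out_dir) {
  list(cells = utils::read.csv(file.path(out_dir, "cells.csv")),
       coefficients = utils::read.csv(file.path(out_dir,
                                                "model_coefficients.csv")))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, f),
                                       row.names = FALSE)
  }
  w(out$thermal, "thermal.csv")
  w(out$scores, "survey_scores.csv")
  w(out$taxon_summary, "taxon_summary.csv")
  w(out$cells, "cells.csv")
  w(out$drivers$data, "driver_matrix.csv")
  w(as.data.frame(out$drivers$registry), "transform_registry.csv")
  w(out$drivers$dropped, "dropped_cells.csv")
  w(out$model$coefficients, "model_coefficients.csv")
  w(out$perturbation, "perturbation.csv")
  w(out$scenario$cells, "scenario_cells.csv")
  w(out$scenario$actions, "scenario_actions.csv")
  jsonlite::write_json(
    list(terms = out$model$terms, bic = out$model$bic,
         adj_r_squared = out$model$adj_r_squared, n = out$model$n),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file names the input bundle directory and any thresholds;
#' unspecified options take the [run_pipeline()] defaults. Recognized
#' keys: `input_dir` (required), `out_dir`, `cluster_km`, `min_cells`,
#' `min_surveys_per_taxon`, `dhw_quantile`, `manageable`,
#' `synonyms_csv`, `resume`.
#'
#' @param path YAML config path.
#' @return see [run_pipeline()].
#' @export
run_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$input_dir)) stop("config must name input_dir")
  if (!dir.exists(cfg$input_dir)) {
    stop("input_dir does not exist: ", cfg$input_dir)
  }
  bundle <- load_bundle(cfg$input_dir)
  synonyms <- if (!is.null(cfg$synonyms_csv)) {
    utils::read.csv(cfg$synonyms_csv)
  } else NULL
  args <- list(bundle = bundle, synonyms = synonyms)
  for (k in c("out_dir", "cluster_km", "min_cells",
              "min_surveys_per_taxon", "dhw_quantile", "manageable",
              "resume")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(run_pipeline, args)
}
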