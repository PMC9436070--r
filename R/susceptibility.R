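#' Resolve a susceptibility score for each taxon
#'
#' Looks up each taxon in the score table; a species missing from the table
#' falls back to its genus entry (rank `"genus"`, matched on the first word
#' of the taxon name). Each fallback is reported via `message()`.
#'
#' @param taxa character vector of taxon names/codes.
#' @param score_table data frame with columns `taxon`, `rank`
#'   (`"species"`/`"genus"`), `score` (integers 1-5).
#' @return numeric vector of scores; error naming the taxon if unresolvable.
#' @export
resolve_scores <- function(taxa, score_table) {
  stopifnot(all(c("taxon", "rank", "score") %in% names(score_table)))
  if (any(!score_table$score %in% 1:5)) {
    stop("susceptibility scores must be integers in 1..5")
  }
  idx <- match(taxa, score_table$taxon)
  miss <- which(is.na(idx))
  for (i in miss) {
    genus <- strsplit(taxa[i], "[ _]")[[1]][1]
    j <- which(score_table$taxon == genus & score_table$rank == "genus")
    if (length(j) == 0) stop("no susceptibility score for taxon: ", taxa[i])
    idx[i] <- j[1]
    message("susceptibility: genus fallback ", taxa[i], " -> ", genus)
  }
  score_table$score[idx]
}

#' Cover-weighted taxonomic bleaching susceptibility (BS) per survey
#'
#' For a survey s with taxa t, covers P_st (percent of substrate) and
#' susceptibility scores S_t (1 = least to 5 = most susceptible),
#' `BS = sum_t(P_st * S_t) / P_s`, where P_s is total live coral cover.
#' Unscored live cover (P_s greater than the summed taxon covers) dilutes
#' BS toward zero, exactly as the formula implies.
#'
#' @param rows data frame with columns `taxon` and `cover` for one survey.
#' @param score_table see [resolve_scores()].
#' @param total_cover P_s, total live coral cover percent; must be positive.
#' @return BS, a unitless score in (0, 5].
#' @export
compute_bs <- function(rows, score_table, total_cover) {
  if (!is.finite(total_cover) || total_cover <= 0) {
    stop("total live coral cover must be positive; survey excluded")
  }
  if (any(rows$cover < 0)) stop("negative taxon cover")
  if (sum(rows$cover) > total_cover + 1e-8) {
    stop("summed taxon covers exceed total live coral cover")
  }
  s <- resolve_scores(rows$taxon, score_table)
  sum(rows$cover * s) / total_cover
}

#' Apply a taxonomic synonym map to survey rows
#'
#' Rewrites taxon codes through the transitive closure of `from -> to`
#' pairs, then merges rows that collapse onto the same taxon within a
#' survey: covers are summed and the taxon percent-bleached becomes the
#' cover-weighted mean. A cyclic map is rejected.
#'
#' @param rows data frame with columns `survey_id`, `taxon`, `cover` and
#'   optionally `taxon_pct_bleached`.
#' @param synonyms data frame with columns `from`, `to` (may be empty).
#' @return rows with synonyms resolved and duplicates merged.
#' @export
apply_synonyms <- function(rows, synonyms) {
  if (nrow(synonyms) == 0) return(rows)
  map <- stats::setNames(synonyms$to, synonyms$from)
  resolve <- function(x) {
    seen <- character()
    while (x %in% names(map)) {
      if (x %in% seen) stop("cycle in synonym map at taxon: ", x)
      seen <- c(seen, x)
      x <- map[[x]]
    }
    x
  }
  rows$taxon <- vapply(rows$taxon, resolve, character(1), USE.NAMES = FALSE)
  key <- interaction(rows$survey_id, rows$taxon, drop = TRUE)
  if (!anyDuplicated(key)) return(rows)
  parts <- split(rows, key)
  merged <- lapply(parts, function(g) {
    out <- g[1, , drop = FALSE]
    out$cover <- sum(g$cover)
    if ("taxon_pct_bleached" %in% names(g)) {
      out$taxon_pct_bleached <- if (out$cover > 0) {
        sum(g$cover * g$taxon_pct_bleached) / out$cover
      } else mean(g$taxon_pct_bleached)
    }
    out
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$survey_id, out$taxon), , drop = FALSE]
}

#' Per-taxon bleaching summary by island
#'
#' Taxa observed on fewer than `min_surveys` surveys within an island are
#' dropped from that island's table; for the rest the mean and standard
#' error of per-taxon percent bleached are reported.
#'
#' @param rows data frame with columns `island`, `survey_id`, `taxon`,
#'   `taxon_pct_bleached`.
#' @param min_surveys minimum surveys per taxon per island (default 6).
#' @return data frame `island`, `taxon`, `n_surveys`, `mean_pct_bleached`,
#'   `se_pct_bleached` (0 when all values identical, NA when n = 1).
#' @export
taxon_bleaching_summary <- function(rows, min_surveys = 6) {
  stopifnot(min_surveys >= 1)
  key <- interaction(rows$island, rows$taxon, drop = TRUE)
  parts <- split(rows, key)
  out <- lapply(parts, function(g) {
    n <- length(unique(g$survey_id))
    if (n < min_surveys) return(NULL)
    x <- g$taxon_pct_bleached
    data.frame(
      island = g$island[1], taxon = g$taxon[1], n_surveys = n,
      mean_pct_bleached = mean(x),
      se_pct_bleached = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(island = character(), taxon = character(),
                      n_surveys = integer(), mean_pct_bleached = numeric(),
                      se_pct_bleached = numeric()))
  }
  rownames(out) <- NULL
  out[order(out$island, out$taxon), , drop = FALSE]
}
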