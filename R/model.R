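#' Weighted least-squares fit of the bleaching model
#'
#' Fits `response ~ terms` by weighted least squares, minimizing
#' `sum(w_i (y_i - x_i beta)^2)`. The reported BIC follows the weighted
#' residual-sum-of-squares convention `n log(wRSS / n) + k log(n)`, with
#' `n` the number of rows (each cluster cell counts once regardless of its
#' weight) and `k` the number of estimated coefficients.
#'
#' @param formula model formula (response on the square-root percent
#'   bleached scale by convention).
#' @param data data frame of standardized drivers plus the response.
#' @param weights positive observation weights (see [compute_weights()]).
#' @param registry optional [fit_registry()] carried along for
#'   back-transformation of predictions.
#' @return object of class `reef_wls`: list with the underlying `lm` fit,
#'   `terms` (labels), `coefficients` table (estimate, se, t, p), `n`,
#'   `bic`, `adj_r_squared`, `sigma2` (weighted MSE), `registry`.
#' @export
wls_fit <- function(formula, data, weights, registry = NULL) {
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }
  df <- data
  df$.wls_w <- weights
  fit <- stats::lm(formula, data = df, weights = .wls_w)
  if (anyNA(coef(fit))) {
    stop("design is rank deficient; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  k <- length(coef(fit))
  ct <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1], se = sm$coefficients[, 2],
    t = sm$coefficients[, 3], p = sm$coefficients[, 4],
    row.names = NULL
  )
  n_obs <- length(resid(fit))
  wrss <- sum(weights * resid(fit)^2)
  structure(list(
    fit = fit, formula = formula,
    terms = attr(stats::terms(fit), "term.labels"),
    coefficients = ct, n = n_obs,
    bic = n_obs * log(wrss / n_obs) + k * log(n_obs),
    adj_r_squared = sm$adj.r.squared,
    sigma2 = wrss / fit$df.residual,
    weights = weights, registry = registry
  ), class = "reef_wls")
}

#' @export
print.reef_wls <- function(x, ...) {
  cat("Weighted linear model:", deparse(x$formula), "\n")
  cat("n =", x$n, " BIC =", round(x$bic, 2),
      " adj R^2 =", round(x$adj_r_squared, 3), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
predict.reef_wls <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

# BIC of a column subset of a prebuilt design matrix (intercept included)
.bic_cols <- function(X, y, w, cols) {
  f <- stats::lm.wfit(X[, c("(Intercept)", cols), drop = FALSE], y, w)
  if (any(is.na(f$coefficients))) return(Inf)
  n <- length(y)
  n * log(sum(w * f$residuals^2) / n) + (length(cols) + 1) * log(n)
}

# mains that appear in a retained interaction are protected (marginality)
.eligible_terms <- function(terms) {
  ints <- grep(":", terms, value = TRUE)
  parents <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
  terms[grepl(":", terms) | !(terms %in% parents)]
}

#' Backward stepwise selection by BIC under marginality
#'
#' Starts from the full candidate model (all main effects plus the listed
#' two-way interactions) and greedily removes, at each step, the single
#' eligible term whose removal most lowers the BIC, stopping when no
#' removal lowers it. A main effect is never removed while one of its
#' interactions is retained (marginality); ties are broken by alphabetical
#' term order. By default the candidate interactions pair each `focal`
#' variable (acute thermal stress and taxonomic susceptibility) with every
#' other driver.
#'
#' @param response numeric response (square-root percent bleached).
#' @param data data frame of standardized driver columns.
#' @param weights positive observation weights.
#' @param main_effects character vector of driver names (default: every
#'   column of `data`).
#' @param interactions character vector of `"a:b"` labels, or `NULL` to
#'   build them from `focal`.
#' @param focal variables whose interactions with every other driver enter
#'   the candidate set.
#' @param registry optional [fit_registry()] attached to the result.
#' @return the selected model as a [wls_fit()] object, with attribute
#'   `"path"` recording the removal sequence.
#' @export
stepwise_bic <- function(response, data, weights,
                         main_effects = names(data), interactions = NULL,
                         focal = intersect(c("acute_dhw", "bs_score"),
                                           main_effects),
                         registry = NULL) {
  if (is.null(interactions)) {
    interactions <- unlist(lapply(focal, function(f) {
      vapply(setdiff(main_effects, f), function(d) {
        paste(sort(c(f, d)), collapse = ":")
      }, character(1))
    }))
    interactions <- sort(unique(interactions))
  }
  terms <- c(sort(main_effects), sort(interactions))
  df <- data
  df$.y <- response
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))), df)
  y <- response; w <- weights
  cur <- terms
  cur_bic <- .bic_cols(X, y, w, cur)
  if (!is.finite(cur_bic)) stop("full candidate model is not estimable")
  path <- character(0)
  repeat {
    if (length(cur) == 0) break
    elig <- sort(.eligible_terms(cur))
    if (length(elig) == 0) break
    bics <- vapply(elig, function(t) .bic_cols(X, y, w, setdiff(cur, t)),
                   numeric(1))
    best <- which.min(bics)  # first (alphabetical) minimum on ties
    if (bics[best] >= cur_bic) break
    cur <- setdiff(cur, elig[best])
    path <- c(path, elig[best])
    cur_bic <- bics[best]
  }
  rhs <- if (length(cur) == 0) "1" else paste(cur, collapse = " + ")
  out <- wls_fit(stats::as.formula(paste(".y ~", rhs)), df, w,
                 registry = registry)
  attr(out, "path") <- path
  out
}

#' Weighted one-way ANOVA with Tukey post-hoc comparisons
#'
#' The omnibus F test comes from the weighted linear model with group
#' indicators. Pairwise Tukey HSD comparisons use the weighted group means
#' with per-group effective sample size `sum(w)` and studentized-range
#' critical values (an approximation appropriate to weighted cell means).
#'
#' @param response numeric response (square-root percent bleached).
#' @param group grouping factor (zone or island).
#' @param weights positive observation weights.
#' @return list with `anova` (F, df, p), `tukey` (pairwise table), and
#'   `dropped` (singleton groups removed, with a warning).
#' @export
weighted_anova_oneway <- function(response, group, weights) {
  group <- factor(group)
  sizes <- table(group)
  dropped <- names(sizes)[sizes < 2]
  if (length(dropped) > 0) {
    warning("dropping singleton group(s): ", paste(dropped, collapse = ", "))
    keep <- !group %in% dropped
    response <- response[keep]; weights <- weights[keep]
    group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2) stop("need at least two groups with two cells each")
  d <- data.frame(.y = response, .g = group)
  fit <- wls_fit(.y ~ .g, d, weights)
  an <- stats::anova(fit$fit)
  lev <- levels(group)
  W <- tapply(weights, group, sum)
  m <- tapply(weights * response, group, sum) / W
  mse <- fit$sigma2
  df_res <- fit$fit$df.residual
  pairs <- utils::combn(lev, 2)
  tuk <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = m[pairs[2, ]] - m[pairs[1, ]], row.names = NULL
  )
  se <- sqrt(mse / 2 * (1 / W[pairs[1, ]] + 1 / W[pairs[2, ]]))
  tuk$q <- abs(tuk$diff) / se
  tuk$p_adj <- stats::ptukey(tuk$q, nlevels(group), df_res,
                             lower.tail = FALSE)
  list(
    anova = data.frame(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                       p = an$`Pr(>F)`[1]),
    tukey = tuk, dropped = dropped
  )
}

# keep only combos of `unit` x depth_bin present in every year
.both_years <- function(cells, unit) {
  yrs <- sort(unique(cells$year))
  key <- paste(cells[[unit]], cells$depth_bin)
  by_year <- split(key, cells$year)
  common <- Reduce(intersect, by_year)
  drop <- setdiff(unique(key), common)
  if (length(drop) > 0) {
    message("temporal analysis drops ", length(drop), " ", unit,
            " x depth-bin combination(s) not visited in all years")
  }
  cells[key %in% common, , drop = FALSE]
}

#' Temporal test for the main islands: weighted mixed model with LRT
#'
#' Square-root percent bleached is modelled on year, zone and their
#' interaction (fixed) with island as a random intercept, fitted by
#' maximum likelihood with the cell weights. Significance of each term
#' comes from likelihood-ratio tests of nested ML fits: interaction
#' against the additive model, and each main effect against the additive
#' model without it. Only zone-by-depth-bin combinations surveyed in both
#' years enter.
#'
#' @param cells cell table with columns `year`, `zone`, `island`,
#'   `mean_pct_bleached`, `depth_bin`.
#' @param weights positive observation weights aligned with `cells`.
#' @return list with `lrt` (term, chisq, df, p) and `fit` (the full
#'   `lmerMod`).
#' @export
temporal_tests_mhi <- function(cells, weights) {
  cells$.w <- weights
  d <- .both_years(cells, "zone")
  d$year <- factor(d$year); d$zone <- factor(d$zone)
  d$.y <- sqrt(d$mean_pct_bleached)
  ctl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  fit_ml <- function(f) {
    suppressMessages(lme4::lmer(f, data = d, weights = .w, REML = FALSE,
                                control = ctl))
  }
  full <- fit_ml(.y ~ year * zone + (1 | island))
  add  <- fit_ml(.y ~ year + zone + (1 | island))
  no_z <- fit_ml(.y ~ year + (1 | island))
  no_y <- fit_ml(.y ~ zone + (1 | island))
  lrt_row <- function(term, small, big) {
    ch <- max(0, 2 * (as.numeric(stats::logLik(big)) -
                        as.numeric(stats::logLik(small))))
    df <- attr(stats::logLik(big), "df") - attr(stats::logLik(small), "df")
    data.frame(term = term, chisq = ch, df = df,
               p = stats::pchisq(ch, df, lower.tail = FALSE))
  }
  lrt <- rbind(
    lrt_row("year", no_y, add),
    lrt_row("zone", no_z, add),
    lrt_row("year:zone", add, full)
  )
  list(lrt = lrt, fit = full, data = d)
}

#' Temporal test for the northwestern atolls: weighted two-way ANOVA
#'
#' Weighted two-way ANOVA of square-root percent bleached with fixed
#' effects of year, island and their interaction. Only island-by-depth-bin
#' combinations surveyed in both years enter.
#'
#' @param cells cell table with columns `year`, `island`,
#'   `mean_pct_bleached`, `depth_bin`.
#' @param weights positive observation weights aligned with `cells`.
#' @return list with `anova` (the sequential ANOVA table) and `fit`.
#' @export
temporal_tests_nwhi <- function(cells, weights) {
  cells$.w <- weights
  d <- .both_years(cells, "island")
  d$year <- factor(d$year); d$island <- factor(d$island)
  d$.y <- sqrt(d$mean_pct_bleached)
  fit <- wls_fit(.y ~ year * island, d, d$.w)
  list(anova = stats::anova(fit$fit), fit = fit)
}
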