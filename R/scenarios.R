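#' Predict percent bleached from a fitted model
#'
#' Predicts on the square-root scale, squares, and clips to \[0, 100\].
#' A negative square-root-scale prediction is clipped to zero (and
#' counted); clipping signals extrapolation beyond the fitted range.
#'
#' @param model a [wls_fit()] / [stepwise_bic()] result.
#' @param rows data frame of driver values in the standardized units the
#'   model was fitted on.
#' @return numeric vector of predicted percent bleached; attribute
#'   `"n_clipped"` counts clipped predictions.
#' @export
predict_bleached <- function(model, rows) {
  eta <- stats::predict(model$fit, newdata = rows)
  clipped <- sum(eta < 0 | eta^2 > 100)
  out <- pmin(pmax(eta, 0)^2, 100)
  attr(out, "n_clipped") <- clipped
  out
}

# refit the model with a term set, keeping weights and data
.refit_terms <- function(model, keep) {
  resp <- all.vars(model$formula)[1]
  rhs <- if (length(keep) == 0) "1" else paste(keep, collapse = " + ")
  wls_fit(stats::as.formula(paste(resp, "~", rhs)),
          model$fit$model, model$weights, registry = model$registry)
}

# term labels involving a driver (its main effect and interactions)
.terms_with <- function(terms, driver) {
  terms[vapply(strsplit(terms, ":", fixed = TRUE),
               function(p) driver %in% p, logical(1))]
}

#' Partial-regression curve for one driver
#'
#' The reduced model refits the selected terms without the driver and all
#' of its interactions. The curve is the back-transformed full-model
#' prediction over the driver's observed range (all other drivers at their
#' means) minus the back-transformed intercept contribution of the reduced
#' model; the points are the reduced-model residuals added to its
#' intercept, back-transformed and offset the same way, carrying the
#' observation weights.
#'
#' @param model a [wls_fit()] result containing `driver`.
#' @param data the analysis data (standardized driver columns).
#' @param driver driver name; must appear in the selected model.
#' @param grid_n number of curve evaluation points.
#' @return list with `curve` (driver value, predicted partial percent),
#'   `points` (observed driver value, partial residual percent, weight),
#'   and `reduced` (the reduced [wls_fit()]).
#' @export
partial_regression <- function(model, data, driver, grid_n = 100) {
  if (!driver %in% model$terms) stop("driver not in selected model: ", driver)
  reduced <- .refit_terms(model, setdiff(model$terms,
                                         .terms_with(model$terms, driver)))
  b0_red <- coef(reduced$fit)[["(Intercept)"]]
  base_pct <- max(b0_red, 0)^2
  xs <- seq(min(data[[driver]]), max(data[[driver]]), length.out = grid_n)
  vars <- setdiff(all.vars(stats::as.formula(model$formula)[[3]]), driver)
  newrow <- as.data.frame(lapply(data[vars], mean))
  grid <- newrow[rep(1, grid_n), , drop = FALSE]
  grid[[driver]] <- xs
  curve_pct <- predict_bleached(model, grid) - base_pct
  res <- stats::resid(reduced$fit)
  pts_pct <- pmax(b0_red + res, 0)^2 - base_pct
  list(
    curve = data.frame(driver = xs, partial_pct = as.numeric(curve_pct)),
    points = data.frame(driver = data[[driver]], partial_pct = pts_pct,
                        weight = model$weights),
    reduced = reduced
  )
}

#' Prediction surface over an interacting driver pair
#'
#' Evaluates the model over a grid spanning the observed ranges of two
#' drivers whose interaction is in the model, holding every other driver
#' at its mean, and returns predicted percent bleached (and the
#' square-root-scale linear predictor) per grid node plus the observed
#' driver pairs.
#'
#' @param model a [wls_fit()] result.
#' @param data the analysis data.
#' @param driver_a,driver_b the interacting pair (either order).
#' @param grid_n grid resolution per axis (default 25).
#' @return list with `surface` (a, b, eta_sqrt, pct) and `observed`.
#' @export
interaction_surface <- function(model, data, driver_a, driver_b,
                                grid_n = 25) {
  lab <- c(paste(driver_a, driver_b, sep = ":"),
           paste(driver_b, driver_a, sep = ":"))
  if (!any(lab %in% model$terms)) {
    stop("no ", driver_a, " x ", driver_b, " interaction in the model")
  }
  xs <- seq(min(data[[driver_a]]), max(data[[driver_a]]), length.out = grid_n)
  ys <- seq(min(data[[driver_b]]), max(data[[driver_b]]), length.out = grid_n)
  grid <- expand.grid(a = xs, b = ys)
  vars <- setdiff(all.vars(stats::as.formula(model$formula)[[3]]),
                  c(driver_a, driver_b))
  base <- as.data.frame(lapply(data[vars], mean))
  rows <- base[rep(1, nrow(grid)), , drop = FALSE]
  rows[[driver_a]] <- grid$a
  rows[[driver_b]] <- grid$b
  eta <- stats::predict(model$fit, newdata = rows)
  surf <- data.frame(a = grid$a, b = grid$b, eta_sqrt = eta,
                     pct = pmin(pmax(eta, 0)^2, 100))
  names(surf)[1:2] <- c(driver_a, driver_b)
  list(surface = surf,
       observed = data.frame(a = data[[driver_a]], b = data[[driver_b]]))
}

#' One-standard-deviation perturbation analysis
#'
#' For each driver in turn, predicts percent bleached at a synthetic
#' observation with every driver at its mean (0 in standardized units) and
#' the target driver moved to +1 or -1 SD; the baseline holds everything
#' at the mean. With centred predictors the baseline equals the squared
#' intercept exactly.
#'
#' @param model a [wls_fit()] result.
#' @param drivers drivers to perturb; defaults to every main effect in the
#'   model.
#' @return data frame with `driver`, `direction` (+1/-1), `predicted_pct`,
#'   `baseline_pct`.
#' @export
perturb_model <- function(model, drivers = NULL) {
  vars <- all.vars(stats::as.formula(model$formula)[[3]])
  if (is.null(drivers)) drivers <- intersect(model$terms, vars)
  base <- as.data.frame(as.list(stats::setNames(rep(0, length(vars)), vars)))
  baseline <- as.numeric(predict_bleached(model, base))
  rows <- lapply(drivers, function(d) {
    vapply(c(1, -1), function(dir) {
      r <- base
      if (d %in% names(r)) r[[d]] <- dir
      as.numeric(predict_bleached(model, r))
    }, numeric(1))
  })
  data.frame(
    driver = rep(drivers, each = 2),
    direction = rep(c(1, -1), length(drivers)),
    predicted_pct = unlist(rows),
    baseline_pct = baseline
  )
}

#' Management scenario at fixed high thermal stress
#'
#' Simulates a severe heating event by holding acute thermal stress at a
#' high quantile of its observed distribution over the analysis cells
#' (default the 95th percentile), keeping every other driver at its
#' observed value. Each manageable driver is then reduced by one standard
#' deviation in turn and the per-cell reduction in predicted bleaching is
#' computed; `best_action` is the action with the largest reduction (ties
#' broken alphabetically).
#'
#' @param model a [wls_fit()] result.
#' @param data analysis cells with standardized driver columns.
#' @param manageable drivers a manager could act on.
#' @param dhw_quantile quantile of `dhw_var` at which thermal stress is
#'   held (default 0.95).
#' @param delta shift applied to the managed driver, in SD units
#'   (default -1).
#' @param dhw_var name of the acute thermal-stress column.
#' @return list with `cells` (one row per cell: baseline and best action),
#'   `actions` (one row per cell x action with predicted percent and
#'   reduction), and `dhw_fixed` (the standardized DHW value used).
#' @export
management_scenario <- function(model, data,
                                manageable = c("bs_score", "par",
                                               "sewage_effluent", "tourism",
                                               "urban_runoff"),
                                dhw_quantile = 0.95, delta = -1,
                                dhw_var = "acute_dhw") {
  manageable <- sort(intersect(manageable, names(data)))
  if (length(manageable) == 0) stop("no manageable drivers available")
  dhw_fix <- stats::quantile(data[[dhw_var]], dhw_quantile, names = FALSE)
  base_rows <- data
  base_rows[[dhw_var]] <- dhw_fix
  baseline <- as.numeric(predict_bleached(model, base_rows))
  acts <- lapply(manageable, function(a) {
    rows <- base_rows
    rows[[a]] <- rows[[a]] + delta
    pred <- as.numeric(predict_bleached(model, rows))
    data.frame(cell = seq_len(nrow(data)), action = a,
               predicted_pct = pred, reduction = baseline - pred)
  })
  actions <- do.call(rbind, acts)
  per_cell <- split(actions, actions$cell)
  best <- vapply(per_cell, function(g) {
    g$action[order(-g$reduction, g$action)][1]  # ties -> alphabetical
  }, character(1))
  cells <- data.frame(
    cell = seq_len(nrow(data)),
    baseline_pct = baseline,
    best_action = best,
    best_reduction = vapply(per_cell, function(g) max(g$reduction),
                            numeric(1))
  )
  list(cells = cells, actions = actions, dhw_fixed = dhw_fix)
}
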