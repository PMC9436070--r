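test_that("back-transformed prediction: intercept-only, clipping, dot-product oracle", {
  m0 <- exact_model(c("(Intercept)" = 4))
  rows <- data.frame(x = rnorm(5))
  expect_equal(as.numeric(predict_bleached(m0, rows)), rep(16, 5))

  # negative sqrt-scale prediction clips to zero and is flagged
  mneg <- exact_model(c("(Intercept)" = -1, x = 0.1))
  p <- predict_bleached(mneg, data.frame(x = 0))
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "n_clipped"), 1)

  # random rows against a term-by-term dot product
  beta <- c("(Intercept)" = 3, a = 1, b = -0.5, "a:b" = 0.25)
  m <- exact_model(beta)
  set.seed(14)
  rows2 <- data.frame(a = rnorm(10), b = rnorm(10))
  eta <- beta["(Intercept)"] + beta["a"] * rows2$a + beta["b"] * rows2$b +
    beta["a:b"] * rows2$a * rows2$b
  expect_equal(as.numeric(predict_bleached(m, rows2)),
               pmin(pmax(eta, 0)^2, 100), tolerance = 1e-9)
})

test_that("partial regression: closed form for a single predictor, flat when beta = 0", {
  m <- exact_model(c("(Intercept)" = 4, x = 1))
  data <- m$fit$model
  pr <- partial_regression(m, data, "x", grid_n = 11)
  b0r <- coef(pr$reduced$fit)[["(Intercept)"]]
  expect_equal(pr$curve$partial_pct,
               (4 + pr$curve$driver)^2 - b0r^2, tolerance = 1e-8)
  # removing a driver with no interactions drops exactly one term
  expect_equal(length(pr$reduced$terms), length(m$terms) - 1)

  mz <- exact_model(c("(Intercept)" = 4, x = 1e-12, z = 1))
  prz <- partial_regression(mz, mz$fit$model, "x", grid_n = 7)
  expect_lt(diff(range(prz$curve$partial_pct)), 1e-6)

  expect_error(partial_regression(m, data, "nope"), "not in selected model")
})

test_that("interaction surface: mixed difference recovers the interaction, symmetric in order", {
  beta <- c("(Intercept)" = 3, a = 1, b = 1, "a:b" = 1)
  m <- exact_model(beta)
  d <- m$fit$model
  s <- interaction_surface(m, d, "a", "b", grid_n = 11)
  # pick sqrt-scale values at constructed corners via direct prediction
  corner <- function(av, bv) {
    r <- data.frame(a = av, b = bv)
    as.numeric(predict(m$fit, newdata = r))
  }
  mixed <- corner(2, 2) - corner(2, 0) - corner(0, 2) + corner(0, 0)
  expect_equal(mixed, 4 * beta[["a:b"]], tolerance = 1e-9)

  # additive model: mixed second difference of the surface is ~ 0
  madd <- exact_model(c("(Intercept)" = 3, a = 1, b = 1, "a:b" = 1e-13))
  sa <- interaction_surface(madd, madd$fit$model, "a", "b", grid_n = 5)
  eta <- matrix(sa$surface$eta_sqrt, 5, 5)
  expect_lt(max(abs(diff(t(diff(eta))))), 1e-8)

  # symmetry under swapping the pair
  s2 <- interaction_surface(m, d, "b", "a", grid_n = 11)
  expect_equal(sort(s$surface$pct), sort(s2$surface$pct), tolerance = 1e-9)

  expect_error(interaction_surface(m, d, "a", "zz"), "interaction")
})

test_that("perturbation: baseline is squared intercept; +/-1 SD closed forms", {
  m <- exact_model(c("(Intercept)" = 4, x = 1, z = 0.5, "x:z" = 0.3))
  pt <- perturb_model(m)
  expect_true(all(pt$baseline_pct == 16))  # centred: interactions vanish

  m1 <- exact_model(c("(Intercept)" = 4, x = 1))
  p1 <- perturb_model(m1)
  expect_equal(p1$predicted_pct[p1$driver == "x" & p1$direction == 1], 25)
  expect_equal(p1$predicted_pct[p1$driver == "x" & p1$direction == -1], 9)

  # perturbing a driver not in the model leaves the baseline unchanged
  p_abs <- perturb_model(m1, drivers = c("x", "ghost"))
  expect_equal(p_abs$predicted_pct[p_abs$driver == "ghost"], c(16, 16),
               tolerance = 1e-9)
})

test_that("management scenario: dominance, exhaustive oracle, observed-DHW consistency", {
  set.seed(19)
  n <- 40
  d <- data.frame(acute_dhw = rnorm(n), urban_runoff = rnorm(n),
                  tourism = rnorm(n), bs_score = rnorm(n))
  # only urban_runoff matters among the manageable drivers
  beta <- c("(Intercept)" = 4, acute_dhw = 1, urban_runoff = 0.5)
  m <- exact_model(beta)
  sc <- management_scenario(m, d, manageable = c("tourism", "urban_runoff"))
  expect_true(all(sc$cells$best_action == "urban_runoff"))
  expect_true(all(sc$cells$best_reduction >= 0))

  # per-cell best action equals a brute-force evaluation of every action
  beta2 <- c("(Intercept)" = 4, acute_dhw = 1, urban_runoff = 0.5,
             bs_score = 0.4, "acute_dhw:bs_score" = 0.6,
             "acute_dhw:urban_runoff" = -0.2)
  m2 <- exact_model(beta2)
  sc2 <- management_scenario(m2, d,
                             manageable = c("bs_score", "urban_runoff",
                                            "tourism"))
  dhw_fix <- quantile(d$acute_dhw, 0.95, names = FALSE)
  for (i in seq_len(nrow(d))) {
    base_row <- d[i, ]; base_row$acute_dhw <- dhw_fix
    base <- as.numeric(predict_bleached(m2, base_row))
    red <- vapply(c("bs_score", "tourism", "urban_runoff"), function(a) {
      r <- base_row; r[[a]] <- r[[a]] - 1
      base - as.numeric(predict_bleached(m2, r))
    }, numeric(1))
    best <- names(red)[order(-red, names(red))][1]
    expect_equal(sc2$cells$best_action[i], best)
    expect_equal(sc2$cells$baseline_pct[i], base, tolerance = 1e-9)
  }

  # a cell whose observed DHW equals the fixed quantile keeps its ordinary
  # prediction as the scenario baseline: pick the quantile that lands
  # exactly on an order statistic
  r <- 35
  j <- order(d$acute_dhw)[r]
  sc3 <- management_scenario(m2, d, manageable = "tourism",
                             dhw_quantile = (r - 1) / (n - 1))
  expect_equal(sc3$dhw_fixed, d$acute_dhw[j], tolerance = 1e-12)
  expect_equal(sc3$cells$baseline_pct[j],
               as.numeric(predict_bleached(m2, d[j, ])), tolerance = 1e-9)

  expect_error(management_scenario(m2, d, manageable = "nothing_here"),
               "manageable")
})
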