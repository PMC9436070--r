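test_that("WLS matches closed-form weighted normal equations", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(n)
    w <- runif(n, 0.2, 1)
    fit <- wls_fit(y ~ x1 + x2, d, w)
    X <- cbind(1, d$x1, d$x2)
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * d$y))
    expect_equal(unname(coef(fit$fit)), as.numeric(beta), tolerance = 1e-10)
  }
})

test_that("equal weights reproduce OLS; splitting a row halves its weight", {
  set.seed(3)
  d <- data.frame(x = rnorm(20))
  d$y <- 2 + d$x + rnorm(20)
  fit_w <- wls_fit(y ~ x, d, rep(0.7, 20))
  expect_equal(coef(fit_w$fit), coef(lm(y ~ x, d)), tolerance = 1e-10)

  # duplicating a row with weight 1/2 each == that row with weight 1
  d2 <- rbind(d, d[7, ])
  w2 <- c(rep(1, 20), 0.5); w2[7] <- 0.5
  fit_split <- wls_fit(y ~ x, d2, w2)
  fit_orig <- wls_fit(y ~ x, d, rep(1, 20))
  expect_equal(coef(fit_split$fit), coef(fit_orig$fit), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the aliased term", {
  d <- data.frame(x1 = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(wls_fit(y ~ x1 + x2, d, rep(1, 10)), "x2")
})

test_that("BIC follows the stated weighted-RSS convention", {
  set.seed(4)
  d <- data.frame(x = rnorm(30))
  d$y <- 1 + d$x + rnorm(30)
  w <- runif(30, 0.5, 1)
  fit <- wls_fit(y ~ x, d, w)
  wrss <- sum(w * resid(fit$fit)^2)
  expect_equal(fit$bic, 30 * log(wrss / 30) + 2 * log(30))
  # predictions reproduce fitted values on training rows
  expect_equal(predict(fit, d), fitted(fit$fit), tolerance = 1e-9)
})

test_that("backward BIC keeps real structure, respects marginality, and is locally optimal", {
  set.seed(8)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n))
  y <- 1 + d$x1 + d$x2 + d$x1 * d$x2 + rnorm(n, 0, 0.5)
  w <- rep(1, n)
  sel <- stepwise_bic(y, d, w, main_effects = paste0("x", 1:4),
                      interactions = c("x1:x2", "x1:x3"))
  expect_true(all(c("x1", "x2", "x1:x2") %in% sel$terms))
  expect_false("x1:x3" %in% sel$terms)

  # marginality: parents of retained interactions are present
  ints <- grep(":", sel$terms, value = TRUE)
  parents <- unique(unlist(strsplit(ints, ":")))
  expect_true(all(parents %in% sel$terms))

  # BIC(selected) <= BIC(full candidate model)
  full <- wls_fit(y ~ x1 + x2 + x3 + x4 + x1:x2 + x1:x3, cbind(d, y = y), w)
  expect_lte(sel$bic, full$bic)

  # local optimality: no single eligible removal lowers BIC further
  for (t in sel$terms) {
    if (!grepl(":", t) && t %in% parents) next
    keep <- setdiff(sel$terms, t)
    rhs <- if (length(keep) == 0) "1" else paste(keep, collapse = " + ")
    red <- wls_fit(as.formula(paste("y ~", rhs)), cbind(d, y = y), w)
    expect_gte(red$bic, sel$bic)
  }
})

test_that("selection agrees with stepAIC under the BIC penalty", {
  set.seed(12)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 2 + 1.5 * d$a - d$b + rnorm(n, 0, 0.7)
  w <- runif(n, 0.3, 1)
  sel <- stepwise_bic(d$y, d[c("a", "b", "c")], w,
                      main_effects = c("a", "b", "c"), interactions = NULL,
                      focal = character())
  d$.w <- w
  full <- lm(y ~ a + b + c, data = d, weights = .w)
  ref <- MASS::stepAIC(full, direction = "backward", k = log(n), trace = 0)
  expect_setequal(sel$terms, attr(terms(ref), "term.labels"))
})

test_that("weighted one-way ANOVA matches a hand-built table and degenerates sensibly", {
  # equal weights, 3 groups: SSB = 14, SSW = 6 -> F = 7 on (2, 6) df
  y <- c(1, 2, 3, 2, 3, 4, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- weighted_anova_oneway(y, g, rep(1, 9))
  expect_equal(res$anova$F, 7, tolerance = 1e-9)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 6)
  expect_equal(res$anova$p, pf(7, 2, 6, lower.tail = FALSE))

  # two identical groups: F ~ 0, p ~ 1
  res2 <- weighted_anova_oneway(c(1, 2, 3, 1, 2, 3),
                                rep(c("a", "b"), each = 3), rep(1, 6))
  expect_lt(res2$anova$F, 1e-20)
  expect_gt(res2$anova$p, 0.999)

  # Tukey table is symmetric in group order
  res3 <- weighted_anova_oneway(y, factor(g, levels = c("c", "a", "b")),
                                rep(1, 9))
  p1 <- sort(res$tukey$p_adj)
  p3 <- sort(res3$tukey$p_adj)
  expect_equal(p1, p3, tolerance = 1e-12)

  # singleton group dropped with a warning
  expect_warning(
    res4 <- weighted_anova_oneway(c(y, 9), c(g, "d"), rep(1, 10)),
    "singleton"
  )
  expect_equal(res4$dropped, "d")
})

test_that("temporal tests: null-year limit and WLS limit of the mixed model", {
  base <- expand.grid(zone = paste0("z", 1:3), depth_bin = c("shallow", "mid"),
                      rep = 1:4)
  base$island <- ifelse(base$zone == "z1", "i1", "i2")
  set.seed(6)
  base$mean_pct_bleached <- runif(nrow(base), 5, 50)
  two <- rbind(transform(base, year = 2015), transform(base, year = 2019))
  w <- rep(1, nrow(two))

  # identical data in both years: the year LRT statistic vanishes
  res <- temporal_tests_mhi(two, w)
  expect_lt(res$lrt$chisq[res$lrt$term == "year"], 1e-4)
  expect_true(all(res$lrt$chisq >= 0))

  # no island-level variance: fixed effects collapse to the WLS fit
  d <- res$data
  fe <- lme4::fixef(res$fit)
  ref <- wls_fit(.y ~ year * zone, d, d$.w)
  expect_equal(unname(fe), unname(coef(ref$fit)[names(fe)]),
               tolerance = 1e-4)

  # NWHI two-way weighted ANOVA runs and reports year/island/interaction
  nw <- rbind(transform(base, year = 2014), transform(base, year = 2019))
  nw$mean_pct_bleached <- runif(nrow(nw), 5, 60)
  res2 <- temporal_tests_nwhi(nw, rep(1, nrow(nw)))
  expect_setequal(rownames(res2$anova)[1:3],
                  c("year", "island", "year:island"))
})
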