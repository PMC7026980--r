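test_that("basis matches an independent truncated-power evaluation", {
  for (knots in list(c(5, 10, 15), c(4, 8, 12, 16), c(2, 6, 10, 14, 18))) {
    x <- seq(0, 22, length.out = 100)
    expect_equal(unname(rcs_basis(x, knots)), rcs_reference(x, knots),
                 tolerance = 1e-10)
  }
})

test_that("basis is (x, 0) below the first knot and has linear tails", {
  knots <- c(6, 10, 16)
  x <- seq(0, 6, length.out = 20)
  B <- rcs_basis(x, knots)
  expect_equal(B[, 1], x)
  expect_equal(unname(B[, 2]), rep(0, 20))
  # numerical second derivative vanishes outside the boundary knots
  d2 <- function(f, x, h = 1e-3) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  for (m in 3:5) {
    kn <- seq(4, 16, length.out = m)
    for (j in seq_len(m - 1)) {
      f <- function(v) rcs_basis(v, kn)[, j]
      expect_lt(abs(d2(f, kn[m] + 1)), 1e-6)
      expect_lt(abs(d2(f, kn[1] - 1)), 1e-6)
      # and is nonzero inside for the nonlinear terms
      if (j > 1) expect_gt(abs(d2(f, mean(kn))), 1e-6)
    }
  }
  expect_error(rcs_basis(1:10, c(5, 5, 10)), "strictly increasing")
})

test_that("default knot placement hits the documented quantiles", {
  set.seed(2)
  x <- runif(1e5, 0, 20)
  expect_equal(place_knots(x, 3), c(2, 10, 18), tolerance = 0.1)
  expect_equal(place_knots(x, 4), c(1, 7, 13, 19), tolerance = 0.1)
  expect_equal(place_knots(x, 5), quantile(x, c(.05, .275, .5, .725, .95),
                                           names = FALSE),
               tolerance = 1e-10)
  expect_equal(place_knots(sample(x), 3), place_knots(x, 3))
  expect_error(place_knots(rep(7, 100), 3), "distinct")
})

test_that("the fitted curve is anchored at the zero reference", {
  st <- tiny_study(seed = 207, n = 2000L, zips = 8L, months = 48L,
                   hazard = 0.008, rr = 1.6)
  pm <- expand_person_months(st$cohort, st$residence, st$expo, cause = "*")
  sfit <- fit_spline_model(pm, m = 3)
  grid <- seq(0, 15, by = 0.5)
  cur <- rr_curve(sfit, grid)
  expect_equal(cur[exposure == 0, rr], 1)
  expect_equal(cur[exposure == 0, hi95 - lo95], 0)
  expect_true(all(cur$lo95 <= cur$rr & cur$rr <= cur$hi95))
})

test_that("a linear fit's curve is exactly log-linear and matches rr_per_10", {
  st <- tiny_study(seed = 207, n = 2000L, zips = 8L, months = 48L,
                   hazard = 0.008, rr = 1.6)
  pm <- expand_person_months(st$cohort, st$residence, st$expo, cause = "*")
  fit <- pm_cox(pm)
  cur <- rr_curve(fit, grid = c(0, 5, 10, 20))
  b <- unname(fit$coefficients[1])
  expect_equal(cur$rr, exp(b * c(0, 5, 10, 20)), tolerance = 1e-12)
  expect_equal(cur[exposure == 10, rr], unname(rr_per_10(fit)["rr"]),
               tolerance = 1e-12)
})

test_that("zero spline coefficients give a flat curve", {
  fit <- structure(list(
    coefficients = c(x = 0, x1 = 0), converged = TRUE,
    vcov = matrix(0, 2, 2, dimnames = list(c("x", "x1"), c("x", "x1")))),
    class = "cox_fit")
  attr(fit, "knots") <- c(5, 10, 15)
  attr(fit, "spline_terms") <- c("x", "x1")
  cur <- rr_curve(fit, grid = seq(0, 20, 2))
  expect_equal(cur$rr, rep(1, nrow(cur)))
})

test_that("curves are invariant to the basis parameterization", {
  # refit with shifted knots spanning the same data: the fitted curve on a
  # common grid must agree closely even though coefficients differ
  st <- tiny_study(seed = 208, n = 3000L, zips = 8L, months = 48L,
                   hazard = 0.01, rr = 1.8)
  pm <- expand_person_months(st$cohort, st$residence, st$expo, cause = "*")
  k <- place_knots(pm$pm25_12mo, 3)
  f1 <- fit_spline_model(pm, knots = k)
  # same spline space: translated exposure, translated knots
  pm2 <- data.table::copy(pm)[, pm25_12mo := pm25_12mo + 5]
  f2 <- fit_spline_model(pm2, knots = k + 5)
  g <- seq(min(pm$pm25_12mo), max(pm$pm25_12mo), length.out = 40)
  c1 <- rr_curve(f1, g, x_ref = g[1])
  c2 <- rr_curve(f2, g + 5, x_ref = g[1] + 5)
  expect_equal(c1$rr, c2$rr, tolerance = 1e-6)
})

test_that("knot-count comparison ranks by AIC with ties to fewer knots", {
  st <- tiny_study(seed = 209, n = 2500L, zips = 8L, months = 48L,
                   hazard = 0.01, rr = 1.5)
  pm <- expand_person_months(st$cohort, st$residence, st$expo, cause = "*")
  tab <- compare_knot_counts(pm)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$converged))
  expect_identical(tab$k_params, c(2L, 3L, 4L))
  expect_identical(tab$m[which.min(tab$aic)], attr(tab, "selected"))
  tab2 <- compare_knot_counts(pm)
  expect_equal(tab$aic, tab2$aic)   # deterministic given the data
  # nesting identity: forcing the extra coefficients to zero shifts AIC by
  # exactly 2 * the added parameter count
  f3 <- attr(tab, "fits")[["3"]]
  k3 <- attr(f3, "knots")
  sp <- add_spline_terms(pm, "pm25_12mo", k3)
  cells <- aggregate_cells(sp$pm, covariates = sp$covariates,
                           informative_only = TRUE)
  ll_zero <- partial_loglik(cells, c(unname(f3$coefficients[1]), 0))$loglik
  lin <- pm_cox(pm)
  expect_equal(ll_zero, partial_loglik(
    aggregate_cells(pm, covariates = "pm25_12mo", informative_only = TRUE),
    unname(f3$coefficients[1]))$loglik, tolerance = 1e-9)
  aic_lin_at <- 2 * 2 - 2 * ll_zero
  expect_equal(aic_lin_at - (2 * 1 - 2 * ll_zero), 2)
  expect_true(is.finite(lin$loglik))
})

test_that("the nonlinearity Wald test has one df for three knots", {
  st <- tiny_study(seed = 209, n = 2500L, zips = 8L, months = 48L,
                   hazard = 0.01, rr = 1.5)
  pm <- expand_person_months(st$cohort, st$residence, st$expo, cause = "*")
  f <- fit_spline_model(pm, m = 3)
  nt <- nonlinearity_test(f)
  expect_identical(unname(nt["df"]), 1)
  expect_gte(nt[["p"]], 0); expect_lte(nt[["p"]], 1)
  lin <- pm_cox(pm)
  expect_error(nonlinearity_test(lin), "no nonlinear")
})
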