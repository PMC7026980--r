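m0 <- ym_to_month("2000-01")

one_person <- function(death = TRUE, icd = "I21") {
  cohort <- data.table::data.table(
    id = "P1", birth_month = m0 - 70 * 12L, sex = "female", race = "White",
    entry_month = m0, end_month = m0 + 2L,
    death_month = if (death) m0 + 2L else NA_integer_,
    icd10_cause = if (death) icd else NA_character_)
  residence <- data.table::data.table(id = "P1", start_month = m0,
                                      zip = "ZA")
  expo <- data.table::data.table(id = "P1", month = m0 + 0:2,
                                 pm25_12mo = c(9, 10, 11))
  list(cohort = cohort, residence = residence, expo = expo)
}

test_that("expansion: one row per at-risk month, event at the death month", {
  w <- one_person()
  pm <- expand_person_months(w$cohort, w$residence, w$expo,
                             cause = "All CVD")
  expect_identical(nrow(pm), 3L)
  expect_identical(pm$fu_index, 1:3)
  expect_identical(pm$event, c(0L, 0L, 1L))
  # modeling a cause the death does not belong to: competing-cause censor
  pm2 <- expand_person_months(w$cohort, w$residence, w$expo,
                              cause = "All cancer")
  expect_identical(pm2$event, c(0L, 0L, 0L))
  # switching the cause on the expansion reproduces a fresh expansion
  set_event_cause(pm, "All cancer")
  expect_identical(pm$event, pm2$event)
  set_event_cause(pm, "IHD")
  expect_identical(pm$event, c(0L, 0L, 1L))
})

test_that("expansion: the age bin advances at the birthday month", {
  cohort <- data.table::data.table(
    id = "P1", birth_month = m0 - 90 * 12L + 2L, sex = "male",
    race = "White", entry_month = m0, end_month = m0 + 5L,
    death_month = NA_integer_, icd10_cause = NA_character_)
  residence <- data.table::data.table(id = "P1", start_month = m0,
                                      zip = "ZA")
  expo <- data.table::data.table(id = "P1", month = m0 + 0:5,
                                 pm25_12mo = 10)
  pm <- expand_person_months(cohort, residence, expo, cause = "*")
  expect_identical(pm$age_cat, c("89", "89", "90+", "90+", "90+", "90+"))
})

test_that("expansion rejects deaths before entry and overlapping segments", {
  w <- one_person()
  bad <- data.table::copy(w$cohort)
  bad$death_month <- m0 - 1L
  expect_error(expand_person_months(bad, w$residence, w$expo, cause = "*"),
               "P1")
  res2 <- rbind(w$residence,
                data.table::data.table(id = "P1", start_month = m0,
                                       zip = "ZB"))
  expect_error(expand_person_months(w$cohort, res2, w$expo, cause = "*"),
               "overlapping")
})

test_that("aggregation compresses exactly and counts balance", {
  pm <- tiny_pm()
  cells <- aggregate_cells(pm)
  expect_identical(sum(cells$n_at_risk), nrow(pm))
  expect_identical(sum(cells$n_events), sum(pm$event))
  expect_true(all(cells$n_events <= cells$n_at_risk))
  # all-distinct covariates: no compression
  pm2 <- data.table::copy(pm)[, pm25_12mo := pm25_12mo + seq_len(.N) * 1e-9]
  expect_identical(nrow(aggregate_cells(pm2)), nrow(pm2))
  # shared covariate vector in one stratum-month: a single cell
  pm3 <- data.table::data.table(
    age_cat = "70", sex = "f", race = "W", zip = "Z", fu_index = 1L,
    event = c(rep(1L, 3), rep(0L, 997)), pm25_12mo = 10)
  c3 <- aggregate_cells(pm3)
  expect_identical(nrow(c3), 1L)
  expect_identical(c3$n_at_risk, 1000L)
  expect_identical(c3$n_events, 3L)
})

test_that("cells and raw person-months give identical likelihood pieces", {
  pm <- tiny_pm()
  cells <- aggregate_cells(pm)
  raw <- aggregate_cells(pm, collapse = FALSE)
  for (b in c(-0.1, 0, 0.07)) {
    a <- partial_loglik(cells, b)
    r <- partial_loglik(raw, b)
    expect_equal(a$loglik, r$loglik, tolerance = 1e-8)
    expect_equal(a$gradient, r$gradient, tolerance = 1e-8)
    expect_equal(a$information, r$information, tolerance = 1e-8)
  }
  f1 <- fit_cox(cells); f2 <- fit_cox(raw)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(sqrt(diag(f1$vcov)), sqrt(diag(f2$vcov)), tolerance = 1e-8)
})

test_that("informative-only aggregation changes nothing but the size", {
  pm <- tiny_pm()
  full <- fit_cox(aggregate_cells(pm))
  fast <- fit_cox(aggregate_cells(pm, informative_only = TRUE))
  expect_equal(full$coefficients, fast$coefficients, tolerance = 1e-10)
  expect_equal(full$vcov, fast$vcov, tolerance = 1e-10)
  expect_equal(full$loglik, fast$loglik, tolerance = 1e-10)
})

test_that("gradient at zero equals events minus risk-set means", {
  pm <- tiny_pm()
  cells <- aggregate_cells(pm)
  got <- partial_loglik(cells, 0)
  # closed form: sum over events of (x_event - unweighted risk-set mean)
  dt <- data.table::as.data.table(pm)
  dt[, rs_mean := mean(pm25_12mo), by = list(skey, fu_index)]
  want <- dt[event == 1L, sum(pm25_12mo - rs_mean)]
  expect_equal(unname(got$gradient), want, tolerance = 1e-8)
})

test_that("no covariate contrast makes the likelihood flat", {
  pm3 <- data.table::data.table(
    age_cat = "70", sex = "f", race = "W", zip = rep(c("A", "B"), each = 50),
    fu_index = rep(1:5, 20), event = rep(c(1L, rep(0L, 9)), 10),
    pm25_12mo = 10)
  cells <- aggregate_cells(pm3)
  expect_equal(partial_loglik(cells, 0.3)$loglik,
               partial_loglik(cells, -0.2)$loglik, tolerance = 1e-12)
  expect_equal(unname(partial_loglik(cells, 0.4)$gradient), 0,
               tolerance = 1e-12)
  expect_error(fit_cox(cells), "contrast")
})

test_that("fits match the reference survival implementation", {
  skip_if_not_installed("survival")
  pm <- tiny_pm()
  cells <- aggregate_cells(pm)
  fit <- fit_cox(cells)
  cf <- suppressWarnings(survival::coxph(
    survival::Surv(fu_index - 1, fu_index, event) ~ pm25_12mo +
      survival::strata(age_cat, sex, race, zip),
    data = pm, ties = "breslow",
    control = survival::coxph.control(eps = 1e-12, iter.max = 50)))
  expect_equal(unname(fit$coefficients), unname(coef(cf)),
               tolerance = 1e-8)
  expect_equal(sqrt(fit$vcov[1, 1]), sqrt(vcov(cf)[1, 1]),
               tolerance = 1e-8)
})

test_that("coefficients are invariant to translating a covariate", {
  pm <- tiny_pm()
  f1 <- fit_cox(aggregate_cells(pm))
  pm2 <- data.table::copy(pm)[, pm25_12mo := pm25_12mo + 7.3]
  f2 <- fit_cox(aggregate_cells(pm2))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-6)
})

test_that("strata without events do not alter the estimates", {
  pm <- tiny_pm()
  f1 <- fit_cox(aggregate_cells(pm))
  extra <- data.table::data.table(
    id = "GHOST", month = m0 + 0:9, fu_index = 1:10, zip = "ZZZ",
    age_cat = "77", sex = "female", race = "Other", event = 0L,
    death_root = NA_character_, skey = max(pm$skey) + 1L,
    pm25_12mo = rnorm(10, 10))
  pm2 <- rbind(pm, extra, fill = TRUE)
  f2 <- fit_cox(aggregate_cells(pm2))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("a perfectly separating covariate flags a monotone likelihood", {
  # within each risk set the event always has the larger covariate value
  pm <- data.table::data.table(
    age_cat = "70", sex = "f", race = "W", zip = "Z",
    fu_index = rep(1:20, each = 5),
    event = rep(c(1L, 0L, 0L, 0L, 0L), 20),
    x = rep(c(1, 0, 0, 0, 0), 20))
  cells <- aggregate_cells(pm, covariates = "x")
  fit <- fit_cox(cells)
  expect_true(fit$monotone)
  expect_false(fit$converged)
  expect_error(rr_per_10(fit), "unconverged")
})

test_that("risk ratios per 10 invert the log scale with Wald bounds", {
  fit <- structure(list(coefficients = c(x = log(1.088) / 10),
                        vcov = matrix(0, 1, 1, dimnames = list("x", "x")),
                        converged = TRUE), class = "cox_fit")
  rr <- rr_per_10(fit)
  expect_equal(unname(rr["rr"]), 1.088, tolerance = 1e-12)
  fit0 <- structure(list(coefficients = c(x = 0),
                         vcov = matrix(0.01^2, 1, 1,
                                       dimnames = list("x", "x")),
                         converged = TRUE), class = "cox_fit")
  rr0 <- rr_per_10(fit0)
  expect_equal(unname(rr0["rr"]), 1)
  expect_lt(rr0["lo95"], 1); expect_gt(rr0["hi95"], 1)
  # CI width grows with the standard error at fixed beta
  widths <- vapply(c(0.005, 0.01, 0.02), function(s) {
    f <- structure(list(coefficients = c(x = 0.01),
                        vcov = matrix(s^2, 1, 1,
                                      dimnames = list("x", "x")),
                        converged = TRUE), class = "cox_fit")
    r <- rr_per_10(f); unname(r["hi95"] - r["lo95"])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
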