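test_that("the same seed reproduces the study byte for byte", {
  cfg <- sim_config(n_beneficiaries = 500L, n_zips = 8L, n_months = 30L)
  a <- simulate_study(cfg, seed = 77)
  b <- simulate_study(cfg, seed = 77)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$residence, b$residence)
  expect_identical(a$exposures$pm25, b$exposures$pm25)
  expect_identical(a$exposures$no2, b$exposures$no2)
  c2 <- simulate_study(cfg, seed = 78)
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("exposure calibration hits the documented targets", {
  cfg <- sim_config()      # 500 ZIPs, 108 months
  set.seed(55)
  ex <- simulate_exposures(cfg)
  zm_pm <- zip_exposure_12mo(ex$pm25, "pm12")
  zm_no <- zip_exposure_12mo(ex$no2, "no12")
  zm <- merge(zm_pm, zm_no, by = c("zip", "month"))
  zm <- zm[stats::complete.cases(zm)]
  r <- cor(zm$pm12, zm$no12)
  expect_lt(abs(r - 0.59), 0.05)
  expect_lt(abs(mean(zm$pm12) - 10.32), 0.5)
  expect_lt(abs(sd(zm$pm12) - 3.15), 0.5)
  # urban ZIPs carry higher concentrations on average
  urb <- merge(zm[, list(m = mean(pm12)), by = zip],
               ex$zips[, list(zip, urban)], by = "zip")
  expect_gt(urb[urban == TRUE, mean(m)], urb[urban == FALSE, mean(m)])
  # an unattainable correlation target errors at calibration time
  expect_error(simulate_exposures(sim_config(target_corr_no2 = 0.95)),
               "unattainable")
})

test_that("generated data pass the cohort validators", {
  st <- tiny_study(seed = 88, n = 2000L, zips = 12L, months = 48L,
                   hazard = 0.01)
  expect_identical(nrow(validate_cohort(st$cohort, st$residence)), 0L)
  # all deaths carry classifiable codes
  codes <- st$cohort[!is.na(icd10_cause), icd10_cause]
  cl <- classify_cause(codes)
  expect_true(all(vapply(cl, length, 1L) >= 1L))
  n_unclassified <- sum(!vapply(
    cl, function(s) any(c("Non-accidental", "Accidental") %in% s), TRUE))
  expect_identical(n_unclassified, 0L)
})

test_that("a null world shows no exposure-mortality gradient", {
  st <- tiny_study(seed = 99, n = 8000L, zips = 10L, months = 48L,
                   hazard = 0.01, rr = 1.0)
  pm <- expand_person_months(st$cohort, st$residence, st$expo, cause = "*")
  # death rates by tertile of the spatial (ZIP-mean) exposure; the spatial
  # field is independent of demographics, so under a null effect deaths
  # are proportional to person-months within tertile
  zmean <- pm[, list(zm = mean(pm25_12mo)), by = zip]
  zmean[, tert := cut(zm, quantile(zm, c(0, 1/3, 2/3, 1)),
                      include.lowest = TRUE, labels = FALSE)]
  pm2 <- merge(pm, zmean[, list(zip, tert)], by = "zip")
  tab <- pm2[, list(deaths = sum(event), months = .N), by = tert]
  ch <- suppressWarnings(stats::chisq.test(
    tab$deaths, p = tab$months / sum(tab$months)))
  expect_gt(ch$p.value, 0.001)
  # and the fitted log RR is within 3 SE of null
  fit <- pm_cox(pm)
  b <- unname(fit$coefficients[1])
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(b), 3 * se)
})

test_that("event counts scale linearly with cohort size", {
  d <- vapply(c(2000L, 4000L), function(n) {
    st <- tiny_study(seed = 44, n = n, zips = 10L, months = 36L,
                     hazard = 0.01)
    st$truth$n_deaths
  }, numeric(1))
  ratio <- d[2] / d[1]
  se <- sqrt(1 / d[1] + 1 / d[2]) * 2   # delta method on the log ratio
  expect_lt(abs(log(ratio) - log(2)), 3 * se + 0.05)
})

test_that("doubling the baseline hazard doubles deaths at first order", {
  # small-hazard limit: keep cumulative mortality low so depletion of the
  # risk set stays second-order
  d1 <- tiny_study(seed = 45, n = 20000L, zips = 8L, months = 24L,
                   hazard = 5e-4)$truth$n_deaths
  d2 <- tiny_study(seed = 45, n = 20000L, zips = 8L, months = 24L,
                   hazard = 1e-3)$truth$n_deaths
  expect_lt(abs(d2 / d1 - 2), 0.25)
})

test_that("the truth sidecar round-trips planted parameters", {
  st <- tiny_study(seed = 88, n = 2000L, zips = 12L, months = 48L,
                   hazard = 0.01)
  dir <- file.path(tempdir(), "study-rt")
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$truth$family_rr_per10$CVD, 1.088)
  expect_equal(back$truth$seed, 88)
  expect_equal(back$cohort$entry_month, st$cohort[order(id), entry_month])
  expect_equal(nrow(back$exposures$pm25), nrow(st$exposures$pm25))
  unlink(dir, recursive = TRUE)
})

test_that("ICD codes sample uniformly over a cause's category roots", {
  st <- tiny_study(seed = 46, n = 6000L, zips = 8L, months = 48L,
                   hazard = 0.02)
  ihd <- st$cohort[!is.na(icd10_cause)][
    vapply(classify_cause(icd10_cause), function(s) "IHD" %in% s, TRUE)]
  roots <- icd10_root(ihd$icd10_cause)
  expect_setequal(sort(unique(roots)), paste0("I2", 0:5))
  tab <- table(roots)
  ch <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(ch$p.value, 1e-4)
})
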