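test_that("grid matching equals an exhaustive nearest-point search", {
  set.seed(5)
  cent <- data.table::data.table(zip = sprintf("Z%03d", 1:100),
                                 lat = runif(100, 30, 45),
                                 lon = runif(100, -120, -75))
  grid <- data.table::data.table(grid_id = sprintf("G%04d", 1:1000),
                                 lat = runif(1000, 30, 45),
                                 lon = runif(1000, -120, -75))
  got <- match_to_grid(cent, grid)
  for (i in seq_len(nrow(cent))) {
    d <- haversine_km(cent$lat[i], cent$lon[i], grid$lat, grid$lon)
    expect_identical(got$grid_id[got$zip == cent$zip[i]],
                     grid$grid_id[which.min(d)])
  }
})

test_that("grid matching is deterministic: zero distance and ties", {
  grid <- data.table::data.table(grid_id = c("B", "A"),
                                 lat = c(40, 40), lon = c(-100, -90))
  cent <- data.table::data.table(zip = "Z1", lat = 40, lon = -100)
  expect_identical(match_to_grid(cent, grid)$grid_id, "B")
  # equidistant: lexicographically smaller id wins
  cent2 <- data.table::data.table(zip = "Z2", lat = 40, lon = -95)
  expect_identical(match_to_grid(cent2, grid)$grid_id, "A")
  expect_error(match_to_grid(cent, grid[0]), "empty")
})

test_that("haversine agrees with the spherical law of cosines", {
  set.seed(9)
  la1 <- runif(50, -60, 60); lo1 <- runif(50, -180, 180)
  la2 <- runif(50, -60, 60); lo2 <- runif(50, -180, 180)
  to_rad <- pi / 180
  loc <- 6371.0088 * acos(pmin(1, pmax(-1,
    sin(la1 * to_rad) * sin(la2 * to_rad) +
      cos(la1 * to_rad) * cos(la2 * to_rad) * cos((lo2 - lo1) * to_rad))))
  expect_equal(haversine_km(la1, lo1, la2, lo2), loc, tolerance = 1e-6)
})

test_that("trailing 12-month mean: constants, ramps, linearity", {
  expect_equal(moving_average_12(rep(10, 24))[12:24], rep(10, 13))
  expect_equal(moving_average_12(1:12)[12], 6.5)
  expect_true(all(is.na(moving_average_12(1:24)[1:11])))
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(moving_average_12(2 * x + 3 * y),
               2 * moving_average_12(x) + 3 * moving_average_12(y))
})

test_that("a window crossing a move averages each month's residence", {
  m0 <- ym_to_month("2000-01")
  cohort <- data.table::data.table(
    id = "P1", birth_month = m0 - 70 * 12L, sex = "female", race = "White",
    entry_month = m0 + 11L, end_month = m0 + 23L,
    death_month = NA_integer_, icd10_cause = NA_character_)
  residence <- data.table::data.table(
    id = "P1", start_month = c(m0, m0 + 18L), zip = c("ZA", "ZB"))
  months <- m0 + 0:23
  surface <- rbind(
    data.table::data.table(zip = "ZA", month = months, value = 8),
    data.table::data.table(zip = "ZB", month = months, value = 12))
  expo <- person_exposure_12mo(cohort, residence, surface)
  # at the last month (m0+23), window m0+12..m0+23: 6 months in ZA (8),
  # 6 in ZB (12) -> 10
  expect_equal(expo[month == m0 + 23L, pm25_12mo], 10)
  # before the move the window is all ZA
  expect_equal(expo[month == m0 + 17L, pm25_12mo], 8)
  # one month after the move: 11 months at 8, 1 at 12
  expect_equal(expo[month == m0 + 18L, pm25_12mo], (11 * 8 + 12) / 12)
})

test_that("incomplete windows signal missing exposure", {
  m0 <- ym_to_month("2000-01")
  cohort <- data.table::data.table(
    id = "P1", birth_month = m0 - 70 * 12L, sex = "male", race = "White",
    entry_month = m0 + 5L, end_month = m0 + 10L,
    death_month = NA_integer_, icd10_cause = NA_character_)
  residence <- data.table::data.table(id = "P1", start_month = m0,
                                      zip = "ZA")
  surface <- data.table::data.table(zip = "ZA", month = m0 + 0:10,
                                    value = 10)  # no pre-window history
  expo <- person_exposure_12mo(cohort, residence, surface)
  expect_true(all(is.na(expo$pm25_12mo)))
  pm <- expand_person_months(cohort, residence, expo, cause = "*")
  expect_identical(nrow(pm), 0L)
  expect_identical(attr(pm, "n_dropped_missing"), 6L)
})

test_that("warm-season ozone averages daily 1-h maxima April-September", {
  daily <- data.table::data.table(zip = "Z1", year = 2001L, doy = 91:273,
                                  value = 60)
  expect_equal(warm_season_ozone(daily)$o3_warm, 60)
  alt <- data.table::data.table(zip = "Z1", year = 2001L, doy = 91:273,
                                value = rep(c(40, 60), length.out = 183))
  expect_equal(warm_season_ozone(alt)$o3_warm, mean(alt$value),
               tolerance = 1e-12)
  # more than 25% missing -> NA signal
  sparse <- daily[1:100]
  expect_true(is.na(warm_season_ozone(sparse)$o3_warm))
  empty <- daily[0]
  expect_identical(nrow(warm_season_ozone(empty)), 0L)
})

test_that("low-exposure restriction is strict and nested", {
  zm <- data.table::data.table(zip = c("A", "B", "C"),
                               zip_mean = c(9, 11, 7.5))
  expect_setequal(restrict_low_pm(zm, 10), c("A", "C"))
  expect_false("B" %in% restrict_low_pm(zm, 10))
  r8 <- restrict_low_pm(zm, 8); r10 <- restrict_low_pm(zm, 10)
  r12 <- restrict_low_pm(zm, 12)
  expect_true(all(r8 %in% r10) && all(r10 %in% r12))
})

test_that("monitor subset equals the brute-force all-pairs filter", {
  set.seed(12)
  cent <- data.table::data.table(zip = sprintf("Z%03d", 1:200),
                                 lat = runif(200, 35, 40),
                                 lon = runif(200, -100, -95))
  mon <- data.table::data.table(lat = runif(20, 35, 40),
                                lon = runif(20, -100, -95))
  got <- monitor_subset(cent, mon, radius_miles = 6)
  radius_km <- 6 * 1.609344
  want <- cent$zip[vapply(seq_len(200), function(i)
    min(haversine_km(cent$lat[i], cent$lon[i], mon$lat, mon$lon)) <=
      radius_km, TRUE)]
  expect_setequal(got, want)
  # monitor exactly at a centroid retains that ZIP
  mon2 <- data.table::data.table(lat = cent$lat[1], lon = cent$lon[1])
  expect_true(cent$zip[1] %in% monitor_subset(cent, mon2))
})
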