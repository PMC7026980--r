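# Synthetic Medicare-like study generator.
#
# The generator emulates the structure of a national elderly-cohort
# air-pollution mortality study: an open cohort of beneficiaries aged 65+
# followed monthly over 2000-2008, ZIP-level monthly PM2.5 decomposed into
# a traffic and a non-traffic component, NO2 driven by the traffic
# component with spatial noise calibrated in closed form to a target
# 12-month PM2.5-NO2 correlation, warm-season ozone, annual tracer species
# (an EC-like traffic marker, a sulfate-like secondary marker), ZIP-level
# income with the two missing source years, and cause-specific deaths drawn
# from stratified discrete-time proportional hazards with known planted
# log risk ratios. Everything is seed-deterministic.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 108 months (2000-2008),
#' 74% of beneficiaries in urban ZIP codes, overall mean 12-month PM2.5
#' near 10.3 ug/m3 (sd near 3.1) with urban above non-urban means, a
#' PM2.5-NO2 12-month correlation target of 0.59, a cause mix following the
#' national elderly cause-of-death distribution, and planted risk ratios
#' per 10 ug/m3 at the magnitudes typical of SES-adjusted national
#' estimates (CVD 1.088, respiratory 1.056, cancer 1.025, accidental ~1,
#' other non-accidental 1.051). Any field can be overridden by name.
#'
#' @param ... overrides of the default fields.
#' @return object of class \code{sim_config} (a named list).
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_beneficiaries = 50000L,
    n_zips = 500L,
    urban_fraction = 0.74,
    start_ym = "2000-01",
    n_months = 108L,
    # exposure surface (ug/m3 for PM components; NO2 in ppb)
    mu_nontraffic = c(nonurban = 6.77, urban = 6.87),
    mu_traffic = c(nonurban = 1.40, urban = 4.20),
    sd_nontraffic = 2.1,
    sd_traffic = 1.6,           # lognormal across ZIPs (positive)
    season_amp = 1.5,           # annual cycle, cancels in 12-month means
    ar_phi = 0.4,
    ar_sd_nontraffic = 1.5,     # marginal sd of monthly AR(1) deviations
    ar_sd_traffic = 0.6,
    trend_total = -2.8,         # secular decline over the window (on nt)
    no2_scale = 1.5,            # ppb NO2 per ug/m3 traffic PM2.5
    no2_base = 4,
    target_corr_no2 = 0.59,
    o3_base = 38, o3_nt_coef = 0.8, o3_spatial_sd = 4, o3_daily_sd = 8,
    include_ozone = TRUE,       # daily warm-season series can be skipped
    ec_coef = 0.15, ec_sd = 0.03,
    sulfate_coef = 0.35, sulfate_sd = 0.10,
    income_base = 38000, income_urban_lift = 0.25, income_sdlog = 0.30,
    income_growth = 1.03,
    # cohort
    prevalent_fraction = 0.75,
    entry_age_rate = 0.11,      # truncated-exponential prevalent age mix
    new_entrant_at_65 = 0.80,
    female_fraction = 0.55,
    race_probs = c(White = 0.85, Black = 0.08, Hispanic = 0.03,
                   Asian = 0.02, Other = 0.02),
    move_prob_month = 0.0025,
    # hazards
    base_hazard_65 = 0.0015,    # total monthly hazard at age 65, female
    gompertz_slope = 0.075,     # log-hazard per year of age
    male_mult = 1.5,
    cause_shares = c(IHD = 0.210, CBV = 0.072, CHF = 0.030,
                     OtherCVD = 0.090, COPD = 0.060, Pneumonia = 0.029,
                     OtherResp = 0.023, LungCancer = 0.062,
                     OtherCancer = 0.164, Accidental = 0.024,
                     OtherNonAcc = 0.236),
    family_rr_per10 = c(CVD = 1.088, Respiratory = 1.056, Cancer = 1.025,
                        Accidental = 0.998, Other = 1.051),
    uniform_rr_per10 = NULL,    # overrides every family when set
    race_rr_mult = c(White = 1, Black = 1, Hispanic = 1, Asian = 1,
                     Other = 1),               # multiplies RR per 10
    slope_change = NULL,        # list(at=, ratio=): piecewise log-hazard
    beta_traffic_split = NULL   # list(rr_nontraffic=, rr_traffic=)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$urban_fraction >= 0, cfg$urban_fraction <= 1,
            abs(sum(cfg$cause_shares) - 1) < 1e-8,
            cfg$prevalent_fraction >= 0, cfg$prevalent_fraction <= 1)
  structure(cfg, class = "sim_config")
}

# family of each fine simulated cause
.cause_family <- c(IHD = "CVD", CBV = "CVD", CHF = "CVD", OtherCVD = "CVD",
                   COPD = "Respiratory", Pneumonia = "Respiratory",
                   OtherResp = "Respiratory", LungCancer = "Cancer",
                   OtherCancer = "Cancer", Accidental = "Accidental",
                   OtherNonAcc = "Other")

# ICD-10 roots each fine cause samples from
fine_cause_roots <- function() {
  map <- default_cause_map()
  all_cvd <- cause_roots("All CVD", map)
  all_resp <- cause_roots("All respiratory", map)
  all_ca <- cause_roots("All cancer", map)
  nonacc <- cause_roots("Non-accidental", map)
  list(
    IHD = cause_roots("IHD", map),
    CBV = cause_roots("CBV", map),
    CHF = cause_roots("CHF", map),
    OtherCVD = setdiff(all_cvd, c(cause_roots("IHD", map),
                                  cause_roots("CBV", map),
                                  cause_roots("CHF", map))),
    COPD = cause_roots("COPD", map),
    Pneumonia = cause_roots("Pneumonia", map),
    OtherResp = setdiff(all_resp, c(cause_roots("COPD", map),
                                    cause_roots("Pneumonia", map))),
    LungCancer = cause_roots("Lung cancer", map),
    OtherCancer = setdiff(all_ca, cause_roots("Lung cancer", map)),
    Accidental = cause_roots("Accidental", map),
    OtherNonAcc = setdiff(nonacc, c(all_cvd, all_resp, all_ca))
  )
}

# variance factor of a 12-month mean of an AR(1) with unit marginal variance
ar12_factor <- function(phi) {
  k <- 1:11
  (12 + 2 * sum((12 - k) * phi^k)) / 144
}

# Closed-form variance accounting for the NO2 spatial-noise calibration.
# Returns the spatial noise variance (in traffic-PM units) that makes the
# analytic corr(12-mo PM2.5, 12-mo NO2) hit the target; errors if the
# target exceeds the attainable maximum given the configured components.
calibrate_no2_noise <- function(cfg) {
  p <- cfg$urban_fraction
  d_nt <- cfg$mu_nontraffic[["urban"]] - cfg$mu_nontraffic[["nonurban"]]
  d_tr <- cfg$mu_traffic[["urban"]] - cfg$mu_traffic[["nonurban"]]
  d_pm <- d_nt + d_tr
  f12 <- ar12_factor(cfg$ar_phi)
  ar_nt <- cfg$ar_sd_nontraffic^2 * f12
  ar_tr <- cfg$ar_sd_traffic^2 * f12
  n <- cfg$n_months
  trend_var <- (cfg$trend_total / (n - 1))^2 * (n^2 - 1) / 12
  var_pm <- p * (1 - p) * d_pm^2 + cfg$sd_nontraffic^2 +
    cfg$sd_traffic^2 + ar_nt + ar_tr + trend_var
  var_tr <- p * (1 - p) * d_tr^2 + cfg$sd_traffic^2 + ar_tr
  cov_pm_tr <- p * (1 - p) * d_pm * d_tr + cfg$sd_traffic^2 + ar_tr
  r <- cfg$target_corr_no2
  r_max <- cov_pm_tr / sqrt(var_pm * var_tr)
  if (r >= r_max) {
    stop(sprintf(
      "correlation target %.3f unattainable: maximum %.3f given the %s",
      r, r_max, "configured exposure components"))
  }
  var_e <- (cov_pm_tr / (r * sqrt(var_pm)))^2 - var_tr
  list(var_noise = var_e, var_pm12 = var_pm, var_tr12 = var_tr,
       cov_pm_tr = cov_pm_tr, corr_max = r_max,
       mean_pm = p * (cfg$mu_nontraffic[["urban"]] +
                        cfg$mu_traffic[["urban"]]) +
         (1 - p) * (cfg$mu_nontraffic[["nonurban"]] +
                      cfg$mu_traffic[["nonurban"]]))
}

#' Simulate exposure surfaces and tracers
#'
#' Per-ZIP monthly PM2.5 as non-traffic + traffic components (spatial
#' means by urbanicity, a seasonal cycle that cancels in 12-month means, a
#' linear secular decline and AR(1) month-to-month noise), NO2 proportional
#' to the traffic component plus spatial noise calibrated so the analytic
#' 12-month PM2.5-NO2 correlation equals the target, warm-season daily
#' ozone, annual EC-like and sulfate-like tracers, and ZIP-level annual
#' income with the 2000 and 2003 source years absent. The surfaces start
#' 11 months before the study window so every at-risk month has a complete
#' 12-month exposure window.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return list: zips (zip, urban, lat, lon), pm25 / pm25_traffic /
#'   pm25_nontraffic / no2 (long zip-month tables), o3_daily, tracers,
#'   income, calibration (the closed-form accounting).
#' @export
simulate_exposures <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nz <- cfg$n_zips
  start <- ym_to_month(cfg$start_ym)
  months <- seq.int(start - 11L, start + cfg$n_months - 1L)
  nt_tot <- length(months)
  cal <- calibrate_no2_noise(cfg)

  zips <- data.table(
    zip = sprintf("Z%04d", seq_len(nz)),
    urban = runif(nz) < cfg$urban_fraction,
    lat = runif(nz, 30, 45),
    lon = runif(nz, -120, -75))

  mu_nt <- ifelse(zips$urban, cfg$mu_nontraffic[["urban"]],
                  cfg$mu_nontraffic[["nonurban"]])
  mu_tr <- ifelse(zips$urban, cfg$mu_traffic[["urban"]],
                  cfg$mu_traffic[["nonurban"]])
  nt_z <- rnorm(nz, mu_nt, cfg$sd_nontraffic)
  # lognormal traffic field matched to the configured mean and variance
  sdl2 <- log(1 + cfg$sd_traffic^2 / mu_tr^2)
  tr_z <- exp(rnorm(nz, log(mu_tr) - sdl2 / 2, sqrt(sdl2)))

  moy <- month_of_year(months)
  season <- cfg$season_amp * cos(2 * pi * (moy - 1) / 12)
  # linear trend indexed on analysis months (1..n); pre-window months
  # extrapolate the same line
  tidx <- months - start + 1L
  trend <- cfg$trend_total * (tidx - (cfg$n_months + 1) / 2) /
    (cfg$n_months - 1)

  ar_mat <- function(sd_marg) {
    innov_sd <- sd_marg * sqrt(1 - cfg$ar_phi^2)
    e <- matrix(0, nz, nt_tot)
    e[, 1L] <- rnorm(nz, 0, sd_marg)
    for (t in 2:nt_tot) {
      e[, t] <- cfg$ar_phi * e[, t - 1L] + rnorm(nz, 0, innov_sd)
    }
    e
  }
  e_nt <- ar_mat(cfg$ar_sd_nontraffic)
  e_tr <- ar_mat(cfg$ar_sd_traffic)

  nt_mat <- outer(nt_z, rep(1, nt_tot)) +
    outer(rep(1, nz), season + trend) + e_nt
  tr_mat <- outer(tr_z, rep(1, nt_tot)) + e_tr
  tr_mat <- pmax(tr_mat, 0)
  pm_mat <- pmax(nt_mat + tr_mat, 0.1)
  nt_mat <- pm_mat - tr_mat

  no2_noise <- rnorm(nz, 0, sqrt(cal$var_noise))
  no2_mat <- cfg$no2_base + cfg$no2_scale * (tr_mat + no2_noise)
  no2_mat <- pmax(no2_mat, 0.1)

  long <- function(mat) {
    data.table(zip = rep(zips$zip, times = nt_tot),
               month = rep(months, each = nz),
               value = as.vector(mat))
  }

  years <- sort(unique(month_year(seq.int(start, start + cfg$n_months - 1L))))
  # annual component means on analysis months, for tracers
  in_window <- months >= start
  yr_of <- month_year(months[in_window])
  tr_ann <- t(apply(tr_mat[, in_window, drop = FALSE], 1L,
                    function(v) tapply(v, yr_of, mean)))
  nt_ann <- t(apply(nt_mat[, in_window, drop = FALSE], 1L,
                    function(v) tapply(v, yr_of, mean)))
  tracers <- rbind(
    data.table(zip = rep(zips$zip, times = length(years)),
               year = rep(years, each = nz), species = "EC",
               value = pmax(cfg$ec_coef * as.vector(tr_ann) +
                              rnorm(nz * length(years), 0, cfg$ec_sd), 0)),
    data.table(zip = rep(zips$zip, times = length(years)),
               year = rep(years, each = nz), species = "sulfate",
               value = pmax(cfg$sulfate_coef * as.vector(nt_ann) +
                              rnorm(nz * length(years), 0, cfg$sulfate_sd),
                            0)))

  # warm-season daily 1-h max ozone
  o3_daily <- NULL
  if (isTRUE(cfg$include_ozone)) {
    o3_mean_z <- cfg$o3_base + cfg$o3_nt_coef * nt_z +
      rnorm(nz, 0, cfg$o3_spatial_sd)
    warm_doy <- 91:273    # April 1 - September 30, non-leap convention
    nd <- length(warm_doy)
    o3_daily <- data.table(
      zip = rep(rep(zips$zip, times = length(years)), each = nd),
      year = rep(rep(years, each = nz), each = nd),
      doy = rep(warm_doy, times = nz * length(years)),
      value = pmax(rep(rep(o3_mean_z, times = length(years)), each = nd) +
                     rnorm(nz * length(years) * nd, 0, cfg$o3_daily_sd),
                   0))
  }

  inc_years <- setdiff(years, c(2000L, 2003L))
  base_inc <- cfg$income_base *
    exp(rnorm(nz, cfg$income_urban_lift * zips$urban, cfg$income_sdlog))
  income <- data.table(
    zip = rep(zips$zip, times = length(inc_years)),
    year = rep(inc_years, each = nz),
    income = as.vector(outer(base_inc,
                             cfg$income_growth^(inc_years - 2000L))))

  list(zips = zips, pm25 = long(pm_mat), pm25_traffic = long(tr_mat),
       pm25_nontraffic = long(nt_mat), no2 = long(no2_mat),
       o3_daily = o3_daily, tracers = tracers, income = income,
       calibration = cal)
}

# per-family log RR per ug/m3, after any uniform override
family_beta <- function(cfg) {
  rr <- cfg$family_rr_per10
  if (!is.null(cfg$uniform_rr_per10)) {
    rr[] <- cfg$uniform_rr_per10
  }
  log(rr) / 10
}

#' Simulate an open cohort with cause-specific deaths
#'
#' Beneficiaries are assigned a ZIP (urban share as configured),
#' demographics and a staggered entry month; each month at risk the total
#' death hazard is baseline(age, sex) times the cause-share-weighted mean
#' of exp(planted log-RR x 12-month exposure), a Bernoulli death draw ends
#' follow-up, and the fine cause is sampled proportionally to its hazard,
#' with an ICD-10 root drawn uniformly from the cause's ranges. Exposure
#' follows the beneficiary across residential moves exactly as the analysis
#' computes it (trailing 12-month mean over the then-current residence).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param exposures output of \code{\link{simulate_exposures}}.
#' @param seed integer seed, or NULL.
#' @return list: cohort, residence, truth (planted parameters).
#' @export
simulate_cohort <- function(cfg, exposures, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_beneficiaries
  nz <- cfg$n_zips
  start <- ym_to_month(cfg$start_ym)
  n_months <- cfg$n_months
  zips <- exposures$zips

  # wide matrices zip x month for fast lookup
  months_all <- sort(unique(exposures$pm25$month))
  to_mat <- function(dt) {
    m <- matrix(NA_real_, nz, length(months_all),
                dimnames = list(zips$zip, NULL))
    m[cbind(match(dt$zip, zips$zip), match(dt$month, months_all))] <- dt$value
    m
  }
  pm_mat <- to_mat(exposures$pm25)
  split_haz <- !is.null(cfg$beta_traffic_split)
  if (split_haz) {
    tr_mat <- to_mat(exposures$pm25_traffic)
    nt_mat <- to_mat(exposures$pm25_nontraffic)
  }
  col_of <- function(cal_month) match(cal_month, months_all)

  # demographics and entry
  w_zip <- ifelse(zips$urban, cfg$urban_fraction / max(1, sum(zips$urban)),
                  (1 - cfg$urban_fraction) / max(1, sum(!zips$urban)))
  zip_idx <- sample.int(nz, n, replace = TRUE, prob = w_zip)
  sex <- ifelse(runif(n) < cfg$female_fraction, "female", "male")
  race <- sample(names(cfg$race_probs), n, replace = TRUE,
                 prob = cfg$race_probs)
  prevalent <- runif(n) < cfg$prevalent_fraction
  entry_t <- ifelse(prevalent, 1L,
                    sample.int(n_months - 1L, n, replace = TRUE) + 1L)
  age_years <- numeric(n)
  age_years[prevalent] <- 65 + pmin(rexp(sum(prevalent),
                                         cfg$entry_age_rate), 30)
  at65 <- !prevalent & runif(n) < cfg$new_entrant_at_65
  age_years[at65] <- 65
  late_other <- !prevalent & !at65
  age_years[late_other] <- 65 + pmin(rexp(sum(late_other),
                                          cfg$entry_age_rate), 25)
  age_months_entry <- floor(age_years * 12) + sample.int(12L, n, TRUE) - 1L
  entry_month <- start + entry_t - 1L
  birth_month <- entry_month - age_months_entry

  # hazards are family-level (all fine causes of a family share one
  # planted log RR); the fine cause is drawn within family afterwards,
  # which is exactly equivalent and far cheaper
  beta_fam <- family_beta(cfg)
  shares <- cfg$cause_shares
  fine <- names(shares)
  fam_of <- .cause_family[fine]
  fams <- names(beta_fam)
  share_fam <- vapply(fams, function(f) sum(shares[fam_of == f]),
                      numeric(1L))
  race_add <- log(cfg$race_rr_mult[race]) / 10    # per-person additive

  sex_f <- ifelse(sex == "male", cfg$male_mult, 1)
  alive <- rep(TRUE, n)
  death_t <- rep(NA_integer_, n)
  death_cause <- rep(NA_character_, n)
  cur_zip <- zip_idx
  buf <- matrix(NA_real_, n, 12L)      # trailing 12 months of raw PM2.5
  if (split_haz) {
    buf_tr <- matrix(NA_real_, n, 12L)
    b_nt <- log(cfg$beta_traffic_split$rr_nontraffic) / 10
    b_tr <- log(cfg$beta_traffic_split$rr_traffic) / 10
  }
  moves <- vector("list", n_months)

  # circular 12-month buffer with a running sum: O(n) per month
  run_sum <- numeric(n)
  if (split_haz) run_sum_tr <- numeric(n)
  ptr <- 0L
  for (t in seq_len(n_months)) {
    cal <- start + t - 1L
    ptr <- ptr %% 12L + 1L
    entrants <- which(entry_t == t)
    if (length(entrants)) {
      # place months cal-11..cal so the circular pointer overwrites the
      # oldest month on the next update
      pos <- ((ptr + 0:11) %% 12L) + 1L
      cols <- col_of(seq.int(cal - 11L, cal))
      buf[entrants, pos] <- pm_mat[cur_zip[entrants], cols, drop = FALSE]
      run_sum[entrants] <- rowSums(buf[entrants, , drop = FALSE])
      if (split_haz) {
        buf_tr[entrants, pos] <- tr_mat[cur_zip[entrants], cols,
                                        drop = FALSE]
        run_sum_tr[entrants] <- rowSums(buf_tr[entrants, , drop = FALSE])
      }
    }
    act <- which(alive & entry_t <= t)
    if (!length(act)) next
    # residential moves take effect this month, before exposure accrues;
    # fresh entrants stay put in their entry month
    movable <- setdiff(act, entrants)
    mv <- movable[runif(length(movable)) < cfg$move_prob_month]
    if (length(mv)) {
      cur_zip[mv] <- sample.int(nz, length(mv), replace = TRUE)
      moves[[t]] <- data.table(idx = mv, month = cal, zip_i = cur_zip[mv])
    }
    if (t > 1L) {     # entrants this month already hold the full window
      stale <- setdiff(act, entrants)
      if (length(stale)) {
        newv <- pm_mat[cbind(cur_zip[stale], col_of(cal))]
        run_sum[stale] <- run_sum[stale] - buf[cbind(stale, ptr)] + newv
        buf[cbind(stale, ptr)] <- newv
        if (split_haz) {
          newt <- tr_mat[cbind(cur_zip[stale], col_of(cal))]
          run_sum_tr[stale] <- run_sum_tr[stale] -
            buf_tr[cbind(stale, ptr)] + newt
          buf_tr[cbind(stale, ptr)] <- newt
        }
      }
    }
    x12 <- run_sum[act] / 12
    # baseline hazards are per-stratum: the Gompertz term uses the one-year
    # age bin (pooled at 90+), so the stratified proportional-hazards model
    # fitted downstream is exactly the generating model
    age_bin <- pmin((cal - birth_month[act]) %/% 12L, 90L)
    base <- cfg$base_hazard_65 * exp(cfg$gompertz_slope * (age_bin - 65)) *
      sex_f[act]
    if (split_haz) {
      # one (non-traffic, traffic) slope pair shared by every cause
      tr12 <- run_sum_tr[act] / 12
      lin <- b_nt * (x12 - tr12) + b_tr * tr12
      H <- matrix(exp(lin), length(act), length(fams))
    } else if (!is.null(cfg$slope_change)) {
      at <- cfg$slope_change$at
      ratio <- cfg$slope_change$ratio
      xx <- pmin(x12, at) + ratio * pmax(x12 - at, 0)
      H <- exp(outer(xx, beta_fam) + race_add[act] * xx)
    } else {
      H <- exp(outer(x12, beta_fam) + race_add[act] * x12)
    }
    hz <- H %*% share_fam               # share-weighted relative hazard
    p_die <- 1 - exp(-base * as.vector(hz))
    u <- runif(length(act))
    dd <- which(u < p_die)
    if (length(dd)) {
      # family proportional to share_fam * exp(beta_fam x), then the fine
      # cause within family proportional to its share (exposure-free)
      W <- H[dd, , drop = FALSE] *
        matrix(share_fam, length(dd), length(fams), byrow = TRUE)
      cs <- W / rowSums(W)
      pickf <- max.col(matrix(runif(length(dd)), length(dd),
                              length(fams)) <
                         t(apply(cs, 1L, cumsum)), ties.method = "first")
      ii <- act[dd]
      fine_pick <- vapply(pickf, function(k) {
        cand <- fine[fam_of == fams[k]]
        if (length(cand) == 1L) cand else
          sample(cand, 1L, prob = shares[cand])
      }, character(1L))
      alive[ii] <- FALSE
      death_t[ii] <- t
      death_cause[ii] <- fine_pick
    }
  }

  roots <- fine_cause_roots()
  icd <- rep(NA_character_, n)
  dead <- which(!is.na(death_cause))
  if (length(dead)) {
    for (f in unique(death_cause[dead])) {
      sel <- dead[death_cause[dead] == f]
      icd[sel] <- sample(roots[[f]], length(sel), replace = TRUE)
    }
  }

  end_t <- ifelse(is.na(death_t), n_months, death_t)
  ids <- sprintf("B%06d", seq_len(n))
  cohort <- data.table(
    id = ids, birth_month = birth_month, sex = sex, race = race,
    entry_month = entry_month,
    end_month = start + end_t - 1L,
    death_month = ifelse(is.na(death_t), NA_integer_,
                         start + as.integer(death_t) - 1L),
    icd10_cause = icd)
  res0 <- data.table(id = ids, start_month = entry_month,
                     zip = zips$zip[zip_idx])
  mv_all <- rbindlist(moves[!vapply(moves, is.null, TRUE)])
  if (nrow(mv_all)) {
    res_mv <- data.table(id = ids[mv_all$idx], start_month = mv_all$month,
                         zip = zips$zip[mv_all$zip_i])
    residence <- rbind(res0, res_mv)
  } else {
    residence <- res0
  }
  setorder(residence, id, start_month)

  truth <- list(
    seed = seed,
    family_rr_per10 = as.list(exp(10 * family_beta(cfg))),
    race_rr_mult = as.list(cfg$race_rr_mult),
    slope_change = cfg$slope_change,
    beta_traffic_split = cfg$beta_traffic_split,
    base_hazard_65 = cfg$base_hazard_65,
    n_deaths = length(dead))
  list(cohort = cohort, residence = residence, truth = truth)
}

#' Simulate a full synthetic study
#'
#' Exposures plus cohort plus ZIP attributes, with a single seed governing
#' everything. The planted parameters travel in the \code{truth} element
#' (and in the sidecar file written by \code{\link{write_study}}); recovery
#' tests read truth only from there.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return list: cohort, residence, zips, exposures (the
#'   \code{\link{simulate_exposures}} output), ses, truth.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  expo <- simulate_exposures(cfg, seed = NULL)
  coh <- simulate_cohort(cfg, expo, seed = NULL)
  # SES tertiles need at least three ZIP codes; tiny worlds have none
  ses <- if (cfg$n_zips >= 3L) ses_by_year(expo$income) else NULL
  truth <- coh$truth
  truth$seed <- seed
  list(cohort = coh$cohort, residence = coh$residence, zips = expo$zips,
       exposures = expo, ses = ses, truth = truth)
}
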