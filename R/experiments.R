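# Seed-replicated simulation experiments: the package's own calibration
# evidence. Each replicate simulates a fresh study, runs the full pipeline
# (exposure composition, expansion, aggregation, fit) and compares the
# estimate against the planted truth read from the generator's sidecar.

#' Parameter-recovery (coverage) experiment
#'
#' Simulates \code{n_reps} independent cohorts under the configured study
#' conditions, fits the stratified Cox model per modeled cause through the
#' standard pipeline, and reports per-replicate estimates with their Wald
#' intervals against the planted truth. Causes must be aggregates of a
#' single planted cause family (or "*" under a uniform planted risk ratio)
#' so the truth is a well-defined proportional-hazards parameter.
#'
#' @param n_reps number of seed replicates.
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @param causes modeled causes (labels of the cause map, or "*").
#' @param cfg a \code{\link{sim_config}}.
#' @param ses_mode passed to \code{\link{pm_cox}}.
#' @return \code{data.table}: rep, cause, truth_rr, rr, lo95, hi95,
#'   beta_hat, se, covered, n_events.
#' @export
coverage_experiment <- function(n_reps = 100L, seed = 1L,
                                causes = c("All CVD", "All cancer"),
                                cfg = sim_config(include_ozone = FALSE),
                                ses_mode = "none") {
  fam_for_cause <- c("All CVD" = "CVD", "IHD" = "CVD", "CBV" = "CVD",
                     "CHF" = "CVD", "All respiratory" = "Respiratory",
                     "COPD" = "Respiratory", "Pneumonia" = "Respiratory",
                     "All cancer" = "Cancer", "Lung cancer" = "Cancer",
                     "Accidental" = "Accidental")
  rows <- vector("list", n_reps * length(causes))
  k <- 0L
  for (r in seq_len(n_reps)) {
    st <- simulate_study(cfg, seed = seed + r)
    expo <- person_exposure_12mo(st$cohort, st$residence,
                                 st$exposures$pm25)
    pm <- expand_person_months(st$cohort, st$residence, expo,
                               cause = causes[1L],
                               ses = if (ses_mode == "none") NULL else
                                 st$ses)
    for (cause in causes) {
      set_event_cause(pm, cause)
      truth_rr <- if (identical(cause, "*")) {
        stopifnot(!is.null(st$truth$family_rr_per10))
        u <- unique(unlist(st$truth$family_rr_per10))
        stopifnot(length(u) == 1L)   # requires a uniform planted RR
        u
      } else {
        st$truth$family_rr_per10[[fam_for_cause[[cause]]]]
      }
      fit <- pm_cox(pm, ses_mode = ses_mode)
      rr <- rr_per_10(fit)
      k <- k + 1L
      rows[[k]] <- data.table(
        rep = r, cause = cause, truth_rr = truth_rr,
        rr = rr[["rr"]], lo95 = rr[["lo95"]], hi95 = rr[["hi95"]],
        beta_hat = unname(fit$coefficients[1L]),
        se = sqrt(fit$vcov[1L, 1L]),
        covered = rr[["lo95"]] <= truth_rr & truth_rr <= rr[["hi95"]],
        n_events = as.integer(fit$n_events))
    }
  }
  rbindlist(rows)
}

#' Summarise a coverage experiment
#'
#' Per cause: coverage count, mean estimate, Monte-Carlo bias of the mean
#' log-RR slope against the planted value, and its Monte-Carlo standard
#' error.
#'
#' @param res output of \code{\link{coverage_experiment}}.
#' @return \code{data.table} keyed by cause.
#' @export
summarise_coverage <- function(res) {
  res[, list(
    n_reps = .N,
    n_covered = sum(covered),
    coverage = mean(covered),
    mean_rr = exp(mean(log(rr))),
    truth_rr = truth_rr[1L],
    bias_beta = mean(beta_hat) - log(truth_rr[1L]) / 10,
    mc_se_beta = sd(beta_hat) / sqrt(.N),
    mean_events = mean(n_events)
  ), by = cause]
}

#' Type-I error of the spline nonlinearity test under linear truth
#'
#' Simulates small cohorts whose planted log hazard is exactly linear in
#' exposure, fits the 3-knot restricted cubic spline, and applies the Wald
#' test of the nonlinear coefficient at the 5% level.
#'
#' @param n_reps replicates.
#' @param seed base seed.
#' @param cfg simulation configuration for the replicate worlds.
#' @return \code{data.table}: rep, p, significant.
#' @export
spline_type1_experiment <- function(n_reps = 100L, seed = 1L,
                                    cfg = sim_config(
                                      n_beneficiaries = 2000L,
                                      n_zips = 8L, n_months = 36L,
                                      base_hazard_65 = 0.012,
                                      uniform_rr_per10 = 1.5)) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    st <- simulate_study(cfg, seed = seed + r)
    expo <- person_exposure_12mo(st$cohort, st$residence,
                                 st$exposures$pm25)
    pm <- expand_person_months(st$cohort, st$residence, expo, cause = "*")
    p <- tryCatch({
      f <- fit_spline_model(pm, m = 3L)
      if (!f$converged) NA_real_ else nonlinearity_test(f)[["p"]]
    }, error = function(e) NA_real_)
    rows[[r]] <- data.table(rep = r, p = p,
                            significant = !is.na(p) & p < 0.05)
  }
  rbindlist(rows)
}

#' Recovery of a planted slope change
#'
#' Simulates cohorts whose planted log hazard changes slope at a stated
#' exposure, fits the 3-knot spline, and estimates the below/above slope
#' ratio from chord slopes of the fitted log-RR curve.
#'
#' @param n_reps replicates.
#' @param seed base seed.
#' @param at change point (ug/m3).
#' @param ratio planted above/below slope ratio.
#' @param cfg simulation configuration (the slope change is planted on top).
#' @return \code{data.table}: rep, slope_below, slope_above, ratio_hat.
#' @export
slope_change_experiment <- function(n_reps = 20L, seed = 1L, at = 10,
                                    ratio = 0.4,
                                    cfg = sim_config(
                                      n_beneficiaries = 20000L,
                                      n_zips = 10L, n_months = 84L,
                                      base_hazard_65 = 0.006,
                                      ar_sd_nontraffic = 2.5,
                                      trend_total = -5,
                                      uniform_rr_per10 = 2.0)) {
  cfg$slope_change <- list(at = at, ratio = ratio)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    st <- simulate_study(cfg, seed = seed + r)
    expo <- person_exposure_12mo(st$cohort, st$residence,
                                 st$exposures$pm25)
    pm <- expand_person_months(st$cohort, st$residence, expo, cause = "*")
    f <- fit_spline_model(pm, knots = c(at - 3, at, at + 3))
    # chord slopes on the spline's linear tails, clear of the curvature
    # region between the boundary knots
    grid <- c(at - 8, at - 5, at + 5, at + 8)
    cur <- rr_curve(f, grid)
    lrr <- log(cur$rr)
    s_below <- (lrr[2] - lrr[1]) / 3
    s_above <- (lrr[4] - lrr[3]) / 3
    rows[[r]] <- data.table(rep = r, slope_below = s_below,
                            slope_above = s_above,
                            ratio_hat = s_above / s_below)
  }
  rbindlist(rows)
}

#' Attenuation of the two-stage estimate toward the non-traffic effect
#'
#' Simulates worlds whose hazard separates the traffic and non-traffic
#' PM2.5 components, with the traffic slope growing across settings, and
#' fits both the total-PM2.5 model and the second-stage residual-exposure
#' model.
#'
#' With ZIP codes in the strata, the traffic slope is identified by the
#' traffic component's within-ZIP (temporal) variation, so the experiment's
#' world gives the traffic component month-to-month variability comparable
#' to the secondary component's. Several replicates per setting average out
#' Monte-Carlo noise in the fitted slopes.
#'
#' @param rr_traffic vector of planted traffic RRs per 10 ug/m3.
#' @param rr_nontraffic planted non-traffic RR per 10 ug/m3.
#' @param seed base seed.
#' @param n_reps replicates per traffic-effect setting.
#' @param cfg base simulation configuration.
#' @return \code{data.table}: rr_traffic, beta_total, se_total,
#'   beta_resid, se_resid (Monte-Carlo means and standard errors of the
#'   means), beta_nontraffic_true.
#' @export
attenuation_experiment <- function(rr_traffic = c(1.0, 1.6, 2.4),
                                   rr_nontraffic = 1.05, seed = 1L,
                                   n_reps = 3L,
                                   cfg = sim_config(
                                     n_beneficiaries = 30000L,
                                     n_zips = 20L, n_months = 84L,
                                     base_hazard_65 = 0.008,
                                     ar_sd_traffic = 1.5)) {
  rows <- vector("list", length(rr_traffic))
  for (i in seq_along(rr_traffic)) {
    cfg$beta_traffic_split <- list(rr_nontraffic = rr_nontraffic,
                                   rr_traffic = rr_traffic[i])
    bt <- numeric(n_reps); br <- numeric(n_reps)
    vt <- numeric(n_reps); vr <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      st <- simulate_study(cfg, seed = seed + 100L * r)
      expo <- person_exposure_12mo(st$cohort, st$residence,
                                   st$exposures$pm25)
      pm <- expand_person_months(st$cohort, st$residence, expo,
                                 cause = "*")
      zm <- merge(zip_exposure_12mo(st$exposures$pm25, "pm25_12mo"),
                  zip_exposure_12mo(st$exposures$no2, "no2_12mo"),
                  by = c("zip", "month"))
      rm_model <- fit_residual_model(zm[complete.cases(zm)])
      pm2 <- merge(pm, rm_model$residuals, by = c("zip", "month"))
      f_tot <- pm_cox(pm, exposure = "pm25_12mo")
      f_res <- pm_cox(pm2, exposure = "resid_pm25")
      bt[r] <- unname(f_tot$coefficients[1L])
      br[r] <- unname(f_res$coefficients[1L])
      vt[r] <- f_tot$vcov[1L, 1L]
      vr[r] <- f_res$vcov[1L, 1L]
    }
    rows[[i]] <- data.table(
      rr_traffic = rr_traffic[i],
      beta_total = mean(bt),
      se_total = sqrt(mean(vt) / n_reps),
      beta_resid = mean(br),
      se_resid = sqrt(mean(vr) / n_reps),
      beta_nontraffic_true = log(rr_nontraffic) / 10)
  }
  rbindlist(rows)
}
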