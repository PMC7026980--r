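# Study IO and the configuration-driven analysis pipeline.

#' Write / read a synthetic study as delimited text
#'
#' Emits the exact formats the pipeline consumes: cohort.csv (months as ISO
#' "YYYY-MM"), residence.csv, one long CSV per pollutant surface,
#' zip_attributes.csv, income.csv, tracers.csv, o3_daily.csv, and a
#' truth.yaml sidecar carrying every planted parameter and the seed.
#'
#' @param study output of \code{\link{simulate_study}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(dt, name) {
    fwrite(dt, file.path(dir, name))
  }
  co <- copy(as.data.table(study$cohort))
  co[, birth_month := month_to_ym(birth_month)]
  co[, entry_month := month_to_ym(entry_month)]
  co[, end_month := month_to_ym(end_month)]
  co[, death_month := ifelse(is.na(death_month), "",
                             month_to_ym(death_month))]
  wr(co, "cohort.csv")
  re <- copy(as.data.table(study$residence))
  re[, start_month := month_to_ym(start_month)]
  wr(re, "residence.csv")
  for (p in c("pm25", "no2")) {
    su <- copy(study$exposures[[p]])
    su[, month := month_to_ym(month)]
    wr(su, paste0(p, ".csv"))
  }
  wr(study$zips, "zip_attributes.csv")
  wr(study$exposures$income, "income.csv")
  wr(study$exposures$tracers, "tracers.csv")
  if (!is.null(study$exposures$o3_daily)) {
    wr(study$exposures$o3_daily, "o3_daily.csv")
  }
  yaml::write_yaml(study$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  rd <- function(name) fread(file.path(dir, name))
  co <- rd("cohort.csv")
  co[, birth_month := ym_to_month(birth_month)]
  co[, entry_month := ym_to_month(entry_month)]
  co[, end_month := ym_to_month(end_month)]
  dm <- rep(NA_integer_, nrow(co))
  has_dm <- !is.na(co$death_month) & co$death_month != ""
  dm[has_dm] <- ym_to_month(co$death_month[has_dm])
  co[, death_month := dm]
  co[, icd10_cause := ifelse(is.na(icd10_cause) | icd10_cause == "",
                             NA_character_, icd10_cause)]
  re <- rd("residence.csv")
  re[, start_month := ym_to_month(start_month)]
  surf <- function(name) {
    s <- rd(name)
    s[, month := ym_to_month(month)]
    s
  }
  list(cohort = co, residence = re, zips = rd("zip_attributes.csv"),
       exposures = list(pm25 = surf("pm25.csv"), no2 = surf("no2.csv"),
                        income = rd("income.csv"),
                        tracers = rd("tracers.csv"),
                        o3_daily = if (file.exists(file.path(
                          dir, "o3_daily.csv"))) rd("o3_daily.csv")),
       truth = if (file.exists(file.path(dir, "truth.yaml")))
         yaml::read_yaml(file.path(dir, "truth.yaml")) else NULL)
}

#' ZIP-month trailing 12-month exposure averages
#'
#' @param surface long table (zip, month, value) of monthly means.
#' @param col output column name.
#' @return \code{data.table} (zip, month, <col>), NA for incomplete windows.
#' @export
zip_exposure_12mo <- function(surface, col = "pm25_12mo") {
  su <- as.data.table(surface)
  setnames(su, names(su)[1:3], c("zip", "month", "value"))
  setorder(su, zip, month)
  su[, (col) := frollmean(value, 12L, align = "right"), by = zip]
  su[, c("zip", "month", col), with = FALSE]
}

#' Validate pipeline inputs
#'
#' Schema, coverage and invariant checks on the cohort, residence and
#' exposure tables. Errors (structural violations naming the beneficiary)
#' block the analysis; warnings (person-months whose 12-month exposure
#' window is incomplete) are counted — those person-months leave the risk
#' sets.
#'
#' @param cohort,residence cohort tables (encoded months).
#' @param pm25 long exposure surface (zip, month, value).
#' @return list: errors (data.table), n_missing_exposure (count),
#'   ok (logical).
#' @export
validate_inputs <- function(cohort, residence, pm25) {
  errors <- validate_cohort(cohort, residence)
  expo <- person_exposure_12mo(cohort, residence, pm25)
  n_missing <- sum(is.na(expo$pm25_12mo))
  list(errors = errors, n_missing_exposure = n_missing,
       ok = nrow(errors) == 0L)
}

# order-stable djb2-style hash of a serialized object, for stamping
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 5381
  for (b in as.integer(bytes[seq(1, length(bytes),
                                 by = max(1L, length(bytes) %/% 4096L))])) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis matrix
#'
#' Configuration-driven orchestration: expansion, aggregation and fits for
#' every requested cell of (cause) x (base / SES-adjusted / ozone-adjusted)
#' x (total / non-traffic exposure), optional spline exposure-response
#' curves, subgroup effect modification, and low-exposure ZIP restrictions.
#' Every artifact is stamped with the config hash and seed; a
#' machine-readable summary indexes the fits. A failing matrix cell is
#' recorded in the summary and does not abort the others.
#'
#' @param config nested list (or path to a YAML file): fields
#'   \code{simulate} (list of \code{\link{sim_config}} overrides plus
#'   \code{seed}) or \code{input_dir} (a directory from
#'   \code{\link{write_study}}); \code{causes}; \code{variants} (subset of
#'   "base", "ses", "ozone"); \code{exposure_types} (subset of "total",
#'   "nontraffic"); \code{spline} (list: enabled, m); \code{modifiers};
#'   \code{restrict_thresholds}; \code{ses_mode}; \code{out_dir}.
#' @return object of class \code{pm_report}: list with \code{summary}
#'   (one row per fit), \code{fits}, \code{curves}, \code{subgroups},
#'   \code{restrictions}, \code{config_hash}, \code{seed}.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  causes <- cfg$causes %||% "All CVD"
  variants <- cfg$variants %||% c("base", "ses")
  expo_types <- cfg$exposure_types %||% "total"
  ses_mode <- cfg$ses_mode %||% "stratum"
  strata <- c("age_cat", "sex", "race", "zip")
  seed <- cfg$simulate$seed %||% NA_integer_

  if (!is.null(cfg$input_dir)) {
    study <- read_study(cfg$input_dir)
    ses <- ses_by_year(study$exposures$income)
    study$ses <- ses
  } else {
    sim_over <- cfg$simulate %||% list()
    sim_over$seed <- NULL
    sc <- do.call(sim_config, sim_over)
    study <- simulate_study(sc, seed = if (is.na(seed)) 1L else seed)
  }
  val <- validate_inputs(study$cohort, study$residence,
                         study$exposures$pm25)
  if (!val$ok) {
    stop("input validation failed with ", nrow(val$errors), " error(s); ",
         "first: ", val$errors$detail[1L], " (beneficiary ",
         val$errors$id[1L], ")")
  }

  # person-level exposures
  expo <- person_exposure_12mo(study$cohort, study$residence,
                               study$exposures$pm25, col = "pm25_12mo")
  if ("nontraffic" %in% expo_types) {
    zm_pm <- zip_exposure_12mo(study$exposures$pm25, "pm25_12mo")
    zm_no2 <- zip_exposure_12mo(study$exposures$no2, "no2_12mo")
    zm <- merge(zm_pm, zm_no2, by = c("zip", "month"))
    rm_model <- fit_residual_model(zm[complete.cases(zm)])
    study$residual_model <- rm_model
  }
  zip_covars <- NULL
  monitor_zips <- NULL
  if ("ozone" %in% variants) {
    o3 <- warm_season_ozone(study$exposures$o3_daily)
    zip_covars <- o3
    if (!is.null(cfg$monitors)) {
      # ozone-adjusted models run on the subset of ZIP codes near monitors
      mon <- as.data.table(cfg$monitors)
      monitor_zips <- monitor_subset(
        study$zips[, list(zip, lat, lon)], mon,
        radius_miles = cfg$monitor_radius_miles %||% 6)
    }
  }

  summary_rows <- list()
  fits <- list()
  curves <- list()
  subgroups <- list()
  restrictions <- list()

  # one expansion serves every cause: only the event column differs
  pm_base <- expand_person_months(
    study$cohort, study$residence, expo, cause = causes[1L],
    ses = study$ses, zip_covars = zip_covars)
  if (!is.null(study$residual_model)) {
    pm_base <- merge(pm_base, study$residual_model$residuals,
                     by = c("zip", "month"), all.x = TRUE)
    pm_base <- pm_base[!is.na(resid_pm25)]
  }
  for (cause in causes) {
    set_event_cause(pm_base, cause)
    for (variant in variants) {
      for (etype in expo_types) {
        key <- paste(cause, variant, etype, sep = " | ")
        xcol <- if (etype == "total") "pm25_12mo" else "resid_pm25"
        res <- tryCatch({
          pm_v <- pm_base
          if (variant == "ozone") {
            pm_v <- pm_v[!is.na(o3_warm)]
            if (!is.null(monitor_zips)) pm_v <- pm_v[zip %in% monitor_zips]
          }
          fit <- pm_cox(
            pm_v, exposure = xcol, strata = strata,
            extra_covariates = if (variant == "ozone") "o3_warm"
                               else character(),
            ses_mode = if (variant %in% c("ses", "ozone")) ses_mode
                       else "none")
          rr <- rr_per_10(fit, xcol)
          list(fit = fit, rr = rr, error = NA_character_)
        }, error = function(e) list(fit = NULL, rr = c(rr = NA, lo95 = NA,
                                                       hi95 = NA),
                                    error = conditionMessage(e)))
        fits[[key]] <- res$fit
        summary_rows[[key]] <- data.table(
          cause = cause, variant = variant, exposure = etype,
          rr_per10 = res$rr[["rr"]], lo95 = res$rr[["lo95"]],
          hi95 = res$rr[["hi95"]],
          n_events = if (is.null(res$fit)) NA_integer_ else
            as.integer(res$fit$n_events),
          n_person_months = if (is.null(res$fit)) NA_integer_ else
            res$fit$n_person_months,
          n_cells = if (is.null(res$fit)) NA_integer_ else res$fit$n_cells,
          iterations = if (is.null(res$fit)) NA_integer_ else
            res$fit$iterations,
          converged = if (is.null(res$fit)) FALSE else res$fit$converged,
          error = res$error)
      }
    }
    if (isTRUE(cfg$spline$enabled)) {
      sf <- tryCatch({
        strat_sp <- if ("ses" %in% variants) union(strata, "ses") else
          strata
        sfit <- fit_spline_model(pm_base, exposure = "pm25_12mo",
                                 knots = cfg$spline$knots,
                                 m = cfg$spline$m %||% 3L,
                                 strata = strat_sp)
        grid <- seq(0, max(pm_base$pm25_12mo), length.out = 60L)
        rr_curve(sfit, grid)
      }, error = function(e) NULL)
      if (!is.null(sf)) curves[[cause]] <- sf
    }
    for (mod in cfg$modifiers %||% character()) {
      sg <- tryCatch(
        subgroup_rrs(pm_base, modifier = mod, strata = strata),
        error = function(e) NULL)
      if (!is.null(sg)) subgroups[[paste(cause, mod, sep = " | ")]] <- sg
    }
  }

  for (thr in cfg$restrict_thresholds %||% numeric()) {
    zm <- zip_exposure_12mo(study$exposures$pm25, "pm12")
    zmeans <- zm[!is.na(pm12), list(zip_mean = mean(pm12)), by = zip]
    keep_zips <- restrict_low_pm(zmeans, thr)
    cause <- causes[1L]
    set_event_cause(pm_base, cause)
    pm_r <- pm_base[zip %in% keep_zips]
    res <- tryCatch({
      fit <- pm_cox(pm_r, strata = strata, ses_mode = ses_mode)
      c(rr_per_10(fit), n_events = fit$n_events)
    }, error = function(e) c(rr = NA, lo95 = NA, hi95 = NA, n_events = NA))
    restrictions[[as.character(thr)]] <- data.table(
      threshold = thr, cause = cause, n_zips = length(keep_zips),
      rr_per10 = res[["rr"]], lo95 = res[["lo95"]], hi95 = res[["hi95"]],
      n_events = res[["n_events"]])
  }

  out <- list(
    summary = rbindlist(summary_rows),
    fits = fits, curves = curves, subgroups = subgroups,
    restrictions = if (length(restrictions)) rbindlist(restrictions) else
      NULL,
    residual_model = study$residual_model,
    config_hash = config_hash(config),
    seed = seed)
  class(out) <- "pm_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(out$summary, file.path(cfg$out_dir, "rr_table.csv"))
    for (nm in names(curves)) {
      slug <- gsub("[^A-Za-z0-9]+", "_", nm)
      fwrite(curves[[nm]],
             file.path(cfg$out_dir, paste0("curve_", slug, ".csv")))
      if (isTRUE(cfg$figures) &&
            requireNamespace("ggplot2", quietly = TRUE)) {
        p <- plot_rr_curve(curves[[nm]], title = nm)
        ggplot2::ggsave(file.path(cfg$out_dir,
                                  paste0("curve_", slug, ".png")),
                        p, width = 5, height = 4, dpi = 150)
      }
    }
    for (nm in names(subgroups)) {
      fwrite(as.data.table(subgroups[[nm]]),
             file.path(cfg$out_dir, paste0(
               "subgroups_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv")))
    }
    if (!is.null(out$restrictions)) {
      fwrite(out$restrictions, file.path(cfg$out_dir, "restrictions.csv"))
    }
    index <- list(config_hash = out$config_hash, seed = out$seed,
                  n_fits = nrow(out$summary),
                  files = list.files(cfg$out_dir))
    jsonlite::write_json(index, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pm_report <- function(x, ...) {
  cat("Analysis report (config ", x$config_hash, ", seed ", x$seed, ")\n",
      sep = "")
  print(x$summary[, list(cause, variant, exposure,
                         rr_per10 = signif(rr_per10, 4),
                         lo95 = signif(lo95, 4), hi95 = signif(hi95, 4),
                         n_events, converged)])
  invisible(x)
}

#' Plot an exposure-response curve
#'
#' Risk ratio against the zero reference with its pointwise band;
#' requires ggplot2.
#'
#' @param curve an \code{rr_curve}.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_rr_curve <- function(curve, title = "Exposure-response") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = exposure, y = rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo95, ymax = hi95),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = expression(PM[2.5] ~ (mu * g / m^3)),
                  y = "RR vs 0", title = title) +
    ggplot2::theme_minimal()
}
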