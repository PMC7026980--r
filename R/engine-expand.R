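#' Expand a cohort into person-months
#'
#' One row per month at risk, from the follow-up start to death or
#' censoring. Analysis time is follow-up months since entry (the risk-set
#' index); the event indicator is 1 only at the death month and only when
#' the underlying-cause code falls in the modeled cause's ranges — deaths
#' from other causes censor that month (cause-specific hazard convention).
#' The stratum variables are evaluated at the person-month, so the age
#' category advances as the beneficiary ages through follow-up.
#'
#' @param cohort cohort table (id, birth_month, sex, race, entry_month,
#'   end_month, death_month, icd10_cause).
#' @param residence residence table (id, start_month, zip).
#' @param exposure \code{data.table} keyed (id, month) with exposure
#'   columns, e.g. from \code{\link{person_exposure_12mo}}.
#' @param cause modeled cause label.
#' @param map a \code{\link{cause_map}}.
#' @param ses optional \code{data.table} (zip, year, ses) from
#'   \code{\link{ses_by_year}}.
#' @param zip_covars optional \code{data.table} keyed (zip) or (zip, year)
#'   with extra ZIP-level covariate columns (e.g. warm-season ozone).
#' @param drop_missing drop person-months with missing exposure (they leave
#'   the risk set; the count is recorded in attribute
#'   \code{"n_dropped_missing"}).
#' @return \code{data.table}: id, month, fu_index, zip, age_cat, sex, race,
#'   event, exposure columns (+ ses and ZIP covariates when supplied).
#' @export
expand_person_months <- function(cohort, residence, exposure, cause,
                                 map = default_cause_map(), ses = NULL,
                                 zip_covars = NULL, drop_missing = TRUE) {
  co <- copy(as.data.table(cohort))
  re <- copy(as.data.table(residence))
  ex <- as.data.table(exposure)
  bad <- co[!is.na(death_month) & death_month < entry_month]
  if (nrow(bad)) {
    stop("death before follow-up start for beneficiary ",
         paste(head(bad$id, 5L), collapse = ", "))
  }
  setorder(re, id, start_month)
  if (anyDuplicated(re, by = c("id", "start_month"))) {
    dup <- re[duplicated(re, by = c("id", "start_month")), id]
    stop("overlapping residence segments for beneficiary ",
         paste(unique(head(dup, 5L)), collapse = ", "))
  }

  setorder(co, id)
  lens <- co$end_month - co$entry_month + 1L
  id_v <- rep(co$id, times = lens)
  month_v <- sequence(lens, from = co$entry_month)
  fu_v <- sequence(lens)
  pidx <- rep(seq_len(nrow(co)), times = lens)   # person index per row

  # residence at each person-month: constant for single-segment people,
  # rolling join only for movers
  n_seg <- re[, .N, by = id]
  movers <- n_seg[N > 1L, id]
  first_zip <- re[, list(zip = zip[1L]), by = id]
  zip_levels <- sort(unique(re$zip))
  fz <- first_zip$zip[match(co$id, first_zip$id)]
  zip_v <- fz[pidx]
  zip_i <- match(fz, zip_levels)[pidx]
  if (length(movers)) {
    mov_p <- co$id %in% movers
    mrows <- which(mov_p[pidx])
    sub <- data.table(id = id_v[mrows], month = month_v[mrows])
    re2 <- re[id %in% movers, list(id, month = start_month, zip)]
    setkey(re2, id, month)
    setkey(sub, id, month)
    sub <- re2[sub, roll = Inf]
    sub[is.na(zip), zip := first_zip$zip[match(id, first_zip$id)]]
    zip_v[mrows] <- sub$zip
    zip_i[mrows] <- match(sub$zip, zip_levels)
  }

  # per-month demographics; one-year age bins via a lookup table
  age <- (month_v - co$birth_month[pidx]) %/% 12L
  if (min(age) < 65L) {
    stop("attained age below 65 during follow-up (min age ", min(age), ")")
  }
  age_i <- pmin(age, 90L) - 64L                    # 1..26
  age_labels <- c(as.character(65:89), "90+")
  sex_levels <- sort(unique(co$sex))
  race_levels <- sort(unique(co$race))
  sex_i <- match(co$sex, sex_levels)
  race_i <- match(co$race, race_levels)

  # modeled-cause event at the final month; deaths from other causes censor
  is_cause_p <- rep(FALSE, nrow(co))
  has_death <- !is.na(co$death_month)
  if (any(has_death)) {
    roots <- icd10_root(co$icd10_cause[has_death])
    is_cause_p[has_death] <- root_in_cause(roots, cause, map)
  }
  ev <- integer(length(id_v))
  ev[cumsum(lens)] <- as.integer(is_cause_p)
  # death root at the final month, so the modeled cause can be switched
  # on an existing expansion without re-expanding
  dr <- rep(NA_character_, length(id_v))
  if (any(has_death)) {
    dr[cumsum(lens)[has_death]] <- roots
  }

  pm <- data.table(id = id_v, month = month_v, fu_index = fu_v,
                   zip = zip_v, age_cat = age_labels[age_i],
                   sex = co$sex[pidx], race = co$race[pidx],
                   event = ev, death_root = dr)
  # integer key encoding the standard (age, sex, race, zip) stratum; lets
  # the aggregation group on one integer instead of four strings
  n_demo <- length(sex_levels) * length(race_levels)
  if (length(zip_levels) * 26 * n_demo < .Machine$integer.max) {
    set(pm, j = "skey",
        value = ((zip_i - 1L) * 26L + (age_i - 1L)) * n_demo +
          (sex_i[pidx] - 1L) * length(race_levels) + race_i[pidx])
  }

  expo_cols <- setdiff(names(ex), c("id", "month"))
  if (identical(ex$id, pm$id) && identical(ex$month, pm$month)) {
    for (cc in expo_cols) set(pm, j = cc, value = ex[[cc]])
  } else {
    pm <- merge(pm, ex, by = c("id", "month"), all.x = TRUE)
  }
  if (!is.null(ses)) {
    se <- as.data.table(ses)
    pm[, year := month_year(month)]
    pm <- merge(pm, se, by = c("zip", "year"), all.x = TRUE)
    pm[, year := NULL]
  }
  if (!is.null(zip_covars)) {
    zc <- as.data.table(zip_covars)
    if ("year" %in% names(zc)) {
      pm[, year := month_year(month)]
      pm <- merge(pm, zc, by = c("zip", "year"), all.x = TRUE)
      pm[, year := NULL]
    } else {
      pm <- merge(pm, zc, by = "zip", all.x = TRUE)
    }
  }
  n_dropped <- 0L
  if (drop_missing && length(expo_cols)) {
    ok <- !is.na(pm[[expo_cols[1L]]])
    for (cc in expo_cols[-1L]) ok <- ok & !is.na(pm[[cc]])
    n_dropped <- sum(!ok)
    if (n_dropped > 0L) pm <- pm[ok]
  }
  setorder(pm, id, month)
  setattr(pm, "n_dropped_missing", n_dropped)
  setattr(pm, "cause", cause)
  pm[]
}

#' Compress person-months into grouped sufficient statistics
#'
#' Person-months are grouped by (stratum, follow-up index, covariate
#' vector); each cell records how many person-months share that key
#' (\code{n_at_risk}) and how many of them are events (\code{n_events}).
#' Under the Breslow tie rule the partial likelihood, its gradient and the
#' observed information depend on the data only through these cells, so the
#' compression is exact — fits on cells reproduce fits on raw rows to
#' floating-point accuracy. Covariates are matched exactly (no rounding) by
#' default: ZIP-month exposures are already shared across a stratum's
#' members, which is where the compression comes from.
#'
#' @param pm person-month table from \code{\link{expand_person_months}}.
#' @param strata character vector of stratum column names.
#' @param covariates character vector of covariate column names.
#' @param collapse set \code{FALSE} to keep one cell per person-month
#'   (used to verify losslessness of the grouping).
#' @param informative_only drop risk sets without events before grouping.
#'   Those (stratum, time) groups contribute nothing to the Breslow partial
#'   likelihood, so every fit statistic is unchanged while the cell table
#'   shrinks by orders of magnitude on finely stratified cohorts; totals
#'   over all person-months are preserved in the attributes
#'   \code{"n_person_months_total"} and \code{"n_cells"}-related fit
#'   metadata.
#' @return object of class \code{pm_cells}: \code{data.table} with columns
#'   stratum (integer), time, the covariate columns, n_at_risk, n_events.
#' @export
aggregate_cells <- function(pm, strata = c("age_cat", "sex", "race", "zip"),
                            covariates = "pm25_12mo", collapse = TRUE,
                            informative_only = FALSE) {
  pm <- as.data.table(pm)
  miss <- setdiff(c(strata, covariates, "fu_index", "event"), names(pm))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n_pm_total <- nrow(pm)
  if (informative_only) {
    # arithmetic risk-set key (exact in doubles below 2^53): rows outside
    # event-bearing (stratum, time) groups are dropped without sorting
    key <- numeric(nrow(pm))
    overflow <- FALSE
    span <- 1
    for (sc in c(strata, "fu_index")) {
      v <- pm[[sc]]
      if (!is.integer(v)) v <- match(v, unique(v))
      v <- as.numeric(v)
      rng <- range(v)
      span <- span * (rng[2L] - rng[1L] + 1)
      if (span > 2^52) { overflow <- TRUE; break }
      key <- key * (rng[2L] - rng[1L] + 1) + (v - rng[1L])
    }
    if (overflow) {
      work <- pm[, c(strata, "fu_index", "event", covariates),
                 with = FALSE]
      work[, g := .GRP, by = c(strata, "fu_index")]
      keep_g <- work[event == 1L, unique(g)]
      work <- work[g %in% keep_g]
      work[, g := NULL]
    } else {
      keep <- key %in% key[pm[["event"]] == 1L]
      work <- pm[keep, c(strata, "fu_index", "event", covariates),
                 with = FALSE]
    }
  } else {
    work <- pm[, c(strata, "fu_index", "event", covariates), with = FALSE]
  }
  for (cc in covariates) {
    if (any(!is.finite(work[[cc]]))) {
      stop("non-finite values in covariate '", cc,
           "'; drop or impute before aggregation")
    }
  }
  work[, stratum := .GRP, by = strata]
  if (collapse) {
    cells <- work[, list(n_at_risk = .N, n_events = sum(event)),
                  by = c("stratum", "fu_index", covariates)]
  } else {
    cells <- work[, c("stratum", "fu_index", covariates, "event"),
                  with = FALSE]
    cells[, n_at_risk := 1L]
    setnames(cells, "event", "n_events")
  }
  setnames(cells, "fu_index", "time")
  setorderv(cells, c("stratum", "time", covariates))
  setattr(cells, "covariates", covariates)
  setattr(cells, "strata", strata)
  setattr(cells, "n_person_months_total", n_pm_total)
  setattr(cells, "class", c("pm_cells", class(cells)))
  cells[]
}

#' Switch the modeled cause on an existing expansion
#'
#' Re-derives the event indicator for a different cause from the stored
#' death roots; everything else about the person-month table (risk sets,
#' covariates, strata) is cause-independent, so per-cause models can share
#' one expansion.
#'
#' @param pm a person-month table from \code{\link{expand_person_months}}.
#' @param cause new modeled cause label ("*" for death from any cause).
#' @param map a \code{\link{cause_map}}.
#' @return the table, with \code{event} recomputed (modified by reference).
#' @export
set_event_cause <- function(pm, cause, map = default_cause_map()) {
  if (!"death_root" %in% names(pm)) {
    stop("person-month table lacks the death_root column")
  }
  ev <- integer(nrow(pm))
  has <- !is.na(pm$death_root)
  ev[has] <- as.integer(root_in_cause(pm$death_root[has], cause, map))
  set(pm, j = "event", value = ev)
  setattr(pm, "cause", cause)
  invisible(pm)
}

#' @export
print.pm_cells <- function(x, ...) {
  cat(sprintf(
    "pm_cells: %d cells, %d person-months, %d events, covariates: %s\n",
    nrow(x), sum(x$n_at_risk), sum(x$n_events),
    paste(attr(x, "covariates"), collapse = ", ")))
  invisible(x)
}
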