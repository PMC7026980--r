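#' Linear exposure Cox model on a person-month table
#'
#' Convenience wrapper: aggregates cells on the exposure (plus optional
#' adjustment covariates) and fits the stratified Cox model. SES enters
#' either as an extra stratum dimension (\code{ses_mode = "stratum"}, the
#' default) or as indicator adjustment covariates
#' (\code{ses_mode = "covariate"}); the person-month table must then carry
#' a \code{ses} column.
#'
#' @param pm person-month table from \code{\link{expand_person_months}}.
#' @param exposure exposure column name.
#' @param strata stratum columns.
#' @param extra_covariates additional adjustment covariate columns
#'   (e.g. warm-season ozone).
#' @param ses_mode "none", "stratum" or "covariate".
#' @param ... passed to \code{\link{fit_cox}}.
#' @return a \code{cox_fit} with attribute \code{exposure}.
#' @export
pm_cox <- function(pm, exposure = "pm25_12mo",
                   strata = c("age_cat", "sex", "race", "zip"),
                   extra_covariates = character(),
                   ses_mode = c("none", "stratum", "covariate"), ...) {
  ses_mode <- match.arg(ses_mode)
  pm <- as.data.table(pm)
  covars <- c(exposure, extra_covariates)
  if (ses_mode == "stratum") {
    if (!"ses" %in% names(pm)) stop("ses_mode='stratum' needs a ses column")
    strata <- union(strata, "ses")
  } else if (ses_mode == "covariate") {
    if (!"ses" %in% names(pm)) stop("ses_mode='covariate' needs a ses column")
    lev <- sort(unique(pm$ses))
    for (l in lev[-1L]) {
      col <- paste0("ses_", l)
      set(pm, j = col, value = as.numeric(pm$ses == l))
      covars <- c(covars, col)
    }
  }
  cells <- aggregate_cells(pm, strata = stratum_cols(pm, strata),
                           covariates = covars, informative_only = TRUE)
  fit <- fit_cox(cells, ...)
  attr(fit, "exposure") <- exposure
  fit
}

# swap the four standard stratum columns for the precomputed integer key
# when the expansion provides it (identical grouping, much faster)
stratum_cols <- function(pm, strata) {
  std <- c("age_cat", "sex", "race", "zip")
  if ("skey" %in% names(pm) && all(std %in% strata)) {
    c("skey", setdiff(strata, std))
  } else {
    strata
  }
}

#' Effect modification via exposure-by-subgroup interactions
#'
#' Single joint fit with the exposure main effect plus exposure-by-level
#' interaction terms for every non-reference level of the modifier
#' (age group, sex, race, urbanicity or SES level). Each level's risk
#' ratio per 10 ug/m3 is exp(10 (b_main + g_level)) with a delta-method CI
#' from the joint covariance; the reference level's interaction is zero by
#' construction, so its RR is exp(10 b_main). Levels without events are
#' flagged and their RR omitted.
#'
#' @param pm person-month table.
#' @param modifier column name of the categorical modifier.
#' @param reference reference level (default: first sorted level).
#' @param exposure exposure column.
#' @param strata stratum columns; the modifier need not be one of them.
#' @param extra_covariates additional adjustment covariates.
#' @param ... passed to \code{\link{fit_cox}}.
#' @return object of class \code{subgroup_effects}: \code{data.table}
#'   (level, rr, lo95, hi95, n_events, reference, gamma, gamma_se, gamma_z)
#'   with attribute \code{"fit"} (the joint \code{cox_fit}).
#' @export
subgroup_rrs <- function(pm, modifier, reference = NULL,
                         exposure = "pm25_12mo",
                         strata = c("age_cat", "sex", "race", "zip"),
                         extra_covariates = character(), ...) {
  pm <- as.data.table(pm)
  if (!modifier %in% names(pm)) stop("no column '", modifier, "'")
  levs <- sort(unique(as.character(pm[[modifier]])))
  if (is.null(reference)) reference <- levs[1L]
  stopifnot(reference %in% levs)
  levs <- c(reference, setdiff(levs, reference))
  ev_by_level <- pm[, list(n_events = sum(event)), by = c(modifier)]
  setnames(ev_by_level, modifier, "level")

  mod_chr <- as.character(pm[[modifier]])
  # levels without events cannot support an interaction term: flagged, no
  # column. Levels whose informative risk sets carry no exposure contrast
  # are aliased in the information matrix; they are dropped with a warning
  # on retry.
  with_events <- ev_by_level[n_events > 0L, level]
  int_levels <- setdiff(intersect(levs[-1L], with_events), character())
  dropped <- character()
  repeat {
    covars <- exposure
    for (l in int_levels) {
      col <- paste0(exposure, "_x_", l)
      set(pm, j = col, value = pm[[exposure]] * (mod_chr == l))
      covars <- c(covars, col)
    }
    cells <- aggregate_cells(pm, strata = stratum_cols(pm, strata),
                             covariates = c(covars, extra_covariates),
                             informative_only = TRUE)
    fit <- tryCatch(fit_cox(cells, ...), error = function(e) e)
    if (!inherits(fit, "error")) {
      if (isTRUE(fit$converged)) break
      # quasi-separation in a sparse level: its interaction diverges
      ints <- paste0(exposure, "_x_", int_levels)
      bad <- int_levels[abs(fit$coefficients[ints]) > 5]
      bad <- bad[!is.na(bad)]
      if (length(bad) == 0L) break
    } else {
      msg <- conditionMessage(fit)
      bad <- int_levels[paste0(exposure, "_x_", int_levels) %in%
                          regmatches(msg, gregexpr("[A-Za-z0-9_]+",
                                                   msg))[[1L]]]
      if (!grepl("singular", msg) || length(bad) == 0L) stop(fit)
    }
    warning("interaction term(s) without identifiable contrast dropped: ",
            paste(bad, collapse = ", "))
    dropped <- c(dropped, bad)
    int_levels <- setdiff(int_levels, bad)
  }
  if (!isTRUE(fit$converged)) stop("joint interaction fit did not converge")

  b <- fit$coefficients
  V <- fit$vcov
  z <- qnorm(0.975)
  rows <- lapply(levs, function(l) {
    nev <- ev_by_level[level == l, n_events]
    nev <- if (length(nev)) nev else 0L
    if (l == reference) {
      est <- b[[exposure]]
      se <- sqrt(V[exposure, exposure])
      gam <- 0; gse <- NA_real_
    } else if (l %in% int_levels) {
      col <- paste0(exposure, "_x_", l)
      est <- b[[exposure]] + b[[col]]
      se <- sqrt(V[exposure, exposure] + V[col, col] +
                   2 * V[exposure, col])
      gam <- b[[col]]; gse <- sqrt(V[col, col])
    } else {
      est <- NA_real_     # zero events or aliased: RR omitted
    }
    if (nev == 0L || is.na(est)) {
      data.table(level = l, rr = NA_real_, lo95 = NA_real_,
                 hi95 = NA_real_, n_events = as.integer(nev),
                 reference = l == reference, gamma = NA_real_,
                 gamma_se = NA_real_, gamma_z = NA_real_)
    } else {
      data.table(level = l, rr = exp(10 * est),
                 lo95 = exp(10 * (est - z * se)),
                 hi95 = exp(10 * (est + z * se)),
                 n_events = nev, reference = l == reference,
                 gamma = gam, gamma_se = gse,
                 gamma_z = if (l == reference) NA_real_ else gam / gse)
    }
  })
  out <- rbindlist(rows)
  omitted <- out$level[is.na(out$rr)]
  if (length(omitted)) {
    warning("modifier level(s) with no events or no identifiable ",
            "contrast, RR omitted: ", paste(omitted, collapse = ", "))
  }
  setattr(out, "class", c("subgroup_effects", class(out)))
  setattr(out, "fit", fit)
  setattr(out, "modifier", modifier)
  out[]
}

#' @export
print.subgroup_effects <- function(x, ...) {
  cat("Effect modification by", attr(x, "modifier"),
      "- RR per 10 ug/m3\n")
  print(as.data.table(x)[, list(level, rr = signif(rr, 4),
                                lo95 = signif(lo95, 4),
                                hi95 = signif(hi95, 4), n_events,
                                reference)])
  invisible(x)
}
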