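#' One-year age categories with a pooled 90+ bin
#'
#' Attained age in whole years at a given calendar month, binned into
#' one-year categories "65" ... "89" plus a single "90+" category. Pooling
#' ages 90 and above avoids near-empty strata at the oldest ages while
#' keeping one-year resolution where the cohort is dense.
#'
#' @param birth_month,at_month encoded calendar months (see
#'   \code{\link{ym_to_month}}); vectors are recycled.
#' @return character vector of age bins.
#' @export
age_category <- function(birth_month, at_month) {
  age <- (as.integer(at_month) - as.integer(birth_month)) %/% 12L
  if (any(age < 65L)) {
    stop("attained age below 65 is outside the cohort (min age found: ",
         min(age), ")")
  }
  ifelse(age >= 90L, "90+", as.character(age))
}

#' ZIP-level income tertiles
#'
#' Classifies ZIP codes as low/medium/high socio-economic status from the
#' tertiles of the ZIP-level adjusted-income distribution; recomputed per
#' calendar year by the pipeline. Boundary values go to the lower tertile,
#' which makes the labels deterministic and invariant to input order.
#'
#' @param incomes named numeric vector, one income per ZIP code.
#' @return named character vector with levels "low", "medium", "high".
#' @export
classify_ses_tertiles <- function(incomes) {
  if (length(incomes) < 3L || sum(is.finite(incomes)) < 3L) {
    stop("need at least 3 ZIP codes with finite income")
  }
  if (diff(range(incomes, na.rm = TRUE)) == 0) {
    stop("degenerate income distribution: all incomes identical")
  }
  qs <- quantile(incomes, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  out <- ifelse(incomes <= qs[1L], "low",
                ifelse(incomes <= qs[2L], "medium", "high"))
  names(out) <- names(incomes)
  out
}

#' Carry-forward imputation of missing income years
#'
#' The ZIP-level income source lacks 2000 and 2003; those years are filled
#' with the 2001 and 2004 values respectively. All other years pass through
#' unchanged; nothing is overwritten if the target year is already present.
#'
#' @param incomes named numeric vector keyed by year ("2001" etc.).
#' @return completed named numeric vector, sorted by year.
#' @export
impute_missing_income_years <- function(incomes) {
  stopifnot(!is.null(names(incomes)))
  fills <- c("2000" = "2001", "2003" = "2004")
  yrs <- as.integer(names(incomes))
  for (target in names(fills)) {
    donor <- fills[[target]]
    if (!target %in% names(incomes)) {
      if (!donor %in% names(incomes)) {
        # a hole inside the observed span has no donor: that is an error;
        # a target beyond the span (short study window) is simply skipped
        if (as.integer(target) > min(yrs) && as.integer(target) < max(yrs)) {
          stop("cannot impute year ", target, ": donor year ", donor,
               " is absent")
        }
        next
      }
      incomes[target] <- incomes[[donor]]
    }
  }
  incomes[order(as.integer(names(incomes)))]
}

#' Per-year SES levels for a ZIP attribute table
#'
#' Applies the missing-year carry rule per ZIP and then the tertile
#' classification per year.
#'
#' @param zip_income \code{data.table} with columns zip, year, income.
#' @return \code{data.table} with columns zip, year, ses.
#' @export
ses_by_year <- function(zip_income) {
  zi <- as.data.table(zip_income)
  stopifnot(all(c("zip", "year", "income") %in% names(zi)))
  # carry rule per ZIP
  filled <- zi[, {
    v <- setNames(income, as.character(year))
    v <- impute_missing_income_years(v)
    list(year = as.integer(names(v)), income = as.numeric(v))
  }, by = zip]
  filled[, list(zip = zip, ses = classify_ses_tertiles(setNames(income, zip))),
         by = year][, list(zip, year, ses)]
}

#' Validate a beneficiary cohort table
#'
#' Structural checks on the cohort and residence-history tables: follow-up
#' windows ordered, entry age at least 65, death month (when present) equal
#' to the follow-up end, residence segments non-overlapping and covering the
#' follow-up window, ICD-10 codes parseable.
#'
#' @param cohort \code{data.table} with columns id, birth_month, sex, race,
#'   entry_month, end_month, death_month (NA if censored), icd10_cause
#'   (NA if censored).
#' @param residence \code{data.table} with columns id, start_month, zip.
#' @return \code{data.table} of issues (id, check, detail); zero rows means
#'   the cohort validates.
#' @export
validate_cohort <- function(cohort, residence) {
  co <- as.data.table(cohort)
  re <- as.data.table(residence)
  issues <- list()
  bad <- co[entry_month > end_month]
  if (nrow(bad)) {
    issues[[length(issues) + 1L]] <- data.table(
      id = bad$id, check = "window_order",
      detail = "follow-up start after follow-up end")
  }
  bad <- co[!is.na(death_month) & death_month != end_month]
  if (nrow(bad)) {
    issues[[length(issues) + 1L]] <- data.table(
      id = bad$id, check = "death_month",
      detail = "death month differs from follow-up end")
  }
  age <- (co$entry_month - co$birth_month) %/% 12L
  bad <- co[age < 65L]
  if (nrow(bad)) {
    issues[[length(issues) + 1L]] <- data.table(
      id = bad$id, check = "entry_age", detail = "age at entry below 65")
  }
  bad <- co[!is.na(death_month) & is.na(icd10_cause)]
  if (nrow(bad)) {
    issues[[length(issues) + 1L]] <- data.table(
      id = bad$id, check = "missing_cause",
      detail = "death month present but no ICD-10 cause")
  }
  codes <- co[!is.na(icd10_cause), list(id, icd10_cause)]
  if (nrow(codes)) {
    ok <- grepl("^[A-Z]\\d{2}(\\.?\\d{1,2})?$", toupper(codes$icd10_cause))
    if (any(!ok)) {
      issues[[length(issues) + 1L]] <- data.table(
        id = codes$id[!ok], check = "icd10_parse",
        detail = paste0("unparseable ICD-10 code '",
                        codes$icd10_cause[!ok], "'"))
    }
  }
  # residence: sorted, distinct starts, first segment at or before entry
  setorder(re, id, start_month)
  dup <- re[, list(n = .N), by = list(id, start_month)][n > 1L]
  if (nrow(dup)) {
    issues[[length(issues) + 1L]] <- data.table(
      id = dup$id, check = "residence_overlap",
      detail = "two residence segments share a start month")
  }
  first <- re[, list(first_start = start_month[1L]), by = id]
  chk <- merge(co[, list(id, entry_month)], first, by = "id", all.x = TRUE)
  bad <- chk[is.na(first_start) | first_start > entry_month]
  if (nrow(bad)) {
    issues[[length(issues) + 1L]] <- data.table(
      id = bad$id, check = "residence_coverage",
      detail = "no residence segment covering the follow-up start")
  }
  if (length(issues)) rbindlist(issues) else
    data.table(id = character(), check = character(), detail = character())
}
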