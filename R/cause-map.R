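#' Cause-of-death grouping from ICD-10 ranges
#'
#' A cause map names groups of underlying causes of death, each defined by
#' one or more inclusive ranges of ICD-10 three-character category roots
#' ("I20-I25", a single root "C34", or a bare letter span "A-R" meaning
#' A00-R99). A code belongs to every cause whose range contains its root, so
#' the groups are naturally nested (ischemic heart disease inside all
#' cardiovascular inside non-accidental).
#'
#' The default map covers the standard cause hierarchy for elderly-cohort
#' air-pollution mortality studies: non-accidental (A-R), accidental (V-Y),
#' all cardiovascular (I00-I99) with IHD (I20-I25), cerebrovascular
#' (I60-I69) and congestive heart failure (I50), all respiratory (J00-J99)
#' with COPD (J40-J44) and pneumonia (J12-J18), and all cancer with lung
#' cancer (C34). The "C-D" cancer block is bounded at D48, the end of the
#' ICD-10 neoplasms chapter; a literal reading up to D99 would pull in
#' blood-disease codes that are not neoplasms.
#'
#' @param ranges named list: cause label -> character vector of range strings.
#' @return object of class \code{cause_map}: a \code{data.table} with one row
#'   per (cause, range) giving the inclusive root bounds.
#' @export
cause_map <- function(ranges) {
  stopifnot(is.list(ranges), length(names(ranges)) == length(ranges))
  rows <- lapply(names(ranges), function(nm) {
    bounds <- lapply(ranges[[nm]], parse_icd_range)
    data.table(
      cause = nm,
      lo = vapply(bounds, `[`, "", 1L),
      hi = vapply(bounds, `[`, "", 2L)
    )
  })
  out <- rbindlist(rows)
  setattr(out, "class", c("cause_map", class(out)))
  out
}

#' @rdname cause_map
#' @export
default_cause_map <- function() {
  cause_map(list(
    `Non-accidental`   = "A-R",
    `Accidental`       = "V-Y",
    `All CVD`          = "I00-I99",
    `IHD`              = "I20-I25",
    `CBV`              = "I60-I69",
    `CHF`              = "I50",
    `All respiratory`  = "J00-J99",
    `COPD`             = "J40-J44",
    `Pneumonia`        = "J12-J18",
    `All cancer`       = "C00-D48",
    `Lung cancer`      = "C34"
  ))
}

#' Read a cause map from a YAML config
#'
#' The file maps cause labels to lists of range strings; the packaged
#' \code{inst/extdata/cause_map.yaml} holds the default hierarchy.
#'
#' @param path file path.
#' @export
read_cause_map <- function(path) {
  cause_map(yaml::read_yaml(path))
}

# "I20-I25" / "C34" / "A-R" -> c(lo_root, hi_root)
parse_icd_range <- function(s) {
  s <- toupper(trimws(s))
  if (grepl("^[A-Z]\\d{2}-[A-Z]\\d{2}$", s)) {
    c(substr(s, 1L, 3L), substr(s, 5L, 7L))
  } else if (grepl("^[A-Z]\\d{2}$", s)) {
    c(s, s)
  } else if (grepl("^[A-Z]-[A-Z]$", s)) {
    c(paste0(substr(s, 1L, 1L), "00"), paste0(substr(s, 3L, 3L), "99"))
  } else {
    stop("cannot parse ICD-10 range: '", s, "'")
  }
}

#' Three-character root of an ICD-10 code
#'
#' @param code character vector of ICD-10 codes (letter, two digits,
#'   optional subcode, e.g. "I21.4" or "I214").
#' @return character vector of roots ("I21").
#' @export
icd10_root <- function(code) {
  code <- toupper(trimws(code))
  ok <- grepl("^[A-Z]\\d{2}(\\.?\\d{1,2})?$", code)
  if (!all(ok)) {
    stop("malformed ICD-10 code(s): ", paste(unique(code[!ok]), collapse = ", "))
  }
  substr(code, 1L, 3L)
}

#' Map an ICD-10 code to its cause labels
#'
#' Returns every cause of the map whose range contains the code's
#' three-character root; comparison is lexicographic on the fixed-width root,
#' which orders correctly within and across letter blocks.
#'
#' @param code character vector of ICD-10 codes.
#' @param map a \code{cause_map}; defaults to \code{default_cause_map()}.
#' @return for a single code, a character vector of cause labels; for a
#'   vector of codes, a list of such vectors.
#' @examples
#' classify_cause("I21")  # non-accidental, all CVD, IHD
#' @export
classify_cause <- function(code, map = default_cause_map()) {
  roots <- icd10_root(code)
  res <- lapply(roots, function(r) {
    unique(map$cause[map$lo <= r & r <= map$hi])
  })
  if (length(code) == 1L) res[[1L]] else res
}

# logical vector: does each root fall in `cause`'s range set?
# cause "*" means every root (all-cause models).
root_in_cause <- function(roots, cause, map) {
  if (identical(cause, "*")) return(rep(TRUE, length(roots)))
  sub <- as.data.frame(map)[map[["cause"]] == cause, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown cause: '", cause, "'")
  hit <- rep(FALSE, length(roots))
  for (i in seq_len(nrow(sub))) {
    hit <- hit | (sub$lo[i] <= roots & roots <= sub$hi[i])
  }
  hit
}

#' All three-character roots in a cause's ranges
#'
#' Enumerates the letter+digit roots covered by a cause; used when sampling
#' synthetic death codes uniformly over a cause's categories.
#'
#' @inheritParams classify_cause
#' @param cause cause label present in \code{map}.
#' @export
cause_roots <- function(cause, map = default_cause_map()) {
  all_roots <- as.vector(outer(LETTERS, sprintf("%02d", 0:99), paste0))
  all_roots <- sort(all_roots)
  all_roots[root_in_cause(all_roots, cause, map)]
}
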