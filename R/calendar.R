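#' Calendar month encoding
#'
#' Calendar months are stored as consecutive integers,
#' \code{year * 12 + month_of_year}, so that the difference of two encoded
#' months is the number of calendar months between them. \code{ym_to_month}
#' parses ISO "YYYY-MM" strings; \code{month_to_ym} formats the integer back.
#'
#' @param ym character vector of "YYYY-MM" strings.
#' @return integer vector of encoded months.
#' @export
ym_to_month <- function(ym) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", ym)
  if (!all(ok)) {
    stop("malformed month string(s): ", paste(ym[!ok], collapse = ", "))
  }
  yr <- as.integer(substr(ym, 1L, 4L))
  mo <- as.integer(substr(ym, 6L, 7L))
  yr * 12L + mo
}

#' @rdname ym_to_month
#' @param m integer vector of encoded months.
#' @export
month_to_ym <- function(m) {
  m <- as.integer(m)
  yr <- (m - 1L) %/% 12L
  mo <- m - yr * 12L
  sprintf("%04d-%02d", yr, mo)
}

#' @rdname ym_to_month
#' @export
month_year <- function(m) {
  (as.integer(m) - 1L) %/% 12L
}

#' @rdname ym_to_month
#' @export
month_of_year <- function(m) {
  m <- as.integer(m)
  m - ((m - 1L) %/% 12L) * 12L
}
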