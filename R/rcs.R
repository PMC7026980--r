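#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline with m knots and m-1 basis
#' columns, the first being the identity. For j = 1..m-2 the nonlinear
#' term is
#' \deqn{[(x-k_j)_+^3 - (x-k_{m-1})_+^3 (k_m-k_j)/(k_m-k_{m-1})
#'        + (x-k_m)_+^3 (k_{m-1}-k_j)/(k_m-k_{m-1})] / (k_m-k_1)^2,}
#' which is cubic between the boundary knots, exactly linear outside them
#' (the restriction), and zero at and below the first knot. Division by the
#' squared knot span puts every column on the exposure's own units, so
#' coefficients are comparable across knot choices; the fitted curve is
#' invariant to this normalization.
#'
#' @param x numeric exposure values.
#' @param knots strictly increasing numeric knots (3 to 5).
#' @return matrix with m-1 columns named "x", "x1", "x2", ...
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  m <- length(knots)
  if (m < 3L || m > 5L) stop("need 3 to 5 knots, got ", m)
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing: ",
         paste(signif(knots, 4), collapse = ", "))
  }
  cube <- function(u) pmax(u, 0)^3
  k1 <- knots[1L]; km1 <- knots[m - 1L]; km <- knots[m]
  norm <- (km - k1)^2
  out <- matrix(0, length(x), m - 1L)
  out[, 1L] <- x
  for (j in seq_len(m - 2L)) {
    kj <- knots[j]
    out[, j + 1L] <- (cube(x - kj) -
                        cube(x - km1) * (km - kj) / (km - km1) +
                        cube(x - km) * (km1 - kj) / (km - km1)) / norm
  }
  colnames(out) <- c("x", if (m > 2L) paste0("x", seq_len(m - 2L)))
  out
}

#' Default quantile knot placement
#'
#' Knots at empirical quantiles of the person-month exposure distribution:
#' (10, 50, 90) percent for 3 knots, (5, 35, 65, 95) for 4,
#' (5, 27.5, 50, 72.5, 95) for 5. The person-month (not beneficiary)
#' distribution is used because the partial likelihood weights
#' person-months.
#'
#' @param x numeric exposure values (person-month distribution).
#' @param m number of knots (3, 4 or 5).
#' @return numeric vector of knots.
#' @export
place_knots <- function(x, m = 3L) {
  probs <- switch(as.character(m),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    stop("m must be 3, 4 or 5"))
  if (sum(is.finite(x)) < m || length(unique(x[is.finite(x)])) < m) {
    stop("need at least ", m, " distinct exposure values to place knots")
  }
  k <- unname(quantile(x, probs, na.rm = TRUE, names = FALSE))
  if (any(diff(k) <= 0)) {
    stop("duplicate knots after quantile placement; ",
         "reduce the number of knots")
  }
  k
}

#' Append spline basis columns to a person-month table
#'
#' @param pm person-month table.
#' @param exposure exposure column name.
#' @param knots spline knots.
#' @return list: pm (with basis columns added), covariates (their names),
#'   knots.
#' @export
add_spline_terms <- function(pm, exposure = "pm25_12mo", knots) {
  pm <- as.data.table(pm)
  B <- rcs_basis(pm[[exposure]], knots)
  cols <- paste0(exposure, c("", paste0("_s", seq_len(ncol(B) - 1L))))
  for (j in seq_along(cols)) set(pm, j = cols[j], value = B[, j])
  list(pm = pm, covariates = cols, knots = knots)
}

#' Fit a restricted-cubic-spline Cox model
#'
#' Builds the spline basis on the person-month exposure, aggregates cells
#' on the expanded covariates and fits via \code{\link{fit_cox}}.
#'
#' @param pm person-month table from \code{\link{expand_person_months}}.
#' @param exposure exposure column.
#' @param knots knot vector, or NULL to place \code{m} knots at the default
#'   quantiles.
#' @param m number of knots when \code{knots} is NULL.
#' @param strata stratum columns.
#' @param extra_covariates additional adjustment covariate columns.
#' @param ... passed to \code{\link{fit_cox}}.
#' @return a \code{cox_fit} with attributes \code{knots} and
#'   \code{exposure}.
#' @export
fit_spline_model <- function(pm, exposure = "pm25_12mo", knots = NULL,
                             m = 3L, strata = c("age_cat", "sex", "race",
                                                "zip"),
                             extra_covariates = character(), ...) {
  if (is.null(knots)) knots <- place_knots(pm[[exposure]], m)
  sp <- add_spline_terms(pm, exposure, knots)
  cells <- aggregate_cells(sp$pm, strata = stratum_cols(sp$pm, strata),
                           covariates = c(sp$covariates, extra_covariates),
                           informative_only = TRUE)
  fit <- fit_cox(cells, ...)
  attr(fit, "knots") <- knots
  attr(fit, "exposure") <- exposure
  attr(fit, "spline_terms") <- sp$covariates
  fit
}

#' Exposure-response curve relative to a zero reference
#'
#' Risk ratio RR(x) = exp(sum_j b_j (b_j(x) - b_j(x_ref))) over an exposure
#' grid, with pointwise 95% CI from the delta method (g' Sigma g with
#' g = basis(x) - basis(x_ref)). The restriction makes the basis linear
#' below the first knot, so evaluation down to the 0 ug/m3 reference is a
#' well-defined linear-tail extrapolation.
#'
#' @param fit converged \code{cox_fit} from \code{\link{fit_spline_model}}
#'   (or a linear fit, in which case the curve is exactly log-linear).
#' @param grid numeric exposure grid.
#' @param x_ref reference exposure (default 0).
#' @param knots knots (defaults to the fit's).
#' @return \code{data.table} (exposure, rr, lo95, hi95) of class
#'   \code{rr_curve}.
#' @export
rr_curve <- function(fit, grid, x_ref = 0, knots = attr(fit, "knots")) {
  if (!isTRUE(fit$converged)) {
    stop("refusing to draw a curve from an unconverged fit")
  }
  terms <- attr(fit, "spline_terms")
  if (is.null(terms)) {   # linear fit: single exposure term
    terms <- names(fit$coefficients)[1L]
    G <- matrix(grid - x_ref, ncol = 1L)
  } else {
    G <- rcs_basis(grid, knots) - matrix(
      rcs_basis(x_ref, knots), nrow = length(grid),
      ncol = length(terms), byrow = TRUE)
  }
  b <- fit$coefficients[terms]
  Sg <- fit$vcov[terms, terms, drop = FALSE]
  lrr <- as.vector(G %*% b)
  se <- sqrt(pmax(0, rowSums((G %*% Sg) * G)))
  z <- qnorm(0.975)
  out <- data.table(exposure = grid, rr = exp(lrr),
                    lo95 = exp(lrr - z * se), hi95 = exp(lrr + z * se))
  setattr(out, "class", c("rr_curve", class(out)))
  setattr(out, "x_ref", x_ref)
  out[]
}

#' Compare spline models with 3, 4 and 5 knots
#'
#' Fits one restricted-cubic-spline model per candidate knot count and
#' ranks them by AIC on the partial likelihood (2k - 2 loglik). Ties in AIC
#' go to fewer knots; non-convergent candidates are excluded with a
#' warning.
#'
#' @param pm person-month table.
#' @param exposure exposure column.
#' @param m_list candidate knot counts.
#' @inheritParams fit_spline_model
#' @return \code{data.table} (m, k_params, loglik, aic, rank, converged)
#'   with attribute \code{"fits"} (the named list of fits) and
#'   \code{"selected"} (chosen m).
#' @export
compare_knot_counts <- function(pm, exposure = "pm25_12mo",
                                m_list = c(3L, 4L, 5L),
                                strata = c("age_cat", "sex", "race", "zip"),
                                extra_covariates = character(), ...) {
  fits <- list()
  rows <- list()
  for (m in m_list) {
    fit <- tryCatch(
      fit_spline_model(pm, exposure, knots = NULL, m = m, strata = strata,
                       extra_covariates = extra_covariates, ...),
      error = function(e) NULL)
    ok <- !is.null(fit) && isTRUE(fit$converged)
    if (!ok) {
      warning("spline model with ", m, " knots did not converge; excluded")
    } else {
      fits[[as.character(m)]] <- fit
    }
    k <- if (ok) length(fit$coefficients) else NA_integer_
    rows[[length(rows) + 1L]] <- data.table(
      m = m, k_params = k,
      loglik = if (ok) fit$loglik else NA_real_,
      aic = if (ok) 2 * k - 2 * fit$loglik else NA_real_,
      converged = ok)
  }
  tab <- rbindlist(rows)
  conv <- tab[converged == TRUE]
  if (nrow(conv) == 0L) stop("no candidate spline model converged")
  setorder(conv, aic, m)     # AIC ties to fewer knots
  tab[, rank := match(m, conv$m)]
  setattr(tab, "fits", fits)
  setattr(tab, "selected", conv$m[1L])
  tab[]
}

#' Wald test of the nonlinear spline component
#'
#' Joint Wald chi-square test that all nonlinear spline coefficients are
#' zero; with 3 knots this is a one-degree-of-freedom test of departure
#' from log-linearity.
#'
#' @param fit a converged spline \code{cox_fit}.
#' @return named numeric: chisq, df, p.
#' @export
nonlinearity_test <- function(fit) {
  terms <- attr(fit, "spline_terms")
  if (is.null(terms) || length(terms) < 2L) {
    stop("fit has no nonlinear spline terms")
  }
  nl <- terms[-1L]
  b <- fit$coefficients[nl]
  V <- fit$vcov[nl, nl, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  df <- length(nl)
  c(chisq = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
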