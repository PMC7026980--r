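# Small synthetic worlds shared across test files. Built lazily and cached
# per test run so repeated tests do not pay for regeneration.

.world_cache <- new.env(parent = emptyenv())

tiny_study <- function(seed = 101, n = 600L, zips = 5L, months = 36L,
                       hazard = 0.01, rr = NULL, ...) {
  key <- paste("w", seed, n, zips, months, hazard,
               paste(deparse(rr), collapse = ""), sep = "_")
  extra <- list(...)
  if (length(extra)) {
    key <- paste(key, paste(names(extra), vapply(extra, function(x)
      paste(deparse(x), collapse = ""), ""), collapse = "_"), sep = "_")
  }
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  args <- c(list(n_beneficiaries = n, n_zips = zips, n_months = months,
                 base_hazard_65 = hazard), extra)
  if (!is.null(rr)) args$uniform_rr_per10 <- rr
  cfg <- do.call(sim_config, args)
  st <- simulate_study(cfg, seed = seed)
  st$expo <- person_exposure_12mo(st$cohort, st$residence,
                                  st$exposures$pm25)
  .world_cache[[key]] <- st
  st
}

# one random small cohort expanded for all-cause death, for engine tests
tiny_pm <- function(seed = 101, cause = "*", ...) {
  st <- tiny_study(seed = seed, ...)
  expand_person_months(st$cohort, st$residence, st$expo, cause = cause)
}

# independent restricted-cubic-spline evaluation, written directly from the
# truncated-power definition (scalar, loop-based: deliberately unlike the
# vectorised implementation it checks)
rcs_reference <- function(x, knots) {
  m <- length(knots)
  k1 <- knots[1]; km1 <- knots[m - 1]; km <- knots[m]
  out <- matrix(NA_real_, length(x), m - 1)
  pp <- function(u) if (u > 0) u^3 else 0
  for (i in seq_along(x)) {
    out[i, 1] <- x[i]
    for (j in seq_len(m - 2)) {
      kj <- knots[j]
      out[i, j + 1] <- (pp(x[i] - kj) -
                          pp(x[i] - km1) * (km - kj) / (km - km1) +
                          pp(x[i] - km) * (km1 - kj) / (km - km1)) /
        (km - k1)^2
    }
  }
  out
}
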