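#' Great-circle distance
#'
#' Haversine distance in kilometres between points given in decimal degrees.
#' Vectorised over both point sets (recycled).
#'
#' @param lat1,lon1,lat2,lon2 numeric degrees.
#' @return numeric kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Match ZIP centroids to the nearest exposure grid point
#'
#' Each ZIP code is linked to the great-circle-nearest grid point; exact
#' distance ties break to the lexicographically smaller grid identifier so
#' the matching is deterministic.
#'
#' @param centroids \code{data.table} with columns zip, lat, lon.
#' @param grid \code{data.table} with columns grid_id, lat, lon.
#' @return \code{data.table} with columns zip, grid_id, dist_km.
#' @export
match_to_grid <- function(centroids, grid) {
  ce <- as.data.table(centroids)
  gr <- as.data.table(grid)
  if (nrow(gr) == 0L) stop("empty exposure grid")
  gr <- gr[order(as.character(grid_id))]
  out <- ce[, {
    d <- haversine_km(lat, lon, gr$lat, gr$lon)
    i <- which.min(d)  # first minimum = smallest grid_id among ties
    list(grid_id = gr$grid_id[i], dist_km = d[i])
  }, by = zip]
  out
}

#' Trailing 12-month moving average
#'
#' Mean of months t-11 ... t of a monthly series; the first 11 positions are
#' NA. The current month is included in its own window, so the covariate is
#' defined for every at-risk month, not only the death month.
#'
#' @param x numeric monthly series in calendar order.
#' @return numeric vector of the same length.
#' @export
moving_average_12 <- function(x) {
  frollmean(as.numeric(x), 12L, align = "right")
}

#' Per-person 12-month exposure following residential moves
#'
#' Builds each beneficiary's monthly exposure path from the residence
#' history (months before the first recorded segment use that segment's
#' ZIP), then takes the trailing 12-month mean, so a window that crosses a
#' move averages each month's then-current residence. Months whose window is
#' not fully covered by the surface yield NA and are excluded from risk sets
#' downstream (the exclusion is logged by the expansion step).
#'
#' @param cohort cohort table (id, entry_month, end_month, ...).
#' @param residence residence table (id, start_month, zip).
#' @param surface long exposure table (zip, month, value) of monthly means.
#' @param col name for the output column.
#' @return \code{data.table} (id, month, <col>) for months entry..end.
#' @export
person_exposure_12mo <- function(cohort, residence, surface,
                                 col = "pm25_12mo") {
  co <- copy(as.data.table(cohort))
  re <- copy(as.data.table(residence))
  su <- copy(as.data.table(surface))
  setnames(su, names(su)[1:3], c("zip", "month", "value"))
  setorder(co, id)
  setorder(re, id, start_month)

  # ZIP x month matrix of trailing 12-month means (stationary residents
  # read their windows straight off it)
  setorder(su, zip, month)
  su[, v12 := frollmean(value, 12L, align = "right"), by = zip]
  zl <- sort(unique(su$zip))
  ml <- seq.int(min(su$month), max(su$month))
  M12 <- matrix(NA_real_, length(zl), length(ml))
  M12[cbind(match(su$zip, zl), su$month - ml[1L] + 1L)] <- su$v12
  Mraw <- matrix(NA_real_, length(zl), length(ml))
  Mraw[cbind(match(su$zip, zl), su$month - ml[1L] + 1L)] <- su$value
  su[, v12 := NULL]

  mcol <- function(m) {           # column index with out-of-range -> NA
    i <- m - ml[1L] + 1L
    i[i < 1L | i > length(ml)] <- NA_integer_
    i
  }

  n_seg <- re[, .N, by = id]
  movers <- n_seg[N > 1L, id]
  stay <- setdiff(co$id, movers)

  out_stay <- NULL
  if (length(stay)) {
    cs <- co[id %in% stay]
    zi <- re[id %in% stay][, list(zip = zip[1L]), by = id]
    cs <- merge(cs, zi, by = "id", sort = TRUE)
    lens <- cs$end_month - cs$entry_month + 1L
    mon <- sequence(lens, from = cs$entry_month)
    zidx <- rep(match(cs$zip, zl), times = lens)
    out_stay <- data.table(id = rep(cs$id, times = lens), month = mon)
    out_stay[, (col) := M12[cbind(zidx, mcol(mon))]]
  }

  out_move <- NULL
  if (length(movers)) {
    cm <- co[id %in% movers]
    lens <- cm$end_month - cm$entry_month + 12L   # incl. 11 lead-in months
    grid <- data.table(id = rep(cm$id, times = lens),
                       month = sequence(lens, from = cm$entry_month - 11L))
    re2 <- re[id %in% movers, list(id, month = start_month, zip)]
    setkey(re2, id, month)
    setkey(grid, id, month)
    grid <- re2[grid, roll = Inf]
    # months before the first recorded segment use that segment's ZIP
    grid[, zip := {
      z <- zip
      if (anyNA(z)) z[is.na(z)] <- z[which(!is.na(z))[1L]]
      z
    }, by = id]
    grid[, value := Mraw[cbind(match(zip, zl), mcol(month))]]
    setorder(grid, id, month)
    grid[, (col) := frollmean(value, 12L, align = "right"), by = id]
    ent <- cm[, list(id, entry_month)]
    grid <- merge(grid, ent, by = "id")
    out_move <- grid[month >= entry_month, c("id", "month", col),
                     with = FALSE]
  }
  out <- rbind(out_stay, out_move)
  setkey(out, id, month)
  out[]
}

#' Warm-season ozone averages
#'
#' Mean of daily 1-h maximum ozone over the warm season (April-September)
#' per location and year. Years with more than 25% of warm-season days
#' missing are returned as NA (a missing-ozone signal).
#'
#' @param daily \code{data.table} with columns zip, year, doy (day of year),
#'   value (daily 1-h max, ppb).
#' @param warm_months integer months defining the warm season.
#' @param max_missing maximum tolerated fraction of missing days.
#' @return \code{data.table} (zip, year, o3_warm).
#' @export
warm_season_ozone <- function(daily, warm_months = 4:9, max_missing = 0.25) {
  dd <- as.data.table(daily)
  stopifnot(all(c("zip", "year", "doy", "value") %in% names(dd)))
  # day-of-year bounds of the warm season (non-leap convention)
  cum <- cumsum(c(0L, 31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L))
  lo <- cum[min(warm_months)] + 1L
  hi <- cum[max(warm_months) + 1L]
  n_days <- hi - lo + 1L
  dd <- dd[doy >= lo & doy <= hi & !is.na(value)]
  out <- dd[, list(o3_warm = mean(value), n_obs = .N), by = list(zip, year)]
  out[n_obs < (1 - max_missing) * n_days, o3_warm := NA_real_]
  out[, n_obs := NULL]
  out[]
}

#' Restrict to ZIP codes below a mean exposure threshold
#'
#' Returns the ZIP codes whose study-period mean exposure is strictly below
#' the threshold; thresholds of 8, 10 and 12 ug/m3 give nested sets, the
#' basis of the low-exposure restriction analyses.
#'
#' @param zip_means \code{data.table} (zip, zip_mean) of study-period means.
#' @param threshold numeric threshold.
#' @return vector of retained ZIP codes.
#' @export
restrict_low_pm <- function(zip_means, threshold) {
  zm <- as.data.table(zip_means)
  setnames(zm, names(zm)[1:2], c("zip", "zip_mean"))
  zm[zip_mean < threshold, zip]
}

#' ZIP codes within a radius of any monitor
#'
#' Great-circle filter retaining ZIP codes whose centroid lies within
#' \code{radius_miles} of at least one monitoring site; used to define the
#' subset eligible for ozone-adjusted models.
#'
#' @param centroids \code{data.table} (zip, lat, lon).
#' @param monitors \code{data.table} (lat, lon).
#' @param radius_miles numeric radius, default 6 miles.
#' @return vector of retained ZIP codes.
#' @export
monitor_subset <- function(centroids, monitors, radius_miles = 6) {
  ce <- as.data.table(centroids)
  mo <- as.data.table(monitors)
  if (nrow(ce) == 0L || nrow(mo) == 0L) stop("empty location set")
  radius_km <- radius_miles * 1.609344
  keep <- vapply(seq_len(nrow(ce)), function(i) {
    any(haversine_km(ce$lat[i], ce$lon[i], mo$lat, mo$lon) <= radius_km)
  }, logical(1L))
  ce$zip[keep]
}
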