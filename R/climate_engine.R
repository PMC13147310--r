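#' Mean extraterrestrial radiation for a month
#'
#' FAO-56 solar geometry evaluated at the mid-month Julian day
#' (J = round(30.4 m - 15.2)), returning Ra in MJ m-2 day-1.
#'
#' @param lat latitude in decimal degrees, inside (-66.5, 66.5).
#' @param month calendar month 1-12.
#' @return mean daily extraterrestrial radiation (MJ m-2 d-1).
#' @export
extraterrestrial_radiation <- function(lat, month) {
  if (any(abs(lat) >= 66.5)) stop("polar latitudes not supported")
  if (any(month < 1 | month > 12)) stop("month out of range")
  J <- round(30.4 * month - 15.2)
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  gsc <- 0.0820 # MJ m-2 min-1
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

days_in_month <- function(month) {
  c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month]
}

#' Monthly potential evapotranspiration (modified Hargreaves)
#'
#' Daily PET = 0.0013 * 0.408 * Ra * (Tavg + 17) * max(TD - 0.0123 P, 0)^0.76
#' with Ra the mean monthly extraterrestrial radiation (MJ m-2 d-1), Tavg and
#' TD the mean and diurnal range of temperature (degC) and P the monthly
#' precipitation total (mm). Monthly PET is the daily value times the number
#' of days in the month; negative values are clamped to zero.
#'
#' @param tmin_c,tmax_c monthly mean minimum/maximum temperature (degC).
#' @param prec_mm monthly precipitation total (mm).
#' @param lat latitude (decimal degrees).
#' @param month calendar month 1-12 (vectorised with the temperatures).
#' @return monthly PET in mm (>= 0).
#' @export
monthly_pet_hargreaves <- function(tmin_c, tmax_c, prec_mm, lat, month) {
  if (any(tmax_c < tmin_c)) stop("tmax < tmin")
  if (any(prec_mm < 0)) stop("negative precipitation")
  ra <- extraterrestrial_radiation(lat, month)
  tavg <- (tmin_c + tmax_c) / 2
  td <- tmax_c - tmin_c
  daily <- 0.0013 * 0.408 * ra * (tavg + 17) * pmax(td - 0.0123 * prec_mm, 0)^0.76
  pmax(daily, 0) * days_in_month(month)
}

#' Add PET and climatic water balance columns to a monthly climate table
#'
#' @param climate data frame with columns `stand_id`, `year`, `month`,
#'   `tmin_c`, `tmax_c`, `prec_mm`, `lat`.
#' @return the table with `pet_mm` and `cwb_mm = prec_mm - pet_mm` appended.
#' @export
compute_cwb <- function(climate) {
  req <- c("stand_id", "year", "month", "tmin_c", "tmax_c", "prec_mm", "lat")
  miss <- setdiff(req, names(climate))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  climate$pet_mm <- monthly_pet_hargreaves(climate$tmin_c, climate$tmax_c,
                                           climate$prec_mm, climate$lat,
                                           climate$month)
  climate$cwb_mm <- climate$prec_mm - climate$pet_mm
  climate
}

#' Month membership of a named seasonal window
#'
#' Windows follow the dendroclimatological convention relative to the ring
#' formation year: `winter` = previous December to current February,
#' `spring` = March-May, `summer` = June-August, `gs` (growing season) =
#' April-September, `p_summer` = previous June-August. Individual months are
#' addressed as `curr_<m>` or `prev_<m>`.
#'
#' @param season window name.
#' @return data frame with columns `month` and `offset` (0 = current year,
#'   -1 = year before ring formation).
#' @export
season_months <- function(season) {
  season <- tolower(season)
  if (grepl("^curr_\\d+$", season)) {
    m <- as.integer(sub("curr_", "", season))
    return(data.frame(month = m, offset = 0L))
  }
  if (grepl("^prev_\\d+$", season)) {
    m <- as.integer(sub("prev_", "", season))
    return(data.frame(month = m, offset = -1L))
  }
  switch(season,
    winter   = data.frame(month = c(12, 1, 2), offset = c(-1L, 0L, 0L)),
    spring   = data.frame(month = 3:5, offset = 0L),
    summer   = data.frame(month = 6:8, offset = 0L),
    gs       = data.frame(month = 4:9, offset = 0L),
    p_summer = data.frame(month = 6:8, offset = -1L),
    stop("unknown season: ", season)
  )
}

#' Seasonal aggregation of a monthly climate table
#'
#' Temperatures are averaged over the window's months; water-balance (and
#' precipitation) totals are summed by default (`fun = "sum"`), with
#' `fun = "mean"` exposed. Years whose window reaches into an absent prior
#' year are dropped.
#'
#' @param climate monthly table (after [compute_cwb()] for CWB windows).
#' @param variable one of `"tmin"`, `"tmax"`, `"cwb"`, `"prec"`, `"pet"`.
#' @param season window name understood by [season_months()].
#' @param fun aggregation for water variables, `"sum"` (default) or `"mean"`.
#' @return data frame `stand_id`, `year`, `season`, `variable`, `value`.
#' @export
seasonal_aggregate <- function(climate, variable, season, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  col <- switch(variable,
                tmin = "tmin_c", tmax = "tmax_c", cwb = "cwb_mm",
                prec = "prec_mm", pet = "pet_mm",
                stop("unknown variable: ", variable))
  if (!col %in% names(climate)) stop("column ", col, " absent; run compute_cwb() first?")
  sm <- season_months(season)
  agg_fun <- if (variable %in% c("tmin", "tmax")) mean else switch(fun, sum = sum, mean = mean)
  out <- list()
  for (sid in unique(climate$stand_id)) {
    cs <- climate[climate$stand_id == sid, ]
    years <- sort(unique(cs$year))
    idx <- paste(cs$year, cs$month)
    vals <- vapply(years, function(y) {
      keys <- paste(y + sm$offset, sm$month)
      pos <- match(keys, idx)
      if (anyNA(pos)) return(NA_real_)
      agg_fun(cs[[col]][pos])
    }, numeric(1))
    keep <- !is.na(vals)
    if (any(!keep & years > min(years))) {
      warning("stand ", sid, ": ", sum(!keep & years > min(years)),
              " year(s) dropped for missing months in window '", season, "'")
    }
    out[[sid]] <- data.frame(stand_id = sid, year = years[keep],
                             season = season, variable = variable,
                             value = vals[keep])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Like-for-like detrending of a seasonal climate series
#'
#' Removes low-frequency variation with the same frequency-cutoff spline
#' used for ring-width standardization (difference form, so negative water
#' balances remain legal).
#'
#' @param x data frame from [seasonal_aggregate()] (single stand/variable
#'   combinations are detrended independently).
#' @param nyrs,f spline cutoff parameters passed to [cps_spline()].
#' @return input with a `detrended_value` column (value minus spline fit).
#' @export
detrend_climate <- function(x, nyrs = 10, f = 0.5) {
  key <- interaction(x$stand_id, x$variable, x$season, drop = TRUE)
  x$detrended_value <- NA_real_
  for (k in levels(key)) {
    i <- which(key == k)
    i <- i[order(x$year[i])]
    if (length(i) < 20) stop("series shorter than 20 years for ", k)
    x$detrended_value[i] <- x$value[i] - cps_spline(x$value[i], nyrs = nyrs, f = f)
  }
  x
}

#' Classify stands as summer-mesic or summer-xeric
#'
#' Takes the first principal component of the centred/scaled stand-by-year
#' summer climatic water balance matrix over the analysis period, orients
#' it so that higher mean summer CWB scores positive, and splits stands by
#' the sign of their score: positive = mesic, negative (or zero) = xeric.
#' Working on the full stand-by-year matrix (rather than a few summary
#' statistics) keeps the split driven by the persistent moisture contrast
#' between stands even when other summer variables are uninformative.
#'
#' @param climate monthly climate table including `pet_mm`/`cwb_mm`, or a
#'   precomputed stand-by-year numeric matrix of summer CWB.
#' @param period two-element year range used for the classification
#'   (default `c(1980, 2020)`).
#' @return data frame `stand_id`, `pc1`, `gradient` (factor mesic/xeric).
#' @export
classify_gradient <- function(climate, period = c(1980, 2020)) {
  if (is.matrix(climate)) {
    m <- climate
  } else {
    cwb <- seasonal_aggregate(climate, "cwb", "summer")
    cwb <- cwb[cwb$year >= period[1] & cwb$year <= period[2], ]
    stands <- sort(unique(cwb$stand_id))
    years <- sort(unique(cwb$year))
    m <- matrix(NA_real_, length(stands), length(years),
                dimnames = list(stands, years))
    m[cbind(match(cwb$stand_id, stands), match(cwb$year, years))] <- cwb$value
  }
  if (ncol(m) < 10) stop("need >= 10 years in the period")
  if (nrow(m) < 2) stop("need >= 2 stands")
  if (anyNA(m)) stop("incomplete summer CWB matrix")
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate climate matrix: stands identical")
  pc <- run_pca(m[, sds > 0, drop = FALSE], n_components = 1)
  score <- pc$scores[, 1]
  # orient: wetter summers (higher mean CWB) on the positive, mesic side
  if (stats::cor(score, rowMeans(m)) < 0) score <- -score
  data.frame(stand_id = rownames(m), pc1 = as.numeric(score),
             gradient = factor(ifelse(score > 0, "mesic", "xeric"),
                               levels = c("mesic", "xeric")),
             row.names = NULL)
}
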