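#' Default demographic-group climate sensitivities
#'
#' Coefficients (per SD of the seasonal climate anomaly, on the log-BAI
#' scale) for the four quantile-corner demographic groups, nested by
#' gradient type: xeric growth is driven by prior-summer maximum
#' temperature and water balance (stronger in large trees), mesic growth by
#' current spring and summer conditions (moisture in small trees, summer
#' heat in large ones). A flat group -> coefficients map (no gradient
#' nesting) is also accepted by [generate_network()].
#'
#' @return named list gradient -> group -> named coefficient vector.
#' @export
default_group_sensitivity <- function() {
  list(
    mesic = list(
      l_o = c(tmax_summer = -0.25, tmin_spring = 0.15),
      l_y = c(tmax_summer = -0.20, cwb_spring = 0.10),
      s_o = c(cwb_spring = 0.25),
      s_y = c(cwb_spring = 0.20),
      none = c()
    ),
    xeric = list(
      l_o = c(tmax_p_summer = -0.30),
      l_y = c(tmax_p_summer = -0.25),
      s_o = c(cwb_spring = 0.25),
      s_y = c(cwb_spring = 0.15),
      none = c()
    )
  )
}

#' Default post-drought growth legacies by gradient type
#'
#' Multi-year negative ring-width-index departures after severe summer
#' droughts are imposed in xeric regions only.
#'
#' @return named list gradient -> named vector of departures by lag "0".."3".
#' @export
default_drought_legacy <- function() {
  list(
    mesic = c("0" = 0, "1" = 0, "2" = 0, "3" = 0),
    xeric = c("0" = -0.02, "1" = -0.06, "2" = -0.06, "3" = -0.06)
  )
}

#' Default post-onset growth trends by demographic class
#'
#' Log-BAI slopes (per year after the warming onset): gains in small
#' young/mid-aged trees, declines in mid-sized and large young trees,
#' weaker signals in the oldest cohorts.
#'
#' @return named list "age|size" -> slope.
#' @export
default_class_trend <- function() {
  tr <- list()
  for (a in c("<100", "100-199", "200-299", "300+")) {
    for (s in c("10-39", "40-60", "60+")) {
      key <- paste(a, s, sep = "|")
      tr[[key]] <- 0
      if (a %in% c("<100", "100-199")) {
        tr[[key]] <- if (s == "10-39") 0.003 else -0.004
      } else if (a == "200-299" && s == "60+") {
        tr[[key]] <- -0.002
      } else if (a == "300+") {
        tr[[key]] <- if (s == "10-39") 0.002 else if (s == "60+") -0.002 else 0
      }
    }
  }
  tr
}

#' Configuration of a synthetic tree-ring network
#'
#' Bundles and validates all generating parameters: network layout, study
#' span, warming onset, demographic climate sensitivities, drought-legacy
#' departures, class growth trends and noise levels. The defaults are the
#' study conditions used throughout the package's validation: a 1940-2020
#' span, warming from 1980, three network-wide summer droughts, and the
#' sensitivity/legacy/trend structure of [default_group_sensitivity()],
#' [default_drought_legacy()] and [default_class_trend()].
#'
#' @param n_regions_per_gradient regions per gradient type (mesic, xeric).
#' @param n_stands_per_region stands per region.
#' @param n_trees_per_stand cored trees per stand.
#' @param year_span two calendar years, first and last (span >= 60 yr).
#' @param warming_onset calendar year when the warming ramp starts.
#' @param drought_years network-wide severe summer drought years.
#' @param group_sensitivity,drought_legacy,class_trend effect maps (see the
#'   `default_*` helpers).
#' @param size_exponent allometric exponent b in log BAI = a + b log D.
#' @param noise_sd SD of the log-BAI residual.
#' @param gamma_sd between-tree SD of each sensitivity coefficient.
#' @param sy_legacy_attenuation multiplier on drought legacies for the s_y
#'   group (its post-drought deviations are weaker).
#' @param warming_trend_c_per_decade temperature trend after onset.
#' @param seed integer seed controlling the whole network.
#' @return object of class `dd_config`.
#' @export
network_config <- function(n_regions_per_gradient = 2,
                           n_stands_per_region = 4,
                           n_trees_per_stand = 30,
                           year_span = c(1940, 2020),
                           warming_onset = 1980,
                           drought_years = c(1976, 1993, 2003),
                           group_sensitivity = default_group_sensitivity(),
                           drought_legacy = default_drought_legacy(),
                           class_trend = default_class_trend(),
                           size_exponent = 1.6,
                           noise_sd = 0.25,
                           gamma_sd = 0.05,
                           sy_legacy_attenuation = 0.5,
                           warming_trend_c_per_decade = 0.4,
                           seed = 1L) {
  stopifnot(n_regions_per_gradient >= 1, n_stands_per_region >= 1,
            n_trees_per_stand >= 1)
  if (diff(year_span) + 1 < 60) stop("year span must cover at least 60 years")
  for (g in names(drought_legacy)) {
    lags <- as.integer(names(drought_legacy[[g]]))
    if (!all(lags %in% 0:3)) stop("drought legacy lags must be within 0..3")
  }
  if (any(drought_years < year_span[1] | drought_years > year_span[2])) {
    stop("drought years outside the study span")
  }
  structure(list(
    n_regions_per_gradient = n_regions_per_gradient,
    n_stands_per_region = n_stands_per_region,
    n_trees_per_stand = n_trees_per_stand,
    year_span = year_span, warming_onset = warming_onset,
    drought_years = drought_years,
    group_sensitivity = group_sensitivity,
    drought_legacy = drought_legacy, class_trend = class_trend,
    size_exponent = size_exponent, noise_sd = noise_sd,
    gamma_sd = gamma_sd, sy_legacy_attenuation = sy_legacy_attenuation,
    warming_trend_c_per_decade = warming_trend_c_per_decade,
    seed = as.integer(seed)), class = "dd_config")
}

#' Default regional climate parameters along the moisture gradient
#'
#' Monthly climatologies emulate montane central-European beech sites:
#' mesic regions are cooler with wet summers, xeric regions warmer with a
#' pronounced summer precipitation minimum.
#'
#' @param gradient `"mesic"` or `"xeric"`.
#' @param lat latitude (decimal degrees) of the region.
#' @return list of climatology vectors and stochastic settings consumed by
#'   [generate_climate()].
#' @export
default_region_params <- function(gradient = c("mesic", "xeric"), lat = NULL) {
  gradient <- match.arg(gradient)
  if (gradient == "mesic") {
    list(gradient = gradient, lat = if (is.null(lat)) 49.0 else lat,
         tmax = c(0, 2, 7, 13, 18, 21, 23, 23, 18, 12, 5, 1),
         tmin = c(-6, -5, -2, 2, 7, 10, 12, 12, 8, 4, -1, -5),
         prec = c(60, 55, 65, 75, 95, 130, 135, 125, 85, 70, 70, 65),
         rho = 0.3, temp_anom_sd = 1.5, prec_lsd = 0.35, stand_temp_sd = 0.2)
  } else {
    list(gradient = gradient, lat = if (is.null(lat)) 43.0 else lat,
         tmax = c(4, 6, 10, 15, 20, 24, 27, 27, 21, 15, 9, 5),
         tmin = c(-4, -3, 0, 4, 8, 12, 14, 14, 10, 6, 1, -3),
         prec = c(90, 80, 75, 70, 65, 75, 60, 55, 65, 90, 110, 100),
         rho = 0.3, temp_anom_sd = 1.5, prec_lsd = 0.35, stand_temp_sd = 0.2)
  }
}

#' Generate monthly climate for one region's stands
#'
#' Monthly temperature anomalies follow a shared regional AR(1) process with
#' small stand-level noise; precipitation is climatology times shared
#' lognormal anomalies. A linear warming ramp is applied to Tmin and Tmax
#' after the onset year. Imposed drought years have their summer (JJA)
#' precipitation scaled down, iteratively, until the summer climatic water
#' balance z-score (over the full span) is at or below -1.5 in every stand.
#'
#' @param region_params list from [default_region_params()].
#' @param stand_ids character vector of stand identifiers.
#' @param year_span two-element year range.
#' @param warming_onset onset year of the temperature ramp.
#' @param warming_trend_c_per_decade ramp slope (degC per decade).
#' @param drought_years years forced to severe summer drought (may be empty).
#' @param seed integer seed.
#' @return monthly climate table (with `pet_mm`, `cwb_mm`).
#' @export
generate_climate <- function(region_params, stand_ids, year_span,
                             warming_onset = 1980,
                             warming_trend_c_per_decade = 0.4,
                             drought_years = integer(), seed = 1L) {
  rp <- region_params
  if (rp$rho >= 1) stop("AR coefficient rho must be < 1")
  if (rp$rho < 0 || rp$rho > 0.8) stop("rho must lie in [0, 0.8]")
  if (length(drought_years) &&
      any(drought_years < year_span[1] | drought_years > year_span[2])) {
    stop("drought years outside year span")
  }
  set.seed(as.integer(seed))
  years <- seq(year_span[1], year_span[2])
  ny <- length(years)
  nm <- ny * 12
  # shared regional anomalies (AR(1) over consecutive months)
  t_anom <- as.numeric(stats::arima.sim(list(ar = max(rp$rho, 1e-8)), nm,
                                        sd = rp$temp_anom_sd * sqrt(1 - rp$rho^2)))
  p_anom <- exp(as.numeric(stats::arima.sim(list(ar = max(rp$rho, 1e-8)), nm,
                                            sd = rp$prec_lsd * sqrt(1 - rp$rho^2))) -
                rp$prec_lsd^2 / 2)
  grid <- data.frame(year = rep(years, each = 12), month = rep(1:12, ny))
  ramp <- pmax(0, grid$year - warming_onset) / 10 * warming_trend_c_per_decade
  drought_mult <- rep(1, nm) # per-month precipitation multiplier for droughts
  jja_drought <- grid$month %in% 6:8 & grid$year %in% drought_years
  out <- vector("list", length(stand_ids))
  stand_noise <- lapply(stand_ids, function(s) stats::rnorm(nm, 0, rp$stand_temp_sd))
  names(stand_noise) <- stand_ids
  build <- function(mult) {
    res <- vector("list", length(stand_ids))
    for (i in seq_along(stand_ids)) {
      s <- stand_ids[i]
      tmax <- rp$tmax[grid$month] + t_anom + ramp + stand_noise[[s]]
      tmin <- rp$tmin[grid$month] + t_anom + ramp + stand_noise[[s]]
      tmin <- pmin(tmin, tmax - 0.5) # diurnal range stays positive
      prec <- rp$prec[grid$month] * p_anom * mult
      res[[i]] <- data.frame(stand_id = s, year = grid$year, month = grid$month,
                             tmin_c = as.numeric(sprintf("%.2f", tmin)),
                             tmax_c = as.numeric(sprintf("%.2f", tmax)),
                             prec_mm = as.numeric(sprintf("%.1f", pmax(prec, 0))),
                             lat = rp$lat)
    }
    compute_cwb(do.call(rbind, res))
  }
  mult <- drought_mult
  mult[jja_drought] <- 0.35
  clim <- build(mult)
  if (length(drought_years)) {
    for (iter in 1:50) {
      cwb <- seasonal_aggregate(clim, "cwb", "summer")
      ok <- vapply(drought_years, function(dy) {
        all(vapply(stand_ids, function(s) {
          v <- cwb$value[cwb$stand_id == s]
          y <- cwb$year[cwb$stand_id == s]
          (v[y == dy] - mean(v)) / stats::sd(v) <= -1.5
        }, logical(1)))
      }, logical(1))
      if (all(ok)) break
      mult[jja_drought] <- mult[jja_drought] * 0.7
      clim <- build(mult)
      if (iter == 50) stop("could not force drought z-scores below -1.5")
    }
  }
  clim
}

# per-stand z-scored seasonal predictors used by the growth model
climate_zscores <- function(climate) {
  vars <- list(tmax_p_summer = c("tmax", "p_summer"),
               cwb_p_summer  = c("cwb", "p_summer"),
               cwb_spring    = c("cwb", "spring"),
               cwb_summer    = c("cwb", "summer"),
               tmax_summer   = c("tmax", "summer"),
               tmin_spring   = c("tmin", "spring"))
  stands <- unique(climate$stand_id)
  out <- list()
  for (s in stands) {
    cs <- climate[climate$stand_id == s, ]
    years <- sort(unique(cs$year))
    z <- matrix(0, length(years), length(vars),
                dimnames = list(years, names(vars)))
    for (v in names(vars)) {
      agg <- seasonal_aggregate(cs, vars[[v]][1], vars[[v]][2])
      zi <- (agg$value - mean(agg$value)) / stats::sd(agg$value)
      z[match(agg$year, years), v] <- zi
    }
    out[[s]] <- z
  }
  out
}

age_bins <- list("<100" = c(25, 95), "100-199" = c(100, 195),
                 "200-299" = c(200, 295), "300+" = c(300, 440))
# target ranges leave a margin inside each class so that growth noise on the
# realized DBH does not push trees across the 40/60 cm boundaries
size_bins <- list("10-39" = c(12, 37), "40-60" = c(42, 58), "60+" = c(63, 90))
# quantile-corner group implied by the (age bin, size bin) cell
cell_group <- function(ab, sb) {
  if (ab == "<100" && sb == "10-39") return("s_y")
  if (ab == "<100" && sb == "60+") return("l_y")
  if (ab == "300+" && sb == "10-39") return("s_o")
  if (ab == "300+" && sb == "60+") return("l_o")
  "none"
}

# deterministic growth recursion used to calibrate the tree intercept
sim_det_final_d <- function(a, b, d0, n) {
  A <- pi * d0^2 / 4
  d <- d0
  ea <- exp(a)
  for (t in seq_len(n)) {
    A <- A + ea * d^b
    d <- sqrt(4 * A / pi)
  }
  d
}

calibrate_intercept <- function(b, d0, n, target_dbh) {
  lo <- -10; hi <- 5
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (sim_det_final_d(mid, b, d0, n) < target_dbh) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate one tree's ring-width series
#'
#' Multiplicative growth model on basal area increment:
#' log BAI_t = a + b log D_(t-1) + gamma' z_t + delta(lag) 1\[drought at
#' t-lag\] + theta max(0, t - onset) + eps_t, with ring width recovered from
#' the circular cross-section geometry. Widths are reported in mm at the
#' 0.01 mm measurement precision; the returned `dbh_cm` is exactly twice the
#' radius reconstructed from the reported widths plus the seedling core.
#'
#' @param age rings in the series (series ends at the last climate year).
#' @param target_dbh approximate DBH (cm) the intercept is calibrated to.
#' @param gamma named sensitivity vector (columns of the z matrix).
#' @param theta post-onset log-BAI trend per year.
#' @param delta named drought-legacy vector (lags "0".."3").
#' @param zmat stand z-score matrix from the climate (rows named by year).
#' @param drought_years drought event years.
#' @param config `dd_config` (uses `size_exponent`, `noise_sd`,
#'   `warming_onset`, `year_span`).
#' @param seed optional seed (otherwise uses the current RNG stream).
#' @return list with `tree_id`-free fields: `first_year`, `widths` (mm),
#'   `dbh_cm`, `age`.
#' @export
simulate_tree <- function(age, target_dbh, gamma, theta, delta, zmat,
                          drought_years, config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  last <- config$year_span[2]
  first <- last - age + 1
  if (first >= last - 20) stop("recruitment year too close to the end of the span")
  yrs <- seq(first, last)
  d0 <- 0.5
  b <- config$size_exponent
  a <- calibrate_intercept(b, d0, age, target_dbh)
  eff <- stats::rnorm(age, 0, config$noise_sd)
  zyears <- as.integer(rownames(zmat))
  hit <- match(yrs, zyears)
  if (length(gamma) && any(!is.na(hit))) {
    zz <- zmat[hit[!is.na(hit)], names(gamma), drop = FALSE]
    eff[!is.na(hit)] <- eff[!is.na(hit)] + as.numeric(zz %*% gamma)
  }
  if (length(delta)) {
    for (lag in as.integer(names(delta))) {
      pos <- match(drought_years + lag, yrs)
      pos <- pos[!is.na(pos)]
      eff[pos] <- eff[pos] + delta[[as.character(lag)]]
    }
  }
  eff <- eff + theta * pmax(0, yrs - config$warming_onset)
  A <- pi * d0^2 / 4
  d <- d0
  dtraj <- numeric(age)
  for (t in seq_len(age)) {
    bai <- exp(a + eff[t]) * d^b
    A <- A + bai
    dnew <- sqrt(4 * A / pi)
    dtraj[t] <- dnew
    d <- dnew
  }
  if (any(!is.finite(dtraj))) stop("growth recursion diverged; lower noise_sd or trend magnitude")
  w_mm <- diff(c(d0, dtraj)) / 2 * 10
  w_mm <- pmax(round(w_mm * 100), 1) / 100 # measurement precision, widths > 0
  dbh <- 2 * (d0 / 2 + sum(w_mm) / 10)
  list(first_year = first, widths = w_mm,
       dbh_cm = as.numeric(sprintf("%.3f", dbh)), age = age)
}

#' Generate a full synthetic tree-ring network
#'
#' Builds the hierarchical region -> stand -> tree network with known ground
#' truth: regional climates along the mesic/xeric gradient (shared drought
#' years), balanced coverage of the 4 age x 3 size demographic classes via
#' round-robin cell allocation within stands, demographic-group climate
#' sensitivities, gradient-specific drought legacies and class-specific
#' post-onset trends. Fully deterministic for a fixed config seed.
#'
#' @param config a `dd_config` from [network_config()].
#' @return list with `rwl` (per-stand wide ring-width tables, mm),
#'   `tree_meta`, `stands`, `climate` (all stands), and `truth` (the config).
#' @export
generate_network <- function(config) {
  set.seed(config$seed)
  gradients <- c("mesic", "xeric")
  stands_tbl <- list(); clim_all <- list(); meta <- list(); rwl <- list()
  region_seeds <- sample.int(2^31 - 2, 2 * config$n_regions_per_gradient)
  ridx <- 0
  cells <- expand.grid(ab = names(age_bins), sb = names(size_bins),
                       stringsAsFactors = FALSE)
  for (g in gradients) {
    for (r in seq_len(config$n_regions_per_gradient)) {
      ridx <- ridx + 1
      region_id <- sprintf("%s_R%d", g, r)
      rp <- default_region_params(g, lat = if (g == "mesic") 49 - r * 0.5 else 43 + r * 0.5)
      stand_ids <- sprintf("%s_S%d", region_id, seq_len(config$n_stands_per_region))
      clim <- generate_climate(rp, stand_ids, config$year_span,
                               config$warming_onset,
                               config$warming_trend_c_per_decade,
                               config$drought_years, seed = region_seeds[ridx])
      clim_all[[region_id]] <- clim
      stands_tbl[[region_id]] <- data.frame(
        stand_id = stand_ids, region_id = region_id, gradient = g,
        lat = rp$lat,
        lon = as.numeric(sprintf("%.4f", 15 + ridx + seq_along(stand_ids) * 0.05)),
        elevation_m = round(stats::runif(length(stand_ids), 700, 1400)),
        slope_deg = as.numeric(sprintf("%.1f", stats::runif(length(stand_ids), 5, 35))),
        aspect_deg = round(stats::runif(length(stand_ids), 0, 359)),
        plot_area_m2 = 1500)
    }
  }
  climate <- do.call(rbind, c(clim_all, list(make.row.names = FALSE)))
  stands <- do.call(rbind, c(stands_tbl, list(make.row.names = FALSE)))
  zs <- climate_zscores(climate)
  tree_no <- 0
  cell_cursor <- 0
  for (si in seq_len(nrow(stands))) {
    s <- stands$stand_id[si]
    g <- stands$gradient[si]
    region <- stands$region_id[si]
    wide <- NULL
    years_all <- seq(config$year_span[1] - 500, config$year_span[2])
    mat <- matrix(NA_real_, length(years_all), config$n_trees_per_stand)
    ids <- character(config$n_trees_per_stand)
    for (k in seq_len(config$n_trees_per_stand)) {
      cell_cursor <- cell_cursor %% nrow(cells) + 1
      ab <- cells$ab[cell_cursor]; sb <- cells$sb[cell_cursor]
      grp <- cell_group(ab, sb)
      gs <- config$group_sensitivity
      if (!is.null(gs[[g]])) gs <- gs[[g]] # gradient-nested map
      age <- round(stats::runif(1, age_bins[[ab]][1], age_bins[[ab]][2]))
      # corner cells sample the outer part of their size bin so that the
      # realized DBH quantile corners coincide with the intended groups
      srange <- size_bins[[sb]]
      if (sb == "60+") srange <- if (grp != "none") c(76, 90) else c(63, 75)
      if (sb == "10-39") srange <- if (grp != "none") c(12, 30) else c(28, 37)
      target <- stats::runif(1, srange[1], srange[2])
      gam <- gs[[grp]]
      if (is.null(gam)) gam <- c()
      if (length(gam) && config$gamma_sd > 0) {
        gam <- gam + stats::rnorm(length(gam), 0, config$gamma_sd)
      }
      delta <- config$drought_legacy[[g]]
      if (grp == "s_y") delta <- delta * config$sy_legacy_attenuation
      theta <- config$class_trend[[paste(ab, sb, sep = "|")]]
      if (is.null(theta)) theta <- 0
      tr <- simulate_tree(age, target, gam, theta, delta, zs[[s]],
                          config$drought_years, config)
      tree_no <- tree_no + 1
      id <- sprintf("T%05d", tree_no)
      ids[k] <- id
      mat[match(seq(tr$first_year, config$year_span[2]), years_all), k] <- tr$widths
      meta[[id]] <- data.frame(tree_id = id, stand_id = s, region_id = region,
                               gradient = g, dbh_cm = tr$dbh_cm, age_yr = age,
                               plot_area_m2 = stands$plot_area_m2[si],
                               truth_group = grp,
                               truth_class = paste(ab, sb, sep = "|"))
    }
    keep <- rowSums(!is.na(mat)) > 0
    wide <- as.data.frame(mat[keep, , drop = FALSE])
    names(wide) <- ids
    rownames(wide) <- years_all[keep]
    rwl[[s]] <- wide
  }
  tree_meta <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  # realized class coverage check
  cls <- paste(assign_class(tree_meta$age_yr, tree_meta$dbh_cm)$age_class,
               assign_class(tree_meta$age_yr, tree_meta$dbh_cm)$size_class,
               sep = "|")
  missing_cells <- setdiff(paste(cells$ab, cells$sb, sep = "|"), unique(cls))
  if (length(missing_cells)) {
    stop("empty demographic class(es): ", paste(missing_cells, collapse = ", "),
         "; increase n_trees_per_stand or the network size")
  }
  list(rwl = rwl, tree_meta = tree_meta, stands = stands, climate = climate,
       truth = config)
}

#' Write a synthetic dataset to disk
#'
#' Ring widths as one Tucson/.rwl per stand (0.01 mm units, stop marker
#' 999), metadata, stand attributes and monthly climate as CSV, and the
#' generating truth as a plain-text key-value (YAML) file.
#'
#' @param dataset list from [generate_network()].
#' @param dir output directory.
#' @param overwrite allow replacing existing files.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(dataset, dir, overwrite = FALSE) {
  if (length(dataset$rwl) == 0) stop("empty dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(file.path(dir, "tree_meta.csv"), file.path(dir, "stands.csv"))
  if (!overwrite && any(file.exists(paths))) {
    stop("bundle files already present in ", dir, " (use overwrite = TRUE)")
  }
  utils::write.csv(dataset$tree_meta, file.path(dir, "tree_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$stands, file.path(dir, "stands.csv"),
                   row.names = FALSE)
  for (s in names(dataset$rwl)) {
    write_rwl(dataset$rwl[[s]], file.path(dir, paste0(s, ".rwl")),
              overwrite = overwrite)
    cs <- dataset$climate[dataset$climate$stand_id == s,
                          c("year", "month", "tmin_c", "tmax_c", "prec_mm")]
    utils::write.csv(cs, file.path(dir, paste0("climate_", s, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(dataset$truth)) {
    writeLines(yaml::as.yaml(unclass(dataset$truth), precision = 15),
               file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' Read a dataset bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return list with the same structure as [generate_network()] output
#'   (derived PET/CWB columns are recomputed from the stored climate).
#' @export
read_bundle <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "tree_meta.csv"),
                          stringsAsFactors = FALSE)
  stands <- utils::read.csv(file.path(dir, "stands.csv"),
                            stringsAsFactors = FALSE)
  rwl <- list(); clim <- list()
  for (i in seq_len(nrow(stands))) {
    s <- stands$stand_id[i]
    rwl[[s]] <- read_rwl(file.path(dir, paste0(s, ".rwl")))
    cs <- utils::read.csv(file.path(dir, paste0("climate_", s, ".csv")))
    cs$stand_id <- s
    cs$lat <- stands$lat[i]
    clim[[s]] <- cs[, c("stand_id", "year", "month", "tmin_c", "tmax_c",
                        "prec_mm", "lat")]
  }
  truth_path <- file.path(dir, "truth.yaml")
  truth <- if (file.exists(truth_path)) yaml::read_yaml(truth_path) else NULL
  list(rwl = rwl, tree_meta = meta, stands = stands,
       climate = compute_cwb(do.call(rbind, c(clim, list(make.row.names = FALSE)))),
       truth = truth)
}
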