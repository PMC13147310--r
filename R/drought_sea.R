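#' Select network-wide severe summer droughts
#'
#' Per-stand summer CWB z-scores over the analysis period; a year is an
#' event when the share of stands at or below z = -1.5 exceeds the coverage
#' threshold (default 0.90). Events closer than the SEA window length are
#' flagged as overlapping but kept.
#'
#' @param summer_cwb seasonal table (`stand_id`, `year`, `value`) of summer
#'   CWB, e.g. from [seasonal_aggregate()].
#' @param z_threshold z-score threshold (default -1.5).
#' @param coverage required share of stands (default 0.90, strict).
#' @param min_separation years below which two events are flagged as
#'   overlapping (default 7).
#' @param min_years minimum span required to form meaningful z-scores
#'   (default 20; lower only for toy inputs).
#' @return list `years`, `coverage` (per selected year), `overlapping`
#'   (logical per event), `z_by_stand` (stand x year z matrix).
#' @export
select_drought_years <- function(summer_cwb, z_threshold = -1.5,
                                 coverage = 0.90, min_separation = 7,
                                 min_years = 20) {
  stands <- unique(summer_cwb$stand_id)
  years <- sort(unique(summer_cwb$year))
  if (length(years) < min_years) stop("need >= ", min_years, " years")
  if (length(stands) < 2) stop("need >= 2 stands")
  z <- matrix(NA_real_, length(stands), length(years),
              dimnames = list(stands, years))
  for (s in stands) {
    i <- summer_cwb$stand_id == s
    v <- summer_cwb$value[i]
    z[s, match(summer_cwb$year[i], years)] <- (v - mean(v)) / stats::sd(v)
  }
  share <- colMeans(z <= z_threshold, na.rm = TRUE)
  sel <- years[share > coverage]
  overlapping <- rep(FALSE, length(sel))
  if (length(sel) > 1) {
    gaps <- diff(sel)
    overlapping[which(gaps < min_separation)] <- TRUE
    overlapping[which(gaps < min_separation) + 1] <- TRUE
  }
  list(years = sel, coverage = share[as.character(sel)],
       overlapping = overlapping, z_by_stand = z)
}

sea_departures <- function(index, years, events, lags = -3:3) {
  # departure per lag: mean over events of index[event+lag] minus that
  # event's pre-event mean (lags -3..-1)
  dep <- matrix(NA_real_, length(events), length(lags),
                dimnames = list(events, lags))
  for (e in seq_along(events)) {
    pos <- match(events[e] + lags, years)
    pre <- match(events[e] + (-3:-1), years)
    if (anyNA(pos) || anyNA(pre)) next
    dep[e, ] <- index[pos] - mean(index[pre])
  }
  dep
}

#' Double-bootstrap superposed epoch analysis
#'
#' Event-aligned compositing of a residual chronology over lags -3..+3,
#' normalized to each event's pre-event (lags -3..-1) mean. The first
#' bootstrap resamples events with replacement to give a confidence
#' interval per lag; the second draws random pseudo-event sets from
#' non-event years to give a percentile null band. Events whose window
#' leaves the series are dropped with a warning.
#'
#' @param chron data frame `year`, `index`.
#' @param events drought event years (>= 2 usable).
#' @param n_event_boot event-bootstrap replicates (default 1000).
#' @param n_null pseudo-event draws (default 1000).
#' @param seed integer seed.
#' @param lags lag window (default -3:3).
#' @return data frame per lag: departure, ci_low, ci_high, se, null_low,
#'   null_high, significant.
#' @export
sea_double_bootstrap <- function(chron, events, n_event_boot = 1000,
                                 n_null = 1000, seed = 1L, lags = -3:3) {
  years <- chron$year
  usable <- events[(events + min(lags)) >= min(years) &
                   (events + max(lags)) <= max(years)]
  usable <- usable[vapply(usable, function(e) {
    all((e + lags) %in% years)
  }, logical(1))]
  if (length(usable) < length(events)) {
    warning(length(events) - length(usable), " event(s) too close to the series edge dropped")
  }
  if (length(usable) < 2) stop("need at least 2 usable events")
  dep <- sea_departures(chron$index, years, usable, lags)
  point <- colMeans(dep)
  set.seed(as.integer(seed))
  ne <- nrow(dep)
  boot <- t(vapply(seq_len(n_event_boot), function(b) {
    colMeans(dep[sample.int(ne, ne, replace = TRUE), , drop = FALSE])
  }, numeric(length(lags))))
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  se <- apply(boot, 2, stats::sd)
  # null: pseudo-event sets from years outside the real event windows
  blocked <- unique(as.vector(outer(usable, lags, `+`)))
  pool <- years[(years + min(lags)) >= min(years) &
                (years + max(lags)) <= max(years)]
  pool <- setdiff(pool, blocked)
  if (length(pool) < ne) stop("null pool too small")
  win <- diff(range(lags)) # pseudo-events keep the real events' spacing rule
  draw_spaced <- function() {
    for (try in 1:50) {
      ev <- sort(sample(pool, ne, replace = FALSE))
      if (ne == 1 || min(diff(ev)) >= win) return(ev)
    }
    ev
  }
  null_mat <- t(vapply(seq_len(n_null), function(b) {
    colMeans(sea_departures(chron$index, years, draw_spaced(), lags),
             na.rm = TRUE)
  }, numeric(length(lags))))
  nb <- apply(null_mat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(lag = lags, departure = point, ci_low = ci[1, ], ci_high = ci[2, ],
             se = se, null_low = nb[1, ], null_high = nb[2, ],
             significant = point < nb[1, ] | point > nb[2, ],
             row.names = NULL)
}

#' Pool per-stand SEA results across a grouping cell
#'
#' Lag-wise inverse-variance random-effects pooling (DerSimonian-Laird,
#' Hartung-Knapp interval) of stand departures, using each stand's
#' event-bootstrap standard error as the sampling variance. Singleton cells
#' are returned unpooled with a flag.
#'
#' @param sea_list list of per-stand results from
#'   [sea_double_bootstrap()].
#' @return data frame per lag: departure, ci_low, ci_high, tau2, k,
#'   significant (CI excludes 0), pooled flag.
#' @export
pool_sea <- function(sea_list) {
  if (length(sea_list) == 0) stop("no stand results")
  if (length(sea_list) == 1) {
    out <- sea_list[[1]][, c("lag", "departure", "ci_low", "ci_high")]
    out$tau2 <- NA_real_; out$k <- 1L
    out$significant <- out$ci_low > 0 | out$ci_high < 0
    out$pooled <- FALSE
    return(out)
  }
  lags <- sea_list[[1]]$lag
  out <- lapply(seq_along(lags), function(i) {
    yi <- vapply(sea_list, function(x) x$departure[i], numeric(1))
    vi <- vapply(sea_list, function(x) max(x$se[i]^2, 1e-10), numeric(1))
    fit <- metafor::rma(yi = yi, vi = vi, method = "DL", test = "knha")
    data.frame(lag = lags[i], departure = as.numeric(fit$beta),
               ci_low = fit$ci.lb, ci_high = fit$ci.ub, tau2 = fit$tau2,
               k = length(yi),
               significant = fit$ci.lb > 0 | fit$ci.ub < 0, pooled = TRUE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
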