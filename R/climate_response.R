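#' Bootstrapped Pearson correlation between a chronology and climate
#'
#' Point estimate is the plain Pearson correlation on the overlapping
#' years; the confidence interval is the 2.5/97.5 percentile of
#' correlations over year-resampled bootstrap replicates. Significance is
#' declared when the interval excludes zero.
#'
#' @param chron data frame `year`, `index` (residual chronology).
#' @param climate data frame `year`, `value` (detrended seasonal anomaly).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param min_overlap minimum overlapping years (default 25).
#' @return one-row data frame: r, ci_low, ci_high, n_years, significant.
#' @export
bootstrap_correlation <- function(chron, climate, n_boot = 1000, seed = 1L,
                                  min_overlap = 25) {
  yrs <- intersect(chron$year, climate$year)
  if (length(yrs) < min_overlap) stop("overlap too short (", length(yrs), " yr)")
  x <- chron$index[match(yrs, chron$year)]
  y <- climate$value[match(yrs, climate$year)]
  r <- stats::cor(x, y)
  set.seed(as.integer(seed))
  n <- length(yrs)
  rb <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i])
  }, numeric(1))
  ci <- stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  data.frame(r = r, ci_low = ci[1], ci_high = ci[2], n_years = n,
             significant = ci[1] > 0 | ci[2] < 0)
}

#' Pool correlations across stands by random-effects meta-analysis
#'
#' Fisher z-transform with sampling variance 1/(n-3), DerSimonian-Laird
#' between-stand heterogeneity and the Hartung-Knapp small-sample interval
#' (t with k-1 df), back-transformed to the correlation scale.
#'
#' @param r correlations per stand (k >= 2).
#' @param n_years years underlying each correlation (all > 3).
#' @return one-row data frame: pooled_r, ci_low, ci_high, tau2 (z-scale),
#'   k, p.
#' @export
pool_correlations <- function(r, n_years) {
  if (length(r) < 2) stop("need k >= 2 stands")
  if (any(n_years <= 3)) stop("all n must exceed 3")
  z <- atanh(r)
  v <- 1 / (n_years - 3)
  fit <- metafor::rma(yi = z, vi = v, method = "DL", test = "knha")
  data.frame(pooled_r = tanh(as.numeric(fit$beta)),
             ci_low = tanh(fit$ci.lb), ci_high = tanh(fit$ci.ub),
             tau2 = fit$tau2, k = length(r), p = fit$pval)
}

#' Correlations between group/stand chronologies and a climate window
#'
#' Convenience wrapper: computes the bootstrapped correlation for each
#' stand-level chronology against the (detrended) seasonal anomaly of its
#' stand and pools them with the random-effects meta-analysis.
#'
#' @param chron_list named list of chronologies (names = stand ids).
#' @param seasonal detrended seasonal table (from [detrend_climate()]),
#'   single variable/season.
#' @param period optional two-element year range restriction.
#' @param n_boot,seed passed to [bootstrap_correlation()].
#' @return list `per_stand` (records) and `pooled` (one row, NULL if k < 2).
#' @export
pooled_climate_correlation <- function(chron_list, seasonal, period = NULL,
                                       n_boot = 1000, seed = 1L) {
  recs <- list()
  for (s in names(chron_list)) {
    ch <- chron_list[[s]]
    cl <- seasonal[seasonal$stand_id == s, c("year", "detrended_value")]
    names(cl) <- c("year", "value")
    if (!is.null(period)) {
      ch <- ch[ch$year >= period[1] & ch$year <= period[2], ]
      cl <- cl[cl$year >= period[1] & cl$year <= period[2], ]
    }
    rec <- tryCatch(bootstrap_correlation(ch, cl, n_boot = n_boot, seed = seed),
                    error = function(e) NULL)
    if (!is.null(rec)) { rec$unit <- s; recs[[s]] <- rec }
  }
  per_stand <- if (length(recs)) do.call(rbind, c(recs, list(make.row.names = FALSE))) else NULL
  pooled <- if (!is.null(per_stand) && nrow(per_stand) >= 2) {
    pool_correlations(per_stand$r, per_stand$n_years)
  } else NULL
  list(per_stand = per_stand, pooled = pooled)
}

#' Moving-window correlation series
#'
#' Right-aligned windows of fixed length stepped through the overlap; each
#' window yields one bootstrapped correlation record labelled by its last
#' year.
#'
#' @param chron,climate as in [bootstrap_correlation()].
#' @param window_len window length in years (default 30).
#' @param step step between windows (default 1).
#' @param n_boot,seed bootstrap settings (default 500 replicates).
#' @return data frame of records with an `end_year` column.
#' @export
moving_correlation <- function(chron, climate, window_len = 30, step = 1,
                               n_boot = 500, seed = 1L) {
  yrs <- sort(intersect(chron$year, climate$year))
  if (length(yrs) < window_len) stop("window longer than the overlap")
  ends <- yrs[seq(window_len, length(yrs), by = step)]
  out <- lapply(ends, function(e) {
    win <- (e - window_len + 1):e
    rec <- bootstrap_correlation(chron[chron$year %in% win, ],
                                 climate[climate$year %in% win, ],
                                 n_boot = n_boot, seed = seed,
                                 min_overlap = window_len)
    rec$end_year <- e
    rec
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' PCA of a units x climate-variables matrix of pooled correlations
#'
#' Ordination of pooled correlation profiles (e.g. regions x seasonal
#' windows) used to read the mesic/xeric response gradient. Incomplete rows
#' are dropped with a message.
#'
#' @param r_mat numeric matrix, rows = units, columns = climate windows.
#' @param n_components components to return (default 2).
#' @return [run_pca()] result.
#' @export
correlation_pca <- function(r_mat, n_components = 2) {
  r_mat <- as.matrix(r_mat)
  keep <- stats::complete.cases(r_mat)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " incomplete row(s)")
    r_mat <- r_mat[keep, , drop = FALSE]
  }
  run_pca(r_mat, n_components = n_components)
}
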