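#' Filter increment cores on pith proximity
#'
#' Retains series that miss at most 30 mm or 20 years to the pith and are
#' flagged cross-datable; everything else is logged with a reason.
#'
#' @param meta data frame with `tree_id` and optional `pith_offset_mm`,
#'   `pith_offset_years`, `cross_datable` columns (missing columns default
#'   to 0 / TRUE, the synthetic-data case).
#' @param max_mm,max_years retention limits (defaults 30 mm, 20 yr).
#' @return list with `retained` (tree ids) and `log` (tree_id, retained,
#'   reason).
#' @export
filter_cores <- function(meta, max_mm = 30, max_years = 20) {
  n <- nrow(meta)
  off_mm <- if ("pith_offset_mm" %in% names(meta)) meta$pith_offset_mm else rep(0, n)
  off_yr <- if ("pith_offset_years" %in% names(meta)) meta$pith_offset_years else rep(0, n)
  xdat <- if ("cross_datable" %in% names(meta)) meta$cross_datable else rep(TRUE, n)
  reason <- rep("ok", n)
  reason[off_mm > max_mm] <- "pith distance"
  reason[off_yr > max_years] <- ifelse(reason[off_yr > max_years] == "ok",
                                       "pith years", "pith distance + years")
  reason[!xdat] <- "not cross-datable"
  retained <- meta$tree_id[reason == "ok"]
  if (length(retained) == 0 && n > 0) warning("no cores retained")
  list(retained = retained,
       log = data.frame(tree_id = meta$tree_id, retained = reason == "ok",
                        reason = reason))
}

#' Spline-detrend a ring-width series to a ring-width index
#'
#' Fits the frequency-cutoff smoothing spline (50% response at 10 years by
#' default) and returns the ratio index RWI = RW / spline. The spline is
#' floored at a small positive value; series whose spline collapses are
#' rejected.
#'
#' @param w positive ring widths (mm), ordered in time, no NA.
#' @param nyrs,f spline cutoff parameters.
#' @return numeric RWI series (unitless, mean about 1).
#' @export
spline_detrend <- function(w, nyrs = 10, f = 0.5) {
  if (length(w) < 15) stop("series shorter than 15 years")
  if (any(!is.finite(w)) || any(w <= 0)) stop("widths must be positive and finite")
  s <- cps_spline(w, nyrs = nyrs, f = f)
  eps <- 0.05 * mean(w)
  if (any(s < eps)) {
    if (mean(s < eps) > 0.2) stop("spline not positive; series dropped")
    warning("spline floored at ", signif(eps, 3), " for ", sum(s < eps), " year(s)")
    s <- pmax(s, eps)
  }
  w / s
}

#' Autoregressive prewhitening of a detrended series
#'
#' Fits AR(p), p in 0..3 selected by AIC, and returns residuals plus the
#' series mean, removing persistence so the residual chronology carries the
#' year-to-year climate signal.
#'
#' @param x RWI series, length >= 20, finite.
#' @param max_order maximum AR order (default 3).
#' @return residual series, same length (leading fitted values retained as
#'   the mean for the first `p` years).
#' @export
ar_prewhiten <- function(x, max_order = 3) {
  if (length(x) < 20) stop("series shorter than 20 years")
  if (any(!is.finite(x))) stop("non-finite values")
  if (stats::sd(x) == 0) {
    warning("constant series; returned unchanged")
    return(x)
  }
  fit <- stats::ar(x, aic = TRUE, order.max = max_order, method = "yule-walker")
  if (fit$order == 0) return(x)
  res <- fit$resid
  res[is.na(res)] <- 0
  as.numeric(res + mean(x))
}

#' Inter-series correlation and expressed population signal
#'
#' rbar is the mean pairwise Pearson correlation over the common period;
#' EPS = n rbar / (n rbar + (1 - rbar)). A chronology is flagged reliable
#' when EPS exceeds 0.80.
#'
#' @param series_mat matrix years x series (NA outside each series' span).
#' @param min_overlap minimum pairwise overlap in years (default 20).
#' @return list `rbar`, `eps`, `n` (mean sample depth), `reliable`.
#' @export
chronology_stats <- function(series_mat, min_overlap = 20) {
  m <- as.matrix(series_mat)
  if (ncol(m) < 2) stop("need at least 2 series")
  rs <- c()
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      if (sum(ok) >= min_overlap) {
        if (stats::sd(m[ok, i]) > 0 && stats::sd(m[ok, j]) > 0) {
          rs <- c(rs, stats::cor(m[ok, i], m[ok, j]))
        }
      }
    }
  }
  if (length(rs) == 0) stop("insufficient overlap between series")
  rbar <- mean(rs)
  n <- mean(rowSums(!is.na(m))[rowSums(!is.na(m)) > 0])
  eps <- eps_from_rbar(n, rbar)
  list(rbar = rbar, eps = eps, n = n, reliable = eps > 0.80)
}

#' Expressed population signal from sample depth and rbar
#'
#' EPS = n rbar / (n rbar + (1 - rbar)), clamped to \[0, 1\].
#'
#' @param n number of series (sample depth).
#' @param rbar mean inter-series correlation.
#' @return EPS in \[0, 1\].
#' @export
eps_from_rbar <- function(n, rbar) {
  min(max(n * rbar / (n * rbar + (1 - rbar)), 0), 1)
}

#' Assign quantile-corner demographic groups
#'
#' Labels trees by the corners of the joint age/DBH distribution of their
#' reference population: large old (`l_o`, both >= Q75), large young
#' (`l_y`, age <= Q25 and DBH >= Q75), small old (`s_o`), small young
#' (`s_y`); interior trees get `none` and are excluded from group
#' chronologies.
#'
#' @param meta data frame with `tree_id`, `age_yr`, `dbh_cm` and the
#'   reference-population column named in `ref`.
#' @param ref grouping column defining the reference population for the
#'   quantiles (default `"region_id"`).
#' @return `meta` with a `group` factor appended.
#' @export
assign_demographic_group <- function(meta, ref = "region_id") {
  out <- meta
  out$group <- "none"
  for (r in unique(meta[[ref]])) {
    i <- which(meta[[ref]] == r)
    if (length(i) < 8) stop("reference population '", r, "' has fewer than 8 trees")
    qa <- stats::quantile(meta$age_yr[i], c(0.25, 0.75))
    qd <- stats::quantile(meta$dbh_cm[i], c(0.25, 0.75))
    if (qa[1] == qa[2] || qd[1] == qd[2]) {
      stop("degenerate age or DBH quantiles in population '", r, "'")
    }
    age <- meta$age_yr[i]; dbh <- meta$dbh_cm[i]
    lab <- rep("none", length(i))
    lab[age >= qa[2] & dbh >= qd[2]] <- "l_o"
    lab[age <= qa[1] & dbh >= qd[2]] <- "l_y"
    lab[age >= qa[2] & dbh <= qd[1]] <- "s_o"
    lab[age <= qa[1] & dbh <= qd[1]] <- "s_y"
    out$group[i] <- lab
  }
  out$group <- factor(out$group, levels = c("l_o", "l_y", "s_o", "s_y", "none"))
  out
}

#' Build residual series for a set of trees
#'
#' Spline detrending followed by AR prewhitening, applied per tree to a
#' wide ring-width table. Trees whose series are too short (or whose spline
#' collapses) are dropped with a log entry.
#'
#' @param rwl wide table (years x trees, mm) as from [read_rwl()].
#' @param nyrs,f spline cutoff parameters.
#' @param prewhiten apply [ar_prewhiten()] (default TRUE).
#' @return list `residuals` (years x trees matrix), `log` (dropped trees).
#' @export
build_residual_series <- function(rwl, nyrs = 10, f = 0.5, prewhiten = TRUE) {
  years <- as.integer(rownames(rwl))
  out <- matrix(NA_real_, nrow(rwl), ncol(rwl),
                dimnames = list(years, names(rwl)))
  dropped <- character()
  for (j in seq_len(ncol(rwl))) {
    ok <- which(!is.na(rwl[[j]]))
    res <- tryCatch({
      rwi <- spline_detrend(rwl[[j]][ok], nyrs = nyrs, f = f)
      if (prewhiten && length(rwi) >= 20) rwi <- ar_prewhiten(rwi)
      rwi
    }, error = function(e) NULL)
    if (is.null(res)) dropped <- c(dropped, names(rwl)[j]) else out[ok, j] <- res
  }
  list(residuals = out, dropped = dropped)
}

#' Aggregate residual series into a chronology
#'
#' Per-year Tukey biweight robust mean across member series, with sample
#' depth; years below the minimum depth are masked. rbar/EPS statistics are
#' attached when at least two members overlap.
#'
#' @param res_mat years x trees residual matrix (from
#'   [build_residual_series()]).
#' @param members tree ids to aggregate.
#' @param min_depth minimum sample depth per year (default 5).
#' @param label chronology label.
#' @return data frame `year`, `index`, `depth` with attributes `rbar`,
#'   `eps`, `label`.
#' @export
build_chronology <- function(res_mat, members = colnames(res_mat),
                             min_depth = 5, label = "chronology") {
  members <- intersect(members, colnames(res_mat))
  if (length(members) == 0) stop("empty group '", label, "'")
  m <- res_mat[, members, drop = FALSE]
  depth <- rowSums(!is.na(m))
  idx <- rep(NA_real_, nrow(m))
  for (i in which(depth >= max(1, min_depth))) {
    idx[i] <- biweight_mean(m[i, ][!is.na(m[i, ])])
  }
  out <- data.frame(year = as.integer(rownames(m)), index = idx, depth = depth)
  out <- out[!is.na(out$index), ]
  st <- if (length(members) >= 2) {
    tryCatch(chronology_stats(m), error = function(e) list(rbar = NA, eps = NA))
  } else list(rbar = NA, eps = NA)
  attr(out, "rbar") <- st$rbar
  attr(out, "eps") <- st$eps
  attr(out, "label") <- label
  rownames(out) <- NULL
  out
}

#' Demographic-group (or stand) residual chronologies
#'
#' @param res_mat years x trees residual matrix.
#' @param meta tree metadata with `tree_id` and the grouping column.
#' @param by grouping column, e.g. `"group"` (after
#'   [assign_demographic_group()]) or `"stand_id"`.
#' @param min_depth minimum per-year sample depth.
#' @return named list of chronologies (groups `none` excluded when
#'   `by = "group"`).
#' @export
build_group_chronology <- function(res_mat, meta, by = "group", min_depth = 5) {
  labs <- setdiff(unique(as.character(meta[[by]])), "none")
  out <- list()
  for (g in labs) {
    ids <- meta$tree_id[as.character(meta[[by]]) == g]
    ids <- intersect(ids, colnames(res_mat))
    if (length(ids) == 0) next
    out[[g]] <- build_chronology(res_mat, ids, min_depth = min_depth, label = g)
  }
  if (length(out) == 0) stop("no non-empty groups")
  out
}
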