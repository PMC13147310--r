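#' Stand-level demographic class productivity contributions
#'
#' Tree-level Sen slopes are aggregated within each class and trend
#' direction as a basal-area-weighted mean slope, converted to m^2
#' (x 1e-4) and scaled by the class-direction tree density (trees per
#' hectare), yielding contributions in m^2 ha^-1 yr^-1. Trees with no
#' significant direction are excluded; empty class-direction cells report a
#' zero contribution with a flag.
#'
#' @param trends tree trend records ([tree_trends()]).
#' @param meta tree metadata: `tree_id`, `stand_id`, `dbh_cm`, `age_yr`,
#'   `plot_area_m2`.
#' @return data frame: stand_id, age_class, size_class, direction,
#'   contribution, ba_share, n_trees, empty.
#' @export
class_contribution <- function(trends, meta) {
  m <- meta[match(trends$tree_id, meta$tree_id), ]
  cls <- assign_class(m$age_yr, m$dbh_cm)
  d <- data.frame(trends, stand_id = m$stand_id,
                  ba_cm2 = pi * m$dbh_cm^2 / 4,
                  area_ha = m$plot_area_m2 / 1e4,
                  age_class = cls$age_class, size_class = cls$size_class)
  out <- list()
  for (s in unique(d$stand_id)) {
    ds <- d[d$stand_id == s, ]
    ba_stand <- sum(ds$ba_cm2)
    area_ha <- ds$area_ha[1]
    for (ac in levels(ds$age_class)) for (sc in levels(ds$size_class)) {
      dc <- ds[ds$age_class == ac & ds$size_class == sc, ]
      if (nrow(dc) == 0) next
      for (dir in c("positive", "negative")) {
        dd <- dc[dc$direction == dir, ]
        contr <- if (nrow(dd) == 0) 0 else {
          wmean <- sum(dd$sen_slope * dd$ba_cm2) / sum(dd$ba_cm2)
          wmean * 1e-4 * nrow(dd) / area_ha
        }
        out[[length(out) + 1]] <- data.frame(
          stand_id = s, age_class = ac, size_class = sc, direction = dir,
          contribution = contr, ba_share = sum(dc$ba_cm2) / ba_stand,
          n_trees = nrow(dd), empty = nrow(dd) == 0)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Net productivity trend of a region, gradient or the network
#'
#' Per-stand net contribution (positive plus negative summed over classes)
#' averaged over the stands of each cell, with a stand-level bootstrap
#' percentile confidence interval.
#'
#' @param contrib output of [class_contribution()].
#' @param stand_info data frame `stand_id` plus the grouping column.
#' @param grouping column of `stand_info` (`"region_id"`, `"gradient"`) or
#'   `"network"`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return data frame: group, y_net, ci_low, ci_high, n_stands.
#' @export
regional_net_trend <- function(contrib, stand_info, grouping = "region_id",
                               n_boot = 1000, seed = 1L) {
  stand_net <- tapply(contrib$contribution, contrib$stand_id, sum)
  grp <- if (grouping == "network") rep("network", length(stand_net)) else {
    stand_info[[grouping]][match(names(stand_net), stand_info$stand_id)]
  }
  set.seed(as.integer(seed))
  out <- lapply(unique(grp), function(g) {
    v <- stand_net[grp == g]
    if (length(v) >= 3) {
      bt <- vapply(seq_len(n_boot), function(b)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      ci <- stats::quantile(bt, c(0.025, 0.975), names = FALSE)
    } else ci <- c(NA_real_, NA_real_)
    data.frame(group = g, y_net = mean(v), ci_low = ci[1], ci_high = ci[2],
               n_stands = length(v))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Mixed model on class contributions with marginal-mean contrasts
#'
#' Fits contribution ~ class x direction x gradient with random intercepts
#' for stands nested in regions, then compares gradients within each
#' class-direction cell via BH-adjusted estimated-marginal-mean contrasts.
#'
#' @param contrib output of [class_contribution()] (non-empty cells).
#' @param stand_info `stand_id`, `region_id`, `gradient`.
#' @return list `fit`, `emmeans` (cell means), `contrasts` (gradient
#'   differences with `p_adj`).
#' @export
contribution_mixed_model <- function(contrib, stand_info) {
  d <- contrib[!contrib$empty, ]
  i <- match(d$stand_id, stand_info$stand_id)
  d$region_id <- stand_info$region_id[i]
  d$gradient <- factor(stand_info$gradient[i])
  if (nlevels(d$gradient) < 2) stop("both gradient types must be represented")
  d$class <- interaction(d$age_class, d$size_class, drop = TRUE)
  d$direction <- factor(d$direction)
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(contribution ~ class * direction * gradient +
                     (1 | region_id / stand_id), data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  emm <- emmeans::emmeans(fit, ~ gradient | class * direction)
  ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  ct$p_adj <- bh_adjust(ct$p.value)
  list(fit = fit, emmeans = as.data.frame(emm), contrasts = ct)
}

#' Median class-level Sen slopes per stand (with regional fallback)
#'
#' beta_(s,c) is the within-stand median tree Sen slope for class c; when a
#' stand holds fewer than `min_trees` trees of the class, the regional
#' median is used instead.
#'
#' @param trends tree trend records.
#' @param meta tree metadata (`tree_id`, `stand_id`, `region_id`,
#'   `age_yr`, `dbh_cm`).
#' @param min_trees minimum trees for a stand-level median (default 3).
#' @return data frame: stand_id, class, beta, source.
#' @export
class_slope_medians <- function(trends, meta, min_trees = 3) {
  m <- meta[match(trends$tree_id, meta$tree_id), ]
  cls <- assign_class(m$age_yr, m$dbh_cm)
  d <- data.frame(slope = trends$sen_slope, stand_id = m$stand_id,
                  region_id = m$region_id,
                  class = paste(cls$age_class, cls$size_class, sep = "|"))
  out <- list()
  for (s in unique(d$stand_id)) {
    reg <- d$region_id[d$stand_id == s][1]
    for (cl in unique(d$class[d$stand_id == s])) {
      v <- d$slope[d$stand_id == s & d$class == cl]
      if (length(v) >= min_trees) {
        out[[length(out) + 1]] <- data.frame(stand_id = s, class = cl,
                                             beta = stats::median(v),
                                             source = "stand")
      } else {
        vr <- d$slope[d$region_id == reg & d$class == cl]
        out[[length(out) + 1]] <- data.frame(stand_id = s, class = cl,
                                             beta = stats::median(vr),
                                             source = "region")
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Demographic productivity index
#'
#' DPI_(s,t) = sum_c w_(s,t,c) beta_(s,c): basal-area shares of the
#' demographic classes weighted by their median Sen-slope trends. Positive
#' values mark stands dominated by classes with positive growth trends.
#'
#' @param shares data frame `stand_id`, `year`, `class`, `share` (shares
#'   sum to 1 per stand-year within 1e-6; set `use_share = FALSE` to pass
#'   absolute basal areas instead).
#' @param betas data frame `stand_id`, `class`, `beta` (from
#'   [class_slope_medians()]).
#' @param use_share validate the share-sum constraint (default TRUE).
#' @return data frame `stand_id`, `year`, `dpi`.
#' @export
dpi_index <- function(shares, betas, use_share = TRUE) {
  if (use_share) {
    tot <- tapply(shares$share, paste(shares$stand_id, shares$year), sum)
    if (any(abs(tot - 1) > 1e-6)) stop("class shares must sum to 1 per stand-year")
  }
  b <- betas$beta[match(paste(shares$stand_id, shares$class),
                        paste(betas$stand_id, betas$class))]
  if (anyNA(b)) stop("class present in shares but missing a beta: ",
                     paste(unique(shares$class[is.na(b)]), collapse = ", "))
  v <- shares$share * b
  agg <- stats::aggregate(v, list(stand_id = shares$stand_id, year = shares$year), sum)
  names(agg)[3] <- "dpi"
  agg[order(agg$stand_id, agg$year), ]
}

# first PC of one standardized seasonal block (stand-year rows)
block_pc <- function(mat, orient_col) {
  pc <- run_pca(mat, n_components = 1)
  s <- pc$scores[, 1]
  if (pc$loadings[orient_col, 1] < 0) s <- -s
  s
}

#' Assemble the stand-year table for the productivity model
#'
#' Combines reconstructed per-tree basal area trajectories, static stand
#' structure, the demographic productivity index and climate principal
#' components into one complete-case stand-year table. Climate PCs are the
#' first components of the standardized prior-summer block (PC1) and the
#' current spring/summer block (PC2), oriented so warmer conditions score
#' positive.
#'
#' @param bai long BAI table from [bai_from_rw()].
#' @param meta tree metadata.
#' @param stands stand attribute table (`stand_id`, `region_id`,
#'   `gradient`, `slope_deg`, `aspect_deg`, `plot_area_m2`).
#' @param climate monthly climate table (with CWB).
#' @param trends tree trend records for the DPI betas.
#' @param period modelling period (default c(1980, 2020)).
#' @return data frame of stand-year records (one row per stand and year).
#' @export
build_stand_year_table <- function(bai, meta, stands, climate, trends,
                                   period = c(1980, 2020)) {
  d <- bai[bai$year >= period[1] & bai$year <= period[2], ]
  i <- match(d$tree_id, meta$tree_id)
  d$stand_id <- meta$stand_id[i]
  cls <- assign_class(meta$age_yr[i], meta$dbh_cm[i])
  d$class <- paste(cls$age_class, cls$size_class, sep = "|")
  d$area_ha <- meta$plot_area_m2[i] / 1e4
  d$d_end <- sqrt(d$dprev_cm^2 + 4 * d$bai_cm2 / pi)
  d$ba_cm2 <- pi * d$d_end^2 / 4
  # stand-year structure
  key <- paste(d$stand_id, d$year)
  bai_sy <- tapply(d$bai_cm2, key, sum)
  ba_sy <- tapply(d$ba_cm2, key, sum)
  n_sy <- tapply(d$bai_cm2, key, length)
  area <- tapply(d$area_ha, key, function(x) x[1])
  ks <- strsplit(names(bai_sy), " ")
  sy <- data.frame(stand_id = vapply(ks, `[`, "", 1),
                   year = as.integer(vapply(ks, `[`, "", 2)),
                   bai_stand = as.numeric(bai_sy) * 1e-4 / as.numeric(area),
                   ba = as.numeric(ba_sy) * 1e-4 / as.numeric(area),
                   density = as.numeric(n_sy) / as.numeric(area))
  # class basal-area shares -> DPI
  ba_cls <- stats::aggregate(d$ba_cm2,
                             list(stand_id = d$stand_id, year = d$year,
                                  class = d$class), sum)
  tot <- tapply(ba_cls$x, paste(ba_cls$stand_id, ba_cls$year), sum)
  ba_cls$share <- ba_cls$x / as.numeric(tot[paste(ba_cls$stand_id, ba_cls$year)])
  betas <- class_slope_medians(trends, meta)
  dpi <- dpi_index(ba_cls[, c("stand_id", "year", "class", "share")], betas)
  sy$dpi <- dpi$dpi[match(paste(sy$stand_id, sy$year),
                          paste(dpi$stand_id, dpi$year))]
  # static structure
  gini_dbh <- tapply(meta$dbh_cm, meta$stand_id, gini)
  gini_age <- tapply(meta$age_yr, meta$stand_id, gini)
  n_cored <- table(meta$stand_id)
  sy$gini_dbh <- as.numeric(gini_dbh[sy$stand_id])
  sy$gini_age <- as.numeric(gini_age[sy$stand_id])
  sy$weight <- as.numeric(n_cored[sy$stand_id])
  si <- match(sy$stand_id, stands$stand_id)
  sy$region_id <- stands$region_id[si]
  sy$gradient <- factor(stands$gradient[si])
  sy$northness <- cos(stands$aspect_deg[si] * pi / 180)
  sy$slope_deg <- stands$slope_deg[si]
  # climate principal components
  vars <- list(p_tmax = c("tmax", "p_summer"), p_tmin = c("tmin", "p_summer"),
               p_cwb = c("cwb", "p_summer"),
               c_tmax_sp = c("tmax", "spring"), c_tmin_sp = c("tmin", "spring"),
               c_cwb_sp = c("cwb", "spring"),
               c_tmax_su = c("tmax", "summer"), c_tmin_su = c("tmin", "summer"),
               c_cwb_su = c("cwb", "summer"))
  agg <- lapply(vars, function(v) seasonal_aggregate(climate, v[1], v[2]))
  cm <- sapply(names(vars), function(v) {
    a <- agg[[v]]
    a$value[match(paste(sy$stand_id, sy$year), paste(a$stand_id, a$year))]
  })
  ok <- stats::complete.cases(cm) & stats::complete.cases(sy) & sy$bai_stand > 0
  sy <- sy[ok, ]; cm <- cm[ok, , drop = FALSE]
  sy$pc1 <- block_pc(scale(cm[, 1:3]), "p_tmax")
  sy$pc2 <- block_pc(scale(cm[, 4:9]), "c_tmax_su")
  sy$log_bai <- log(sy$bai_stand)
  rownames(sy) <- NULL
  sy
}

nakagawa_r2 <- function(fit) {
  vf <- stats::var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  keep <- vc$grp != "Residual" & is.na(vc$var2) &
    (is.na(vc$var1) | vc$var1 == "(Intercept)")
  vu <- sum(vc$vcov[keep])
  ve <- vc$vcov[vc$grp == "Residual"]
  c(r2_marginal = vf / (vf + vu + ve), r2_conditional = (vf + vu) / (vf + vu + ve))
}

vif_fixed <- function(fit) {
  X <- lme4::getME(fit, "X")
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / max(1 - r2, 1e-12)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

productivity_terms <- function(include_gradient_dpi = FALSE) {
  tt <- c("dpi", "ba", "density", "gini_dbh", "gini_age",
          "pc1", "I(pc1^2)", "pc2", "I(pc2^2)", "northness", "slope_deg",
          "gradient", "dpi:pc1", "dpi:pc2")
  if (include_gradient_dpi) tt <- c(tt, "dpi:gradient")
  tt
}

scale_predictors <- function(sy) {
  for (v in c("dpi", "ba", "density", "gini_dbh", "gini_age", "pc1", "pc2",
              "northness", "slope_deg")) {
    sy[[v]] <- as.numeric(scale(sy[[v]]))
  }
  sy
}

#' Fit the stand-productivity mixed model
#'
#' Gaussian mixed model of log stand BAI on the demographic productivity
#' index, stand structure (basal area, density, size/age Gini), linear and
#' quadratic climate principal components, topography (northness, slope),
#' gradient type and DPI x climate interactions, with random intercepts for
#' stands nested in regions and for calendar year, observation weights from
#' stand replication, REML estimation, and a VIF check (threshold 5,
#' reported not dropped). All continuous predictors are standardized.
#'
#' @param sy stand-year table from [build_stand_year_table()].
#' @param terms fixed-effect term labels (default [productivity_terms()]).
#' @param reml fit by REML (default TRUE).
#' @return list: `fit`, `coefficients` (estimate, se, df, p), `varcomp`,
#'   `r2` (marginal, conditional), `semi_partial` (per term: delta R2m from
#'   refit and a Wald-based partial R2), `vif`, `vif_flag`, `aic`.
#' @export
fit_productivity_glmm <- function(sy, terms = productivity_terms(), reml = TRUE) {
  if (length(unique(sy$stand_id)) < 4) stop("too few stands for the hierarchy")
  sy <- scale_predictors(sy)
  form <- stats::reformulate(c(terms, "(1 | region_id/stand_id)", "(1 | year)"),
                             response = "log_bai")
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(form, data = sy, weights = weight, REML = reml,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  co <- stats::coef(summary(fit))
  r2 <- nakagawa_r2(fit)
  vif <- vif_fixed(fit)
  # semi-partial R2: refit without each term (Delta marginal R2) plus a
  # Wald t-based partial statistic per coefficient
  sp <- vapply(terms, function(tm) {
    red <- setdiff(terms, tm)
    f2 <- stats::reformulate(c(red, "(1 | region_id/stand_id)", "(1 | year)"),
                             response = "log_bai")
    fit2 <- suppressWarnings(suppressMessages(
      lme4::lmer(f2, data = sy, weights = weight, REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    max(0, r2[["r2_marginal"]] - nakagawa_r2(fit2)[["r2_marginal"]])
  }, numeric(1))
  tvals <- co[rownames(co) != "(Intercept)", "t value"]
  dfres <- stats::nobs(fit) - nrow(co)
  wald_partial <- tvals^2 / (tvals^2 + dfres)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fit = fit,
       coefficients = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                                 se = co[, "Std. Error"], df = co[, "df"],
                                 p = co[, "Pr(>|t|)"], row.names = NULL),
       varcomp = vc[, c("grp", "vcov")],
       r2 = r2,
       semi_partial = data.frame(term = terms, delta_r2m = sp),
       wald_partial = wald_partial,
       vif = vif, vif_flag = any(vif >= 5),
       aic = stats::AIC(fit))
}

#' Leave-one-out likelihood-ratio model selection
#'
#' Backward elimination on maximum-likelihood fits: at each step every
#' droppable fixed term (interactions before their main effects) is removed
#' in turn, the likelihood-ratio chi-squared, p and Delta AIC recorded, and
#' the least informative non-significant term (largest p >= alpha) dropped;
#' terms whose removal significantly worsens the fit are retained. The same
#' single-pass procedure is applied to the random terms. A dedicated
#' comparison of the selected model with and without the demographic
#' productivity index (and its climate interactions) is reported, and the
#' final model refitted by REML.
#'
#' @param sy stand-year table.
#' @param terms starting fixed-effect terms.
#' @param alpha retention level (default 0.05).
#' @return list: `selection` (step table), `kept_terms`, `random_tests`,
#'   `dpi_comparison` (chisq, df, p, delta_aic, delta_r2m), `final` (REML
#'   [fit_productivity_glmm()] result on the kept terms).
#' @export
select_model <- function(sy, terms = productivity_terms(), alpha = 0.05) {
  sy <- scale_predictors(sy)
  ml_fit <- function(tt, random = c("(1 | region_id/stand_id)", "(1 | year)")) {
    f <- stats::reformulate(c(tt, random), response = "log_bai")
    suppressWarnings(suppressMessages(
      lme4::lmer(f, data = sy, weights = weight, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
  }
  droppable <- function(tt) {
    inter <- tt[grepl(":", tt)]
    parents <- unique(unlist(lapply(strsplit(inter, ":"), identity)))
    tt[grepl(":", tt) | !(tt %in% parents)]
  }
  kept <- terms
  steps <- list()
  repeat {
    full <- ml_fit(kept)
    cand <- droppable(kept)
    if (length(cand) == 0) break
    res <- lapply(cand, function(tm) {
      red <- ml_fit(setdiff(kept, tm))
      lrt <- stats::anova(red, full)
      data.frame(term = tm, chisq = lrt$Chisq[2], df = lrt$Df[2],
                 p = lrt$`Pr(>Chisq)`[2],
                 delta_aic = stats::AIC(red) - stats::AIC(full))
    })
    res <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    steps[[length(steps) + 1]] <- res
    worst <- res[which.max(res$p), ]
    if (worst$p < alpha) break
    kept <- setdiff(kept, worst$term)
  }
  # random-term tests on the selected fixed structure
  rand_full <- ml_fit(kept)
  rand_tests <- lapply(list(year = "(1 | region_id/stand_id)",
                            stand = "(1 | year)"), function(keep_r) {
    red <- ml_fit(kept, random = keep_r)
    lrt <- suppressWarnings(stats::anova(red, rand_full))
    data.frame(chisq = lrt$Chisq[2], df = lrt$Df[2], p = lrt$`Pr(>Chisq)`[2])
  })
  # with/without-DPI validation on the selected model
  dpi_terms <- kept[kept == "dpi" | grepl("^dpi:|:dpi$", kept)]
  dpi_cmp <- NULL
  if (length(dpi_terms)) {
    red <- ml_fit(setdiff(kept, dpi_terms))
    lrt <- stats::anova(red, rand_full)
    r2_full <- nakagawa_r2(rand_full)[["r2_marginal"]]
    r2_red <- nakagawa_r2(red)[["r2_marginal"]]
    dpi_cmp <- data.frame(chisq = lrt$Chisq[2], df = lrt$Df[2],
                          p = lrt$`Pr(>Chisq)`[2],
                          delta_aic = stats::AIC(red) - stats::AIC(rand_full),
                          delta_r2m = r2_full - r2_red)
  }
  list(selection = steps, kept_terms = kept,
       random_tests = rand_tests, dpi_comparison = dpi_cmp,
       final = fit_productivity_glmm(sy, terms = kept, reml = TRUE))
}

#' Network productivity total as the sum of gradient aggregates
#'
#' The network-level figure is constructed by summing the mesic and xeric
#' gradient aggregates (each a stand mean of net contributions), so the
#' partition identity network = sum(gradient cells) holds exactly.
#'
#' @param contrib output of [class_contribution()].
#' @param stand_info `stand_id`, `gradient`.
#' @param n_boot,seed bootstrap settings for the per-gradient CIs.
#' @return list `by_gradient` (data frame) and `network` (scalar sum).
#' @export
network_net_trend <- function(contrib, stand_info, n_boot = 1000, seed = 1L) {
  byg <- regional_net_trend(contrib, stand_info, grouping = "gradient",
                            n_boot = n_boot, seed = seed)
  list(by_gradient = byg, network = sum(byg$y_net))
}
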