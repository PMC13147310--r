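#' Basal area increments from ring widths
#'
#' Reconstructs stem radii inward from DBH/2 (subtracting widths backwards
#' in time) and converts to annual basal area increments via the circular
#' cross-section formula, BAI_t = pi (r_t^2 - r_(t-1)^2) in cm^2. Trees
#' whose cumulative widths exceed the stated radius are rejected with a log
#' entry.
#'
#' @param rwl wide ring-width table (years x trees, mm).
#' @param meta tree metadata with `tree_id` and `dbh_cm`.
#' @return list `bai` (long data frame: tree_id, year, bai_cm2, dprev_cm)
#'   and `rejected` (tree ids with reasons).
#' @export
bai_from_rw <- function(rwl, meta) {
  years <- as.integer(rownames(rwl))
  out <- list(); rejected <- list()
  for (id in names(rwl)) {
    dbh <- meta$dbh_cm[match(id, meta$tree_id)]
    if (is.na(dbh)) { rejected[[id]] <- "no DBH"; next }
    ok <- which(!is.na(rwl[[id]]))
    w_cm <- rwl[[id]][ok] / 10
    if (any(w_cm <= 0)) { rejected[[id]] <- "nonpositive ring width"; next }
    r_final <- dbh / 2
    r <- r_final - rev(cumsum(rev(w_cm)))      # radius before each ring
    if (min(r) < -1e-9) { rejected[[id]] <- "negative reconstructed radius"; next }
    r <- pmax(r, 0)
    r_after <- r + w_cm
    out[[id]] <- data.frame(tree_id = id, year = years[ok],
                            bai_cm2 = pi * (r_after^2 - r^2),
                            dprev_cm = 2 * r)
  }
  bai <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE))) else NULL
  list(bai = bai,
       rejected = data.frame(tree_id = names(rejected),
                             reason = unlist(rejected, use.names = FALSE)))
}

#' Fit the log-log size model for BAI detrending
#'
#' Linear mixed model log(BAI_it) = b0 + b1 log(D_(i,t-1)) with stand-level
#' random intercepts and slopes for log D and tree-level random intercepts
#' (trees nested in stands), fitted by REML. Singular random-slope fits fall
#' back to random intercepts with a warning.
#'
#' @param bai long BAI table from [bai_from_rw()] (rows with
#'   `dprev_cm > 0`).
#' @param meta tree metadata with `tree_id`, `stand_id`.
#' @return list with `fit` (merMod), `fixef`, `varcomp`, `singular`.
#' @export
fit_size_model <- function(bai, meta) {
  d <- bai[bai$dprev_cm > 0 & bai$bai_cm2 > 0, ]
  d$stand_id <- meta$stand_id[match(d$tree_id, meta$tree_id)]
  if (length(unique(d$stand_id)) < 2) {
    stop("size model needs at least 2 stands (nested structure degenerates)")
  }
  d$log_bai <- log(d$bai_cm2)
  d$log_d <- log(d$dprev_cm)
  fit <- suppressWarnings(
    lme4::lmer(log_bai ~ log_d + (1 + log_d | stand_id) + (1 | stand_id:tree_id),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("random-slope fit singular; falling back to random intercepts")
    fit <- suppressWarnings(
      lme4::lmer(log_bai ~ log_d + (1 | stand_id) + (1 | stand_id:tree_id),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fit = fit, fixef = lme4::fixef(fit),
       varcomp = vc[, c("grp", "var1", "var2", "vcov")], singular = singular)
}

#' Size-detrend BAI with a fitted size model
#'
#' bai_sdt = observed BAI / exp(predicted log BAI), predictions including
#' the stand- and tree-level random effects. New trees absent from the fit
#' fall back to population-level predictions. `bai_sdt_cm2` rescales the
#' ratio index by the tree's mean predicted BAI, giving a size-detrended
#' increment in original units (cm^2/yr) for trend magnitudes and
#' productivity contributions.
#'
#' @param bai long BAI table.
#' @param model list from [fit_size_model()].
#' @param meta tree metadata with `tree_id`, `stand_id`.
#' @return `bai` with `bai_sdt` and `bai_sdt_cm2` columns appended.
#' @export
size_detrend <- function(bai, model, meta) {
  d <- bai
  d$stand_id <- meta$stand_id[match(d$tree_id, meta$tree_id)]
  d$log_d <- log(pmax(d$dprev_cm, 1e-12))
  pred <- tryCatch(
    stats::predict(model$fit, newdata = d, allow.new.levels = TRUE),
    error = function(e) stop("prediction failed: ", conditionMessage(e)))
  if (any(!is.finite(pred))) stop("non-finite size-model prediction")
  bai$bai_sdt <- bai$bai_cm2 / exp(pred)
  mean_pred <- tapply(exp(pred), bai$tree_id, mean)
  bai$bai_sdt_cm2 <- bai$bai_sdt * as.numeric(mean_pred[bai$tree_id])
  bai
}

#' Demographic class of a tree
#'
#' Non-overlapping age classes (<100, 100-199, 200-299, 300+ years) and
#' size classes (10-39, \[40,60\], >60 cm); every tree with DBH >= 10 cm
#' maps to exactly one class.
#'
#' @param age_yr cambial age at sampling (years).
#' @param dbh_cm diameter at breast height (cm), >= 10.
#' @return data frame with `age_class` and `size_class` factors.
#' @export
assign_class <- function(age_yr, dbh_cm) {
  if (any(dbh_cm < 10)) stop("DBH below 10 cm outside the class system")
  age_class <- cut(age_yr, c(-Inf, 100, 200, 300, Inf), right = FALSE,
                   labels = c("<100", "100-199", "200-299", "300+"))
  size_class <- factor(ifelse(dbh_cm < 40, "10-39",
                       ifelse(dbh_cm <= 60, "40-60", "60+")),
                       levels = c("10-39", "40-60", "60+"))
  data.frame(age_class = age_class, size_class = size_class)
}

#' Minimum per-group sample size from Welch-test power analysis
#'
#' Smallest equal group size n at which a two-sample t-test (equal
#' variances and sizes, so Welch reduces to the pooled test) on effect size
#' d reaches the target power at the Bonferroni-corrected level
#' alpha / n_comparisons, using exact noncentral-t power.
#'
#' @param effect_size_d Cohen's d (> 0), default 0.8.
#' @param alpha nominal level (default 0.05).
#' @param power target power (default 0.80).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return integer n per group (>= 2).
#' @export
min_sample_size <- function(effect_size_d = 0.8, alpha = 0.05, power = 0.8,
                            n_comparisons = 1) {
  stopifnot(effect_size_d > 0, alpha > 0, alpha < 1, power > 0.5, power < 1)
  a <- alpha / n_comparisons
  for (n in 2:100000) {
    df <- 2 * n - 2
    ncp <- effect_size_d * sqrt(n / 2)
    tc <- stats::qt(1 - a / 2, df)
    pw <- 1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
    if (pw >= power) return(n)
  }
  stop("no n found")
}

#' Class-level size-detrended BAI chronologies
#'
#' Tukey biweight aggregation of per-tree bai_sdt series within each
#' demographic class at stand, region or network level; years with sample
#' depth below the power-analysis threshold are masked.
#'
#' @param bai_sdt long table with `tree_id`, `year`, `bai_sdt`.
#' @param meta tree metadata with `tree_id`, `age_yr`, `dbh_cm` and the
#'   level column.
#' @param level aggregation level column (`"region_id"`, `"stand_id"`) or
#'   `"network"`.
#' @param min_depth minimum per-year depth; default the
#'   [min_sample_size()] threshold for d = 0.8.
#' @return named list of chronologies keyed `<level>|<age>|<size>`.
#' @export
build_class_chronology <- function(bai_sdt, meta, level = "region_id",
                                   min_depth = NULL) {
  if (is.null(min_depth)) min_depth <- min_sample_size()
  cls <- assign_class(meta$age_yr, meta$dbh_cm)
  meta$class <- paste(cls$age_class, cls$size_class, sep = "|")
  lev <- if (level == "network") rep("network", nrow(meta)) else meta[[level]]
  out <- list()
  years <- sort(unique(bai_sdt$year))
  for (u in unique(lev)) {
    for (cl in unique(meta$class[lev == u])) {
      ids <- meta$tree_id[lev == u & meta$class == cl]
      sub <- bai_sdt[bai_sdt$tree_id %in% ids, ]
      if (nrow(sub) == 0) next
      m <- matrix(NA_real_, length(years), length(ids),
                  dimnames = list(years, ids))
      m[cbind(match(sub$year, years), match(sub$tree_id, ids))] <- sub$bai_sdt
      key <- paste(u, cl, sep = "|")
      out[[key]] <- tryCatch(
        build_chronology(m, min_depth = min_depth, label = key),
        error = function(e) NULL)
      if (is.null(out[[key]])) out[[key]] <- NULL
    }
  }
  out
}
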