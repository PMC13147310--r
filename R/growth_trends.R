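#' Sen's slope
#'
#' Median of all pairwise slopes (x_j - x_i)/(j - i), i < j, on a regularly
#' spaced series (or against supplied time points).
#'
#' @param x numeric series with at least 5 finite values.
#' @param t time points (default 1..n).
#' @return slope in units of x per unit time.
#' @export
sen_slope <- function(x, t = seq_along(x)) {
  ok <- is.finite(x) & is.finite(t)
  x <- x[ok]; t <- t[ok]
  if (length(x) < 5) stop("need at least 5 finite values")
  dx <- outer(x, x, `-`)
  dt <- outer(t, t, `-`)
  stats::median(dx[lower.tri(dx)] / dt[lower.tri(dt)])
}

#' Variance-corrected Mann-Kendall trend test
#'
#' S and tau by pair counting with tie-corrected variance; serial
#' correlation is handled through an effective-sample-size variance
#' inflation computed from the autocorrelation structure of the
#' Sen-detrended series. The autocorrelation is taken from an AR(p <= 3)
#' model selected by AIC (Burg estimation, small-sample bias correction at
#' order 1) so that an uncorrelated series yields no correction and a
#' persistent one contributes its full geometric tail, rather than from
#' noisy per-lag empirical estimates. `variant = "hamed-rao"` (default)
#' applies the rank-based third-order weights to the rank series;
#' `"yue-wang"` uses the (1 - i/n) weights on the detrended series;
#' `"none"` skips the correction. The factor is clamped at 1: the
#' correction only ever widens the variance.
#'
#' @param x numeric series, >= 10 values, not all tied.
#' @param variant correction variant.
#' @return list `S`, `tau`, `var_s` (corrected), `p` (two-sided, with
#'   continuity correction), `correction` (variance inflation factor).
#' @export
mann_kendall_corrected <- function(x, variant = c("hamed-rao", "yue-wang", "none")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10) stop("need at least 10 values")
  if (length(unique(x)) == 1) stop("all values tied")
  sgn <- sign(outer(x, x, `-`))
  S <- sum(sgn[lower.tri(sgn)]) # lower.tri entries are x_later - x_earlier
  ties <- table(x)
  ties <- ties[ties > 1]
  var0 <- (n * (n - 1) * (2 * n + 5) -
           sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  tau <- S / sqrt(n * (n - 1) / 2 * (n * (n - 1) / 2 -
                  sum(ties * (ties - 1) / 2)))
  cf <- 1
  if (variant != "none") {
    detr <- x - sen_slope(x) * seq_len(n)
    base <- if (variant == "hamed-rao") rank(detr) else detr
    fit <- stats::ar(base, aic = TRUE, order.max = 3, method = "burg")
    if (fit$order > 0) {
      coefs <- fit$ar
      if (fit$order == 1) { # small-sample bias correction for AR(1)
        coefs <- min(0.99, coefs + (1 + 3 * coefs) / n)
      }
      rho <- stats::ARMAacf(ar = coefs, lag.max = n - 3)[-1]
      i <- seq_len(n - 3)
      cf <- if (variant == "hamed-rao") {
        1 + 2 / (n * (n - 1) * (n - 2)) *
          sum((n - i) * (n - i - 1) * (n - i - 2) * rho)
      } else {
        1 + 2 * sum((1 - i / n) * rho)
      }
      cf <- max(cf, 1) # inflation-only: guard the trend test, never sharpen it
    }
  }
  var_s <- var0 * cf
  z <- if (S > 0) (S - 1) / sqrt(var_s) else if (S < 0) (S + 1) / sqrt(var_s) else 0
  list(S = S, tau = tau, var_s = var_s,
       p = 2 * stats::pnorm(-abs(z)), correction = cf)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p raw p-values in \[0, 1\].
#' @return adjusted p-values (monotone step-up).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Tree-level trend records
#'
#' Sen slope and corrected Mann-Kendall test of each tree's bai_sdt over a
#' period, BH-adjusted across trees, with a direction classification at
#' alpha on the adjusted p.
#'
#' @param bai_sdt long table `tree_id`, `year`, `bai_sdt`.
#' @param period two-element year range (default c(1980, 2020)).
#' @param min_years minimum in-period years per tree (default 20).
#' @param alpha significance level for the direction call (default 0.05).
#' @param value_col column to analyse: the default `"bai_sdt_cm2"`
#'   (size-detrended BAI in original units) yields slopes in cm^2/yr with
#'   the same tau/p/direction as the unitless ratio, since the two differ
#'   only by a per-tree positive constant.
#' @return data frame: tree_id, sen_slope, tau, p, p_adj, direction.
#' @export
tree_trends <- function(bai_sdt, period = c(1980, 2020), min_years = 20,
                        alpha = 0.05, value_col = "bai_sdt_cm2") {
  d <- bai_sdt[bai_sdt$year >= period[1] & bai_sdt$year <= period[2], ]
  ids <- unique(d$tree_id)
  out <- lapply(ids, function(id) {
    v <- d[d$tree_id == id, ]
    v <- v[order(v$year), ]
    if (nrow(v) < min_years) return(NULL)
    mk <- tryCatch(mann_kendall_corrected(v[[value_col]]), error = function(e) NULL)
    if (is.null(mk)) return(NULL)
    data.frame(tree_id = id, sen_slope = sen_slope(v[[value_col]], v$year),
               tau = mk$tau, p = mk$p)
  })
  out <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  out$p_adj <- bh_adjust(out$p)
  out$direction <- ifelse(out$p_adj >= alpha, "none",
                          ifelse(out$sen_slope > 0, "positive", "negative"))
  out$direction <- factor(out$direction, levels = c("positive", "negative", "none"))
  out
}

#' Shares of positive/negative/no-trend trees with a chi-squared test
#'
#' Per-cell shares of trend directions and a chi-squared test on the
#' positive-vs-negative contingency table across cells (with an exact-test
#' fallback when expected counts fall below 5).
#'
#' @param trends tree trend records (from [tree_trends()]).
#' @param grouping factor/character vector aligned with `trends` rows (a
#'   single cell is fine: the test then reduces to a 1 x 2 goodness-of-fit).
#' @return list `shares` (per-cell proportions and counts), `test`
#'   (statistic, p, method).
#' @export
trend_direction_summary <- function(trends, grouping = rep("all", nrow(trends))) {
  tab <- table(grouping, trends$direction)
  shares <- prop.table(tab, margin = 1)
  pn <- tab[, c("positive", "negative"), drop = FALSE]
  if (nrow(pn) >= 2) {
    expected <- outer(rowSums(pn), colSums(pn)) / sum(pn)
    if (any(expected < 5)) {
      tst <- stats::fisher.test(pn, simulate.p.value = nrow(pn) > 2)
      test <- list(statistic = NA_real_, p = tst$p.value,
                   method = "Fisher exact (expected counts < 5)")
    } else {
      tst <- stats::chisq.test(pn, correct = FALSE)
      test <- list(statistic = unname(tst$statistic), p = tst$p.value,
                   method = "chi-squared")
    }
  } else {
    tst <- stats::chisq.test(as.vector(pn))
    test <- list(statistic = unname(tst$statistic), p = tst$p.value,
                 method = "chi-squared goodness-of-fit")
  }
  list(shares = shares, counts = tab, test = test)
}

#' Aligned rank transform (ART) two-way ANOVA
#'
#' For each effect (A, B, A x B) the response is aligned by removing the
#' cell-mean estimates of the other effects, ranked, and analysed with a
#' standard factorial ANOVA on the ranks; only the matching effect's F and
#' p are kept. An alignment check verifies that the summed ranks of the
#' stripped effects stay near-uniform.
#'
#' @param y numeric response.
#' @param a,b factors (>= 2 levels each, >= 3 replicates per cell).
#' @return data frame per effect: F, df1, df2, p, align_ok.
#' @export
art_anova <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("each factor needs >= 2 levels")
  if (any(table(a, b) == 0)) stop("empty cells")
  if (any(table(a, b) < 3)) warning("cells with fewer than 3 replicates")
  mu <- mean(y)
  am <- stats::ave(y, a)
  bm <- stats::ave(y, b)
  cm <- stats::ave(y, interaction(a, b))
  resid <- y - cm
  aligned <- list(
    A  = resid + (am - mu),
    B  = resid + (bm - mu),
    AB = resid + (cm - am - bm + mu)
  )
  # stripped effects should leave (near-)zero level means in the aligned column
  stripped_ok <- function(v, f) {
    tol <- max(0.05 * stats::sd(y), 1e-8)
    all(abs(tapply(v, f, mean)) < tol)
  }
  others <- list(A = list(b), B = list(a), AB = list(a, b))
  out <- lapply(names(aligned), function(eff) {
    r <- rank(aligned[[eff]])
    if (stats::sd(r) == 0) { # fully degenerate alignment (identical cells)
      return(data.frame(effect = eff, F = 0, df1 = NA, df2 = NA, p = 1,
                        align_ok = TRUE))
    }
    fit <- stats::anova(stats::lm(r ~ a * b))
    row <- switch(eff, A = "a", B = "b", AB = "a:b")
    data.frame(effect = eff, F = fit[row, "F value"],
               df1 = fit[row, "Df"], df2 = fit["Residuals", "Df"],
               p = fit[row, "Pr(>F)"],
               align_ok = all(vapply(others[[eff]], function(f)
                 stripped_ok(aligned[[eff]], f), logical(1))))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' OLS regression with heteroscedasticity-consistent (HC3) errors
#'
#' @param y response.
#' @param x single predictor (non-constant), n >= 10.
#' @return one-row data frame: beta, hc_se, t, p (slope only).
#' @export
hc_regression <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 10) stop("need n >= 10")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  v <- sandwich::vcovHC(fit, type = "HC3")
  se <- sqrt(v["x", "x"])
  beta <- stats::coef(fit)[["x"]]
  tval <- beta / se
  data.frame(beta = beta, hc_se = se, t = tval,
             p = 2 * stats::pt(-abs(tval), df = fit$df.residual))
}
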