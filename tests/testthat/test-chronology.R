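test_that("core filtering applies the 30 mm / 20 yr pith rule", {
  meta <- data.frame(tree_id = c("a", "b", "c", "d"),
                     pith_offset_mm = c(10, 31, 5, 0),
                     pith_offset_years = c(5, 5, 25, 0),
                     cross_datable = c(TRUE, TRUE, TRUE, FALSE))
  out <- filter_cores(meta)
  expect_equal(out$retained, "a")
  expect_equal(out$log$reason[out$log$tree_id == "b"], "pith distance")
  expect_equal(out$log$reason[out$log$tree_id == "c"], "pith years")
  expect_equal(out$log$reason[out$log$tree_id == "d"], "not cross-datable")
  empty <- filter_cores(data.frame(tree_id = character()))
  expect_length(empty$retained, 0)
})

test_that("spline detrending divides out smooth growth trends", {
  t <- 1:120
  smooth <- 3 * exp(-t / 80)
  rwi <- spline_detrend(smooth)
  expect_lt(max(abs(rwi - 1)), 0.02)
  expect_lt(abs(mean(rwi) - 1), 0.05)
  # scale invariance
  set.seed(10)
  w <- smooth * exp(rnorm(120, 0, 0.2))
  expect_equal(spline_detrend(w), spline_detrend(7.3 * w), tolerance = 1e-10)
  # a 3-year cycle survives detrending nearly intact
  w3 <- smooth * (1 + 0.2 * sin(2 * pi * t / 3))
  rwi3 <- spline_detrend(w3)
  cyc <- sin(2 * pi * t / 3)
  amp <- coef(lm(rwi3[20:100] ~ cyc[20:100]))[2] / 0.2
  expect_gt(amp, 0.9)
  expect_error(spline_detrend(rep(1, 10)), "15")
  expect_error(spline_detrend(c(rep(1, 20), -1)), "positive")
})

test_that("AR prewhitening removes persistence and preserves white noise", {
  set.seed(11)
  r1 <- function(x) cor(x[-1], x[-length(x)])
  wn <- rnorm(150)
  out <- ar_prewhiten(wn)
  expect_lt(abs(r1(out)), 0.15)
  expect_gt(cor(out, wn), 0.95)
  ar1 <- as.numeric(arima.sim(list(ar = 0.6), 200))
  expect_lt(abs(r1(ar_prewhiten(ar1))), 0.1)
  expect_warning(out <- ar_prewhiten(rep(2, 30)), "constant")
  expect_equal(out, rep(2, 30))
  expect_error(ar_prewhiten(c(rnorm(30), NA)), "finite")
})

test_that("rbar/EPS statistics follow the closed form", {
  yrs <- 1:60
  base <- sin(yrs / 3)
  m <- cbind(a = base, b = base, c = base)
  st <- chronology_stats(m)
  expect_equal(st$rbar, 1)
  expect_equal(st$eps, 1)
  expect_true(st$reliable)
  expect_equal(eps_from_rbar(10, 0.3), 3 / 3.7, tolerance = 1e-12)
  expect_equal(eps_from_rbar(10, 0.3), 0.8108, tolerance = 1e-4)
  expect_equal(eps_from_rbar(8, 0), 0)
  # EPS monotone in n and rbar
  expect_gt(eps_from_rbar(20, 0.3), eps_from_rbar(10, 0.3))
  expect_gt(eps_from_rbar(10, 0.5), eps_from_rbar(10, 0.3))
  # rbar equals the mean of the plain pairwise correlations
  set.seed(12)
  sig <- rnorm(60)
  m2 <- sapply(1:4, function(i) sig + rnorm(60))
  st2 <- chronology_stats(m2)
  cm <- cor(m2)
  expect_equal(st2$rbar, mean(cm[lower.tri(cm)]), tolerance = 1e-12)
  expect_error(chronology_stats(m2[1:5, ]), "overlap")
})

test_that("demographic group labels mark the quantile corners only", {
  set.seed(13)
  meta <- data.frame(tree_id = sprintf("t%02d", 1:40),
                     region_id = "r1",
                     age_yr = c(seq(20, 400, length.out = 39), 200),
                     dbh_cm = c(seq(12, 90, length.out = 39), 45))
  out <- assign_demographic_group(meta)
  qa <- quantile(meta$age_yr, c(0.25, 0.75))
  qd <- quantile(meta$dbh_cm, c(0.25, 0.75))
  corner <- out[out$age_yr >= qa[2] & out$dbh_cm >= qd[2], ]
  expect_true(all(corner$group == "l_o"))
  mid <- out[out$age_yr > qa[1] & out$age_yr < qa[2] &
             out$dbh_cm > qd[1] & out$dbh_cm < qd[2], ]
  expect_true(all(mid$group == "none"))
  # partition: no tree carries two labels, labels only from the corner set
  expect_true(all(table(out$tree_id) == 1))
  expect_error(assign_demographic_group(
    data.frame(tree_id = 1:10, region_id = "r", age_yr = 100, dbh_cm = 30)),
    "degenerate")
  expect_error(assign_demographic_group(meta[1:5, ]), "fewer than 8")
})

test_that("chronology aggregation honours depth, symmetry and identity", {
  yrs <- 1951:2010
  m <- matrix(NA_real_, 60, 3, dimnames = list(yrs, c("x", "y", "z")))
  set.seed(14)
  m[, "x"] <- 1 + rnorm(60, 0, 0.1)
  ch1 <- build_chronology(m, members = "x", min_depth = 1)
  expect_equal(ch1$index, unname(m[, "x"]))
  d <- rnorm(60, 0, 0.1)
  m[, "y"] <- 1 + d; m[, "z"] <- 1 - d
  ch2 <- build_chronology(m, members = c("y", "z"), min_depth = 2)
  expect_equal(ch2$index, rep(1, 60), tolerance = 1e-8)
  expect_true(all(ch2$depth == 2))
  expect_error(build_chronology(m, members = "absent"), "empty")
})
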