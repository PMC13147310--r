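make_trend_rec <- function(tree_id, slope, direction) {
  data.frame(tree_id = tree_id, sen_slope = slope, tau = sign(slope) * 0.5,
             p = 0.001, p_adj = ifelse(direction == "none", 0.5, 0.001),
             direction = factor(direction,
                                levels = c("positive", "negative", "none")))
}

test_that("class contributions convert units as stated", {
  # one tree, slope +10 cm2/yr, 100 trees/ha equivalent (plot 100 m2)
  meta <- data.frame(tree_id = "t1", stand_id = "s1", dbh_cm = 45,
                     age_yr = 150, plot_area_m2 = 100)
  out <- class_contribution(make_trend_rec("t1", 10, "positive"), meta)
  pos <- out[out$direction == "positive" & out$n_trees > 0, ]
  expect_equal(pos$contribution, 10 * 1e-4 * 100) # +0.1 m2 ha-1 yr-1
  # direction 'none' contributes nothing
  out0 <- class_contribution(make_trend_rec("t1", 10, "none"), meta)
  expect_true(all(out0$contribution == 0))
  expect_true(all(out0$empty))
  # equal-BA trees with opposite slopes: symmetric contributions
  meta2 <- data.frame(tree_id = c("a", "b"), stand_id = "s1",
                      dbh_cm = 45, age_yr = 150, plot_area_m2 = 1500)
  tr2 <- rbind(make_trend_rec("a", 10, "positive"),
               make_trend_rec("b", -10, "negative"))
  out2 <- class_contribution(tr2, meta2)
  cc <- out2[out2$n_trees > 0, ]
  expect_equal(sum(cc$contribution), 0, tolerance = 1e-12)
  expect_equal(abs(cc$contribution[1]), abs(cc$contribution[2]))
})

test_that("net trends aggregate stand contributions with partition identity", {
  stands <- sprintf("s%02d", 1:12)
  contrib <- rbind(
    data.frame(stand_id = stands, age_class = "<100", size_class = "10-39",
               direction = "positive", contribution = 0.1, ba_share = 0.5,
               n_trees = 5, empty = FALSE),
    data.frame(stand_id = stands, age_class = "<100", size_class = "40-60",
               direction = "negative", contribution = -0.05, ba_share = 0.5,
               n_trees = 5, empty = FALSE))
  info <- data.frame(stand_id = stands,
                     region_id = rep(c("r1", "r2", "r3", "r4"), each = 3),
                     gradient = rep(c("mesic", "xeric"), each = 6))
  out <- regional_net_trend(contrib, info, "region_id", n_boot = 200)
  expect_equal(out$y_net, rep(0.05, 4))
  expect_true(all(out$ci_low <= 0.05 & out$ci_high >= 0.05))
  net <- network_net_trend(contrib, info, n_boot = 200)
  expect_equal(net$network, sum(net$by_gradient$y_net))
  expect_equal(net$network, 0.1) # two gradient cells of +0.05 each
  # symmetric contributions: bootstrap CI covers zero at near-nominal rate
  set.seed(30)
  cover <- mean(replicate(200, {
    cc <- contrib
    cc$contribution <- sample(c(-0.1, 0.1), nrow(cc), replace = TRUE)
    o <- regional_net_trend(cc, info, "network", n_boot = 200,
                            seed = sample.int(1e6, 1))
    o$ci_low <= 0 && o$ci_high >= 0
  }))
  expect_gte(cover, 0.93)
})

test_that("DPI is the share-weighted sum of class slopes", {
  shares <- data.frame(stand_id = "s1", year = 2000,
                       class = c("A", "B"), share = c(0.5, 0.5))
  betas <- data.frame(stand_id = "s1", class = c("A", "B"),
                      beta = c(0.2, -0.1))
  expect_equal(dpi_index(shares, betas)$dpi, 0.05)
  single <- data.frame(stand_id = "s1", year = 2000, class = "A", share = 1)
  expect_equal(dpi_index(single, betas)$dpi, 0.2)
  # linearity in beta
  betas2 <- betas; betas2$beta <- 3 * betas2$beta
  expect_equal(dpi_index(shares, betas2)$dpi, 3 * dpi_index(shares, betas)$dpi)
  zero <- betas; zero$beta <- 0
  expect_equal(dpi_index(shares, zero)$dpi, 0)
  bad <- shares; bad$share <- c(0.5, 0.6)
  expect_error(dpi_index(bad, betas), "sum to 1")
  expect_error(dpi_index(shares, betas[1, ]), "missing")
})

test_that("class slope medians fall back to the region when sparse", {
  meta <- data.frame(tree_id = sprintf("t%d", 1:8),
                     stand_id = rep(c("s1", "s2"), c(6, 2)),
                     region_id = "r1", age_yr = 150, dbh_cm = 45,
                     plot_area_m2 = 1500)
  tr <- make_trend_rec(meta$tree_id, c(1, 2, 3, 4, 5, 6, 10, 20), "positive")
  out <- class_slope_medians(tr, meta, min_trees = 3)
  expect_equal(out$beta[out$stand_id == "s1"], median(1:6))
  expect_equal(out$source[out$stand_id == "s2"], "region")
  expect_equal(out$beta[out$stand_id == "s2"],
               median(c(1, 2, 3, 4, 5, 6, 10, 20)))
})

test_that("the stand-year table standardizes and orients its pieces", {
  fx <- default_net()
  sm <- suppressWarnings(fit_size_model(fx$bai, fx$net$tree_meta))
  bs <- size_detrend(fx$bai, sm, fx$net$tree_meta)
  tr <- tree_trends(bs)
  sy <- build_stand_year_table(fx$bai, fx$net$tree_meta, fx$net$stands,
                               fx$net$climate, tr)
  expect_true(all(sy$bai_stand > 0))
  expect_true(all(sy$gini_dbh >= 0 & sy$gini_dbh < 1))
  expect_equal(sort(unique(sy$year)), 1980:2020)
  # northness: cos(aspect)
  i <- match(sy$stand_id, fx$net$stands$stand_id)
  expect_equal(sy$northness, cos(fx$net$stands$aspect_deg[i] * pi / 180))
  # PC1 loads on the prior-summer block by construction: correlation with
  # prior-summer Tmax exceeds correlation with current spring CWB
  ps <- seasonal_aggregate(fx$net$climate, "tmax", "p_summer")
  v1 <- ps$value[match(paste(sy$stand_id, sy$year), paste(ps$stand_id, ps$year))]
  cs <- seasonal_aggregate(fx$net$climate, "cwb", "spring")
  v2 <- cs$value[match(paste(sy$stand_id, sy$year), paste(cs$stand_id, cs$year))]
  expect_gt(abs(cor(sy$pc1, v1)), abs(cor(sy$pc1, v2)))
})

test_that("aspect extremes map to the northness poles", {
  expect_equal(cos(0 * pi / 180), 1)
  st <- data.frame(stand_id = "s", aspect_deg = 180)
  expect_equal(cos(st$aspect_deg * pi / 180), -1)
})

test_that("the productivity GLMM recovers known coefficients", {
  sy <- simulate_stand_years(n_stands = 100, n_years = 40, seed = 31)
  fit <- fit_productivity_glmm(sy)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "dpi"] - 0.5), 0.1)
  expect_lt(abs(co$estimate[co$term == "ba"] - 0.3), 0.1)
  expect_true(fit$r2[["r2_marginal"]] <= fit$r2[["r2_conditional"]])
  expect_lte(fit$r2[["r2_conditional"]], 1)
  expect_false(fit$vif_flag) # orthogonal simulated predictors
  expect_gt(fit$semi_partial$delta_r2m[fit$semi_partial$term == "dpi"], 0.02)
})

test_that("a truth without year effects yields a tiny year variance", {
  sy <- simulate_stand_years(n_stands = 60, n_years = 30, sd_year = 0,
                             seed = 32)
  fit <- fit_productivity_glmm(sy)
  v_year <- fit$varcomp$vcov[fit$varcomp$grp == "year"]
  v_res <- fit$varcomp$vcov[fit$varcomp$grp == "Residual"]
  expect_lt(v_year, 0.05 * v_res)
})

test_that("model selection keeps signal, drops noise, respects hierarchy", {
  sy <- simulate_stand_years(n_stands = 60, n_years = 25, seed = 33)
  sel <- select_model(sy, terms = c(productivity_terms(), "noise"))
  expect_true("dpi" %in% sel$kept_terms)
  expect_true("ba" %in% sel$kept_terms)
  expect_false("noise" %in% sel$kept_terms)
  # interactions are never outlived by their main effects
  for (st in sel$selection) {
    mains <- unique(unlist(strsplit(st$term[grepl(":", st$term)], ":")))
    expect_false(any(setdiff(st$term, st$term[grepl(":", st$term)]) %in% mains))
  }
  expect_false(is.null(sel$dpi_comparison))
  expect_lt(sel$dpi_comparison$p, 0.05)
  expect_gt(sel$dpi_comparison$delta_aic, 0)
})

test_that("contribution mixed model recovers an imposed gradient gap", {
  set.seed(34)
  stands <- sprintf("s%02d", 1:24)
  info <- data.frame(stand_id = stands,
                     region_id = rep(sprintf("r%d", 1:8), each = 3),
                     gradient = rep(c("mesic", "xeric"), each = 12))
  gap <- 0.3
  contrib <- do.call(rbind, lapply(stands, function(s) {
    gr <- info$gradient[info$stand_id == s]
    data.frame(stand_id = s,
               age_class = rep(c("<100", "100-199"), each = 2),
               size_class = "10-39",
               direction = rep(c("positive", "negative"), 2),
               contribution = c(0.5 + (gr == "mesic") * gap, -0.2, 0.3, -0.1) +
                 rnorm(4, 0, 0.05),
               ba_share = 0.25, n_trees = 5, empty = FALSE)
  }))
  out <- contribution_mixed_model(contrib, info)
  ct <- out$contrasts
  hit <- ct[ct$class == "<100.10-39" & ct$direction == "positive", ]
  expect_lt(abs(abs(hit$estimate) - gap), 0.15)
  expect_lt(hit$p_adj, 0.05)
})
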