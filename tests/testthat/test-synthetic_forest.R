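test_that("network config validates its invariants", {
  expect_error(network_config(year_span = c(2000, 2020)), "60")
  expect_error(network_config(drought_years = 1900), "span")
  bad_legacy <- default_drought_legacy()
  names(bad_legacy$xeric) <- c("0", "1", "2", "5")
  expect_error(network_config(drought_legacy = bad_legacy), "lags")
  expect_error(network_config(n_stands_per_region = 0))
})

test_that("null-configuration climate reproduces its climatology", {
  rp <- default_region_params("mesic")
  rp$rho <- 0; rp$stand_temp_sd <- 0
  cl <- generate_climate(rp, "s1", c(1940, 2020), warming_trend_c_per_decade = 0,
                         seed = 9)
  for (m in c(1, 7)) {
    v <- cl$tmax_c[cl$month == m]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - rp$tmax[m]), 3 * se)
    p <- cl$prec_mm[cl$month == m]
    expect_lt(abs(mean(p) - rp$prec[m]), 3 * sd(p) / sqrt(length(p)))
  }
  expect_true(all(cl$tmin_c < cl$tmax_c))
  expect_true(all(cl$prec_mm >= 0))
  expect_error(generate_climate(within(rp, rho <- 1), "s1", c(1940, 2020)),
               "rho")
  expect_error(generate_climate(rp, "s1", c(1940, 2020),
                                drought_years = 1900), "span")
})

test_that("the post-onset warming ramp is recovered by regression", {
  rp <- default_region_params("mesic")
  slopes <- vapply(1:25, function(s) {
    cl <- generate_climate(rp, "s1", c(1940, 2020), warming_onset = 1980,
                           warming_trend_c_per_decade = 0.5, seed = 100 + s)
    jja <- seasonal_aggregate(cl, "tmax", "summer")
    jja <- jja[jja$year >= 1980, ]
    unname(coef(lm(value ~ year, jja))[2]) # mean JJA Tmax per year
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.05), 0.02)
})

test_that("imposed droughts are exactly the years the selector returns", {
  fx <- default_net()
  sw <- seasonal_aggregate(fx$net$climate, "cwb", "summer")
  ev <- select_drought_years(sw)
  expect_equal(ev$years, fx$net$truth$drought_years)
  expect_true(all(ev$coverage > 0.90))
})

test_that("tree simulation is exact in the deterministic core", {
  cfg <- tree_config(noise_sd = 0, size_exponent = 0.8)
  zm <- zmat_fixture(1940:2020)
  tr <- simulate_tree(age = 60, target_dbh = 30, gamma = c(), theta = 0,
                      delta = c(), zmat = zm, drought_years = integer(),
                      config = cfg, seed = 1)
  w <- tr$widths
  expect_true(all(w > 0))
  expect_equal(length(w), 60)
  # with b < 1 ring widths decline once past the juvenile geometry
  expect_true(all(diff(w[10:60]) <= 0.011)) # monotone to rounding precision
  # DBH equals twice the reconstructed radius (seed core + widths)
  expect_equal(tr$dbh_cm, as.numeric(sprintf("%.3f", 2 * (0.25 + sum(w) / 10))),
               tolerance = 1e-6)
})

test_that("a strong prior-summer Tmax coefficient shows in tree anomalies", {
  cfg <- tree_config()
  zm <- zmat_fixture(1940:2020, seed = 8)
  neg <- 0
  for (i in 1:100) {
    tr <- simulate_tree(70, 45, gamma = c(tmax_p_summer = -0.3), theta = 0,
                        delta = c(), zmat = zm, drought_years = integer(),
                        config = cfg, seed = 1000 + i)
    yrs <- (2020 - 70 + 1):2020
    logbai <- log(pi * ((cumsum(tr$widths) / 10 + 0.25)^2 -
                        c(0.25, cumsum(tr$widths)/10 + 0.25)[1:70]^2))
    an <- residuals(lm(logbai ~ poly(seq_along(logbai), 3)))
    z <- zm[match(yrs, as.integer(rownames(zm))), "tmax_p_summer"]
    if (cor(an, z) < 0) neg <- neg + 1
  }
  expect_gte(neg, 95)
})

test_that("network generation is deterministic and covers all classes", {
  fx <- default_net()
  net2 <- generate_network(network_config(seed = 7))
  expect_identical(fx$net$tree_meta, net2$tree_meta)
  expect_identical(fx$net$rwl, net2$rwl)
  expect_identical(fx$net$climate, net2$climate)
  # byte-identical bundles
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(fx$net, d1); write_bundle(net2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  cls <- assign_class(fx$net$tree_meta$age_yr, fx$net$tree_meta$dbh_cm)
  expect_true(all(table(cls$age_class, cls$size_class) >= 30))
  # every series ends at the last year
  last <- fx$net$truth$year_span[2]
  for (s in names(fx$net$rwl)) {
    expect_true(all(!is.na(fx$net$rwl[[s]][as.character(last), ])))
  }
  expect_error(generate_network(network_config(n_regions_per_gradient = 1,
                                               n_stands_per_region = 1,
                                               n_trees_per_stand = 1,
                                               seed = 1)),
               "empty demographic class")
})

test_that("tree DBH in the metadata equals the reconstructed diameter", {
  fx <- default_net()
  for (s in names(fx$net$rwl)[1:4]) {
    w <- fx$net$rwl[[s]]
    for (id in names(w)[1:5]) {
      tot <- sum(w[[id]], na.rm = TRUE) / 10
      expect_equal(fx$net$tree_meta$dbh_cm[fx$net$tree_meta$tree_id == id],
                   2 * (0.25 + tot), tolerance = 1e-3)
    }
  }
})
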