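test_that("Sen slope equals the brute-force pairwise median", {
  t <- 1:20
  expect_equal(sen_slope(2 + 0.5 * t), 0.5)
  expect_equal(sen_slope(rep(3, 10)), 0)
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(sample(5:25, 1))
    n <- length(x)
    slopes <- c()
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      slopes <- c(slopes, (x[b] - x[a]) / (b - a))
    }
    expect_equal(sen_slope(x), median(slopes), tolerance = 1e-12)
  }
  # shift invariance and linear scaling
  x <- rnorm(15)
  expect_equal(sen_slope(x + 100), sen_slope(x), tolerance = 1e-12)
  expect_equal(sen_slope(3 * x), 3 * sen_slope(x), tolerance = 1e-12)
  expect_error(sen_slope(1:4), "5")
})

test_that("Mann-Kendall S and tau equal brute-force pair counts", {
  set.seed(24)
  for (i in 1:8) {
    x <- round(rnorm(sample(10:30, 1)), 1) # ties likely
    n <- length(x)
    S <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) S <- S + sign(x[b] - x[a])
    mk <- mann_kendall_corrected(x, variant = "none")
    expect_equal(mk$S, S)
    expect_equal(mk$tau, cor(seq_len(n), x, method = "kendall"),
                 tolerance = 1e-10)
  }
  up <- mann_kendall_corrected(c(1:11 + 0.1 * rnorm(11)), variant = "none")
  expect_lt(up$p, 0.01)
  expect_error(mann_kendall_corrected(rep(1, 15)), "tied")
  expect_error(mann_kendall_corrected(rnorm(5)), "10")
})

test_that("serial-correlation correction inflates the variance under AR(1)", {
  set.seed(25)
  infl <- vapply(1:40, function(i) {
    x <- as.numeric(arima.sim(list(ar = 0.5), 60))
    mann_kendall_corrected(x, variant = "hamed-rao")$correction
  }, numeric(1))
  expect_gt(mean(infl), 1.3) # positive autocorrelation widens the variance
  yw <- vapply(1:40, function(i) {
    set.seed(400 + i)
    x <- as.numeric(arima.sim(list(ar = 0.5), 60))
    mann_kendall_corrected(x, variant = "yue-wang")$correction
  }, numeric(1))
  expect_gt(mean(yw), 1.3)
})

test_that("BH adjustment reproduces the hand step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  set.seed(26)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("direction shares and the chi-squared test match hand arithmetic", {
  # 2x2 table {{30,10},{10,30}}: chi-squared = sum (O-E)^2/E = 20
  tr <- data.frame(tree_id = seq_len(80),
                   sen_slope = rep(c(1, -1, 1, -1), c(30, 10, 10, 30)),
                   tau = 0.5, p = 0.001, p_adj = 0.001,
                   direction = factor(rep(c("positive", "negative",
                                            "positive", "negative"),
                                          c(30, 10, 10, 30)),
                                      levels = c("positive", "negative", "none")))
  g <- rep(c("g1", "g2"), each = 40)
  out <- trend_direction_summary(tr, g)
  O <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(out$test$statistic, sum((O - E)^2 / E))
  expect_equal(out$test$statistic, 20)
  # symmetric table: statistic 0, p 1
  tr$direction <- factor(rep(c("positive", "negative"), 40),
                         levels = levels(tr$direction))
  out2 <- trend_direction_summary(tr, g)
  expect_equal(out2$test$statistic, 0)
  expect_equal(out2$test$p, 1)
  # small expected counts fall back to the exact test
  tr3 <- tr[1:12, ]; g3 <- rep(c("g1", "g2"), each = 6)
  out3 <- trend_direction_summary(tr3, g3)
  expect_match(out3$test$method, "Fisher")
})

test_that("ART ANOVA isolates main effects and degenerates gracefully", {
  set.seed(27)
  a <- gl(2, 20); b <- rep(gl(2, 10), 2)
  y <- ifelse(a == "1", 0, 3) + rnorm(40, 0, 0.3) # pure A effect
  out <- art_anova(y, a, b)
  expect_gt(out$F[out$effect == "A"], 50)
  expect_lt(out$F[out$effect == "B"], 4)
  expect_lt(out$F[out$effect == "AB"], 4)
  expect_true(all(out$align_ok))
  # identical cells: no effect anywhere
  out0 <- art_anova(rep(2, 40), a, b)
  expect_equal(out0$F, rep(0, 3))
  expect_error(art_anova(y[1:20], gl(2, 10), gl(1, 20)), "2 levels")
})

test_that("HC3 errors agree with classical ones under homoskedasticity", {
  set.seed(28)
  ratio <- vapply(1:100, function(i) {
    x <- rnorm(200); y <- 1 + 0.5 * x + rnorm(200)
    fit <- lm(y ~ x)
    hc <- hc_regression(y, x)
    hc$hc_se / summary(fit)$coefficients["x", "Std. Error"]
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.15)
  expect_error(hc_regression(rnorm(20), rep(1, 20)), "constant")
})

test_that("tree trend records classify directions at the adjusted level", {
  set.seed(29)
  yrs <- 1980:2020
  mk_tree <- function(id, slope) {
    data.frame(tree_id = id, year = yrs,
               bai_sdt_cm2 = 10 + slope * (yrs - 1980) + rnorm(41, 0, 0.5))
  }
  d <- rbind(mk_tree("up", 0.4), mk_tree("down", -0.4), mk_tree("flat", 0))
  tr <- tree_trends(d)
  expect_equal(as.character(tr$direction[tr$tree_id == "up"]), "positive")
  expect_equal(as.character(tr$direction[tr$tree_id == "down"]), "negative")
  expect_equal(as.character(tr$direction[tr$tree_id == "flat"]), "none")
  expect_lt(abs(tr$sen_slope[tr$tree_id == "up"] - 0.4), 0.1)
})
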