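# shared fixtures, generated once per test run

.fixture_env <- new.env(parent = emptyenv())

# default-size synthetic network (480 trees) plus the derived objects most
# tests need; built lazily and cached
default_net <- function() {
  if (is.null(.fixture_env$net)) {
    net <- generate_network(network_config(seed = 7))
    rwl <- combine_rwl(net$rwl)
    res <- build_residual_series(rwl)
    meta <- assign_demographic_group(net$tree_meta)
    bai <- bai_from_rw(rwl, net$tree_meta)$bai
    .fixture_env$net <- list(net = net, rwl = rwl, residuals = res$residuals,
                             meta = meta, bai = bai)
  }
  .fixture_env$net
}

# tiny single-stand monthly climate table with constant values
constant_climate <- function(years = 1950:1999, tmin = 5, tmax = 15,
                             prec = 80, lat = 47) {
  compute_cwb(data.frame(stand_id = "s1",
                         year = rep(years, each = 12),
                         month = rep(1:12, length(years)),
                         tmin_c = tmin, tmax_c = tmax, prec_mm = prec,
                         lat = lat))
}

# z-score matrix with named climate columns for simulate_tree()
zmat_fixture <- function(years, vars = c("tmax_p_summer", "cwb_p_summer",
                                         "cwb_spring", "cwb_summer",
                                         "tmax_summer", "tmin_spring"),
                         seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(length(years) * length(vars)), length(years), length(vars),
              dimnames = list(years, vars))
  scale(z)[, , drop = FALSE]
}

# minimal config for direct simulate_tree() calls
tree_config <- function(...) {
  network_config(n_trees_per_stand = 12, ...)
}

# stand-year records simulated directly from the productivity model with
# known coefficients (for GLMM recovery checks)
simulate_stand_years <- function(n_stands = 100, n_years = 40,
                                 beta = c(dpi = 0.5, ba = 0.3, density = 0.2,
                                          gini_dbh = 0.15, gini_age = 0,
                                          pc1 = 0.08, pc2 = 0.05,
                                          northness = 0.1, slope_deg = 0,
                                          noise = 0),
                                 sd_region = 0.15, sd_stand = 0.2,
                                 sd_year = 0.1, sd_resid = 0.3, seed = 1) {
  set.seed(seed)
  n_regions <- max(4, round(n_stands / 10))
  region_of <- rep_len(seq_len(n_regions), n_stands)
  years <- seq(2021 - n_years, 2020)
  u_reg <- rnorm(n_regions, 0, sd_region)
  u_std <- rnorm(n_stands, 0, sd_stand)
  u_yr <- rnorm(n_years, 0, sd_year)
  stand_vals <- list(ba = rnorm(n_stands), density = rnorm(n_stands),
                     gini_dbh = rnorm(n_stands), gini_age = rnorm(n_stands),
                     northness = rnorm(n_stands), slope_deg = rnorm(n_stands))
  d <- expand.grid(stand = seq_len(n_stands), yi = seq_len(n_years))
  sy <- data.frame(stand_id = sprintf("s%03d", d$stand),
                   region_id = sprintf("r%02d", region_of[d$stand]),
                   year = years[d$yi],
                   dpi = rnorm(nrow(d)), pc1 = rnorm(nrow(d)),
                   pc2 = rnorm(nrow(d)), noise = rnorm(nrow(d)),
                   weight = 1,
                   gradient = factor(ifelse(region_of[d$stand] %% 2 == 0,
                                            "mesic", "xeric")))
  for (v in names(stand_vals)) sy[[v]] <- stand_vals[[v]][d$stand]
  lin <- rep(0, nrow(d))
  for (v in names(beta)) lin <- lin + beta[[v]] * sy[[v]]
  sy$log_bai <- lin + u_reg[region_of[d$stand]] + u_std[d$stand] +
    u_yr[d$yi] + rnorm(nrow(d), 0, sd_resid)
  sy
}
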