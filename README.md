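# demodendro

Demographically stratified dendroecological analysis of tree growth.

Large-scale tree-ring studies usually infer forest responses to climate from
canopy-dominant trees, implicitly assuming that all age and size cohorts
respond alike. `demodendro` implements the full analysis chain needed to test
that assumption on a hierarchical tree-ring network (regions → stands →
trees) spanning a summer-moisture gradient, for dendroecologists and forest
ecologists working with ring-width (`.rwl`) collections, per-tree metadata
and monthly climate series:

* **Climate engine** — potential evapotranspiration by the modified
  Hargreaves formula, `PET = 0.0013 · 0.408 Ra (Tavg + 17)
  (TD − 0.0123 P)^0.76` per day, climatic water balance `CWB = P − PET`,
  dendro seasonal windows (`WINTER`, `SPRING`, `SUMMER`, `GS`, `p_summer`),
  like-for-like spline detrending of climate, and a PCA split of stands
  into summer-mesic vs summer-xeric.
* **Ring-width chronologies** — core filtering (≤ 30 mm / ≤ 20 yr to pith),
  cubic-smoothing-spline detrending with a 50 % frequency-response cutoff
  at 10 years (`RWI = RW / spline`), AR prewhitening, Tukey biweight
  aggregation, `rbar` and `EPS = n·rbar / (n·rbar + 1 − rbar)` statistics,
  and demographic groups from the age × DBH quantile corners
  (`l_o`, `l_y`, `s_o`, `s_y`).
* **BAI standardization** — basal area increments from the circular
  cross-section, size detrending by the mixed model
  `log BAI ~ log DBH(t−1) + (1 + log DBH | stand) + (1 | tree)`,
  `BAI_sdt = observed / predicted`, demographic age × size classes and a
  Welch-power sample-size threshold.
* **Climate–growth response** — bootstrapped Pearson correlations over
  monthly/seasonal windows, random-effects meta-analytic pooling
  (Fisher z, DerSimonian–Laird, Hartung–Knapp), moving windows and
  correlation PCA.
* **Drought analysis** — network-wide drought selection (summer CWB
  z ≤ −1.5 in > 90 % of stands) and a double-bootstrap superposed epoch
  analysis with event-resampled confidence intervals and pseudo-event null
  bands, pooled along the gradient.
* **Growth trends** — Sen's slope, variance-corrected Mann–Kendall tests,
  BH false-discovery control, trend-direction shares with chi-squared
  tests, ART ANOVA and HC3 regressions.
* **Productivity model** — demographic class contributions
  (m² ha⁻¹ yr⁻¹), regional and network net trends, the demographic
  productivity index `DPI(s,t) = Σ_c w(s,t,c) · β(s,c)`, and a weighted
  stand-productivity mixed model with Nakagawa R², semi-partial R², VIF
  checks and leave-one-out likelihood-ratio selection.
* **Synthetic networks** — `generate_network()` builds a full network with
  known demographic climate sensitivities, xeric-only drought legacies and
  class-specific post-1980 trends, so every stage can be validated against
  ground truth.

## Worked example

Generate a synthetic network (3 regions per gradient, 9 stands each, truth:
drought years 1976/1993/2003, xeric post-drought legacy −0.06 at lags 1–3,
size exponent 1.6), then recover the droughts, the legacy and the exponent:

```r
library(demodendro)

cfg <- network_config(n_regions_per_gradient = 3, n_stands_per_region = 3,
                      n_trees_per_stand = 16, seed = 42)
net <- generate_network(cfg)
rwl <- combine_rwl(net$rwl)
res <- build_residual_series(rwl)$residuals

ev <- select_drought_years(seasonal_aggregate(net$climate, "cwb", "summer"))
ev$years
#> [1] 1976 1993 2003

stands <- net$stands$stand_id[net$stands$gradient == "xeric"]
seas <- lapply(stands, function(s) {
  ids <- net$tree_meta$tree_id[net$tree_meta$stand_id == s]
  ch <- build_chronology(res, ids, min_depth = 3, label = s)
  sea_double_bootstrap(ch, ev$years, n_event_boot = 500, n_null = 300, seed = 1)
})
pool_sea(seas)[4:7, c("lag", "departure", "ci_low", "ci_high")]
#>  lag departure ci_low ci_high
#>    0    -0.023 -0.041  -0.006
#>    1    -0.039 -0.062  -0.016
#>    2    -0.064 -0.083  -0.045
#>    3    -0.059 -0.083  -0.036

bai <- bai_from_rw(rwl, net$tree_meta)$bai
sm <- fit_size_model(bai, net$tree_meta)
round(sm$fixef[["log_d"]], 3)
#> [1] 1.593
```

The three imposed droughts are recovered exactly; the pooled ring-width
index departures after drought sit on the imposed −0.06 legacy (with the
small lag-0 dip of −0.02), and the allometric size exponent is recovered
from ~430 trees to within 0.01 of its true value.

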