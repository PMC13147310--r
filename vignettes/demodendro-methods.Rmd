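---
title: "Methods: demographically stratified growth analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographically stratified growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`demodendro` analyses how tree-ring growth and its climate sensitivity vary
across the demographic structure of a forest population — age and size
cohorts — along a summer-moisture gradient, and how that variation
aggregates into stand productivity. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
validation does and does not demonstrate.

## Two growth metrics

All analyses start from dated annual ring widths (mm, Tucson `.rwl`
format) and proceed along two standardization paths.

**Ring-width indices (RWI)** isolate the year-to-year climate signal. Each
series is divided by a cubic-smoothing-spline fit whose stiffness is set by
the standard dendrochronological criterion: a sinusoid with a 10-year
period is attenuated to 50 % of its amplitude. We implement the spline as a
discrete second-difference-penalty smoother; its transfer function
$H(\omega) = 1/(1 + \lambda(2\sin(\omega/2))^4)$ gives the closed form
$\lambda = ((1-f)/f)\,(2\sin(\pi/n_{yr}))^{-4}$, so the 50 %-at-10-years
criterion is met by construction (verified empirically to ±1 % away from
the series edges). Ratio indices are then prewhitened with an AR($p$)
model, $p \le 3$ selected by AIC, and aggregated with Tukey's biweight
robust mean (tuning constant 9 on the MAD scale). Chronology reliability is
tracked with the mean inter-series correlation $\bar r$ and the expressed
population signal $EPS = n\bar r/(n\bar r + 1 - \bar r)$; chronologies with
$EPS \le 0.80$ are flagged, never silently dropped.

**Size-detrended basal area increments (BAI_sdt)** support trend and
productivity analysis. BAI comes from the circular cross-section formula
applied to radii reconstructed inward from DBH/2. The size trend is removed
with the mixed model

$$\log BAI_{i,t} = \beta_0 + \beta_1 \log DBH_{i,t-1}
  + u_{0,stand} + u_{1,stand}\log DBH + u_{0,tree} + \varepsilon,$$

fitted by REML; `bai_sdt` is observed/predicted after back-transformation.
Predictions are back-transformed as `exp(fitted)` without a smearing
correction: the ratio form cancels the first-order bias. Because the ratio
is unitless while trend magnitudes and productivity contributions need
cm²/yr, the package also carries `bai_sdt_cm2`, the ratio rescaled by each
tree's mean predicted BAI. The rescaling is a per-tree positive constant,
so Mann–Kendall statistics, p-values and trend directions are identical on
either column; only the slope units change.

## Demographic strata

Two stratifications are deliberately distinct. **Groups** are the corners
of the joint age × DBH distribution of a reference population (the region
by default, configurable): large-old (both ≥ Q75), large-young (age ≤ Q25,
DBH ≥ Q75), small-old, small-young; interior trees are unlabeled and
excluded from group chronologies. **Classes** are fixed bins: age < 100,
100–199, 200–299, 300+ years crossed with DBH 10–39, [40, 60], > 60 cm
(the printed "40–60"/"60+" overlap is resolved as a closed upper bound at
60; configurable). Ages are taken at sampling (static), matching the
design of a one-time coring campaign. Class chronologies require a minimum
per-year sample depth derived from a Welch two-sample power analysis
(Cohen's d = 0.8, α = 0.05 with Bonferroni division, power 0.80, exact
noncentral-t iteration — n = 26 per group at one comparison).

## Climate and the moisture gradient

Monthly PET uses the modified Hargreaves formula with extraterrestrial
radiation from FAO-56 solar geometry at the mid-month Julian day; the
radicand $TD - 0.0123P$ is clamped at zero so wet months cannot produce
complex powers. CWB = P − PET, exactly additive over seasonal windows.
Seasonal windows follow the dendro convention relative to the ring year:
winter spans previous December–February, `p_summer` is the previous
June–August. Climate series entering correlations are detrended
"like-for-like" with the same spline engine used on the rings, in
difference form (anomaly = value − spline) so negative water balances stay
legal.

Stands are classified summer-mesic vs summer-xeric by the sign of the
first principal component of the centred/scaled stand-by-year summer CWB
matrix over 1980–2020, oriented so wetter stands score positive. We
deliberately use the year-resolved matrix rather than a handful of summary
statistics: with scaled summary features, uninformative features carry the
same unit variance as the moisture contrast and the leading component can
mix arbitrarily when only moisture differs between stands; the
year-resolved matrix keeps the component on the persistent between-stand
moisture offset.

## Climate–growth inference

Correlations between residual chronologies and detrended seasonal
anomalies are Pearson coefficients with percentile confidence intervals
from 1000 year-resampled bootstrap replicates (the point estimate is the
plain correlation; the bootstrap only quantifies uncertainty). Stand-level
coefficients are pooled with a random-effects meta-analysis on the Fisher
z scale: sampling variance $1/(n-3)$, DerSimonian–Laird heterogeneity,
Hartung–Knapp interval on $t_{k-1}$ (via `metafor`; the package's tests
verify the pooled values against hand-computed Fisher-z arithmetic).
Moving-window correlations default to 30-year right-aligned windows
stepped by one year.

## Drought legacies (SEA)

Severe network droughts are years in which the summer CWB z-score (over
the full analysis span, configurable) is ≤ −1.5 in more than 90 % of
stands — selected from climate only, independent of growth. The superposed
epoch analysis composites the residual chronology over lags −3…+3 around
each event, normalized to the pre-event mean (lags −3…−1), making the
pre-event departures average exactly zero. Uncertainty is double-bootstrap:
events are resampled with replacement for the confidence interval, and
pseudo-event sets drawn from non-event years give a percentile null band.
Pseudo-events respect the same minimum spacing as the 7-year window;
allowing them to overlap induces negative correlation between pseudo-event
departures and narrows the null band by ~6 %, inflating the false-positive
rate above nominal. Stand-level departures are pooled per lag with the
same random-effects machinery, using the event-bootstrap variance as the
sampling variance.

## Trend inference

Sen's slope is the median of all pairwise slopes; significance comes from
the Mann–Kendall test with tie-corrected variance and a serial-correlation
correction. Instead of summing noisy per-lag empirical autocorrelations
(which we measured to be badly anticonservative — 11 % type-I error on
white noise at the 5 % level, ~20 % under AR(1) with φ = 0.5), the
correction takes the autocorrelation function implied by an AIC-selected
AR($p \le 3$) model of the Sen-detrended ranks (Burg estimation, AR(1)
small-sample bias correction) and applies the rank-based effective-sample-
size weights; the factor is clamped at 1 so the correction only ever
widens the variance. This restores the white-noise size to ~4–5 %. Under
AR(1) φ = 0.5 the test still rejects ~10 % at n = 60 — a limitation of the
variance-correction approach itself: plugging the *true* autocorrelation
into the corrected variance still yields ~8 %. A Yue–Wang-style variant is
available behind the `variant` flag. Tree-level trends (1980–2020, ≥ 20
in-period years) are BH-adjusted across trees and classified
positive/negative/none at α = 0.05 on the adjusted p-values.

## Productivity aggregation and the GLMM

Within each stand, class and trend direction, tree Sen slopes are averaged
with basal-area weights, converted to m² (×10⁻⁴) and scaled by the
class-direction density (trees ha⁻¹), giving contributions in
m² ha⁻¹ yr⁻¹. Regional aggregates are stand means with stand-bootstrap
CIs; the network total is constructed as the sum of the two gradient
aggregates, so the partition identity "network = Σ gradient cells" holds
exactly and is tested.

The demographic productivity index is
$DPI_{s,t} = \sum_c w_{s,t,c}\,\beta_{s,c}$ with $w$ the class basal-area
share (an absolute-BA variant is exposed) and $\beta$ the stand-level
median class Sen slope over 1980–2020, falling back to the regional median
when a stand has fewer than three trees of a class.

Stand productivity is modelled as Gaussian log BAI (m² ha⁻¹ yr⁻¹) on DPI,
stand basal area, density, DBH- and age-Gini coefficients, linear and
quadratic climate principal components, northness (cos aspect), slope,
gradient type and DPI × climate interactions, with random intercepts for
stands nested in regions and for calendar year, and observation weights
equal to the number of cored trees per stand. The climate PCs are
block-wise first components — PC1 of the standardized prior-summer block
(Tmax/Tmin/CWB), PC2 of the current spring + summer block — which
guarantees the "previous summer" vs "current year" interpretation a joint
PCA would not. All continuous predictors are standardized. Reported fit
statistics: Nakagawa marginal/conditional R², per-term semi-partial R²
both as ΔR²m from refitting without the term and as a Wald $t^2/(t^2+df)$
statistic, and VIFs computed on the fixed-effects design (threshold 5,
reported, never auto-dropped). Model selection is backward leave-one-out
on maximum-likelihood fits (LRT p and ΔAIC per candidate; interactions are
droppable before their main effects), repeated for the random terms, with
a dedicated with/without-DPI comparison and a final REML refit. The model
is fitted with `lme4`/`lmerTest`; for a Gaussian identity-link model this
is interchangeable with other mixed-model engines.

## The synthetic network

`generate_network()` emulates the study conditions end to end so that
every stage can be checked against ground truth. Regional monthly climates
follow montane central-European climatologies (mesic: cool, wet summers;
xeric: warm summers with a precipitation minimum) with shared regional
AR(1) anomalies (ρ = 0.3), stand-level noise, a +0.4 °C/decade ramp on
temperatures after 1980, and three imposed network droughts (1976, 1993,
2003) forced by scaling summer precipitation until every stand's summer
CWB z-score is ≤ −1.5. Tree growth is multiplicative on BAI:

$$\log BAI_t = a + b\log D_{t-1} + \gamma' z_t
  + \delta(\mathrm{lag}) + \theta\,(t - 1980)_+ + \varepsilon_t,$$

with $b = 1.6$, noise SD 0.25, ring widths recovered from the cross-
section geometry at 0.01 mm measurement precision, and DBH emerging from
growth (the tree-level intercept is calibrated by bisection to hit a
target DBH, keeping the age–size dependence realistic; cambial ages span
25–440 years so all twelve age × size classes are populated by round-robin
cell allocation).

Group climate sensitivities $\gamma$ are nested by gradient: xeric large
trees respond to prior-summer maximum temperature (−0.30/−0.25 per SD),
xeric small trees to spring water balance; mesic groups respond to current
summer heat and spring moisture. Two deliberate design choices here: (i) a
flat group → coefficient map would impose prior-summer sensitivities in
mesic regions too and generate climate-mediated post-drought departures
there, contradicting the intended xeric-only legacy condition; (ii) the
default xeric sensitivities avoid prior-summer *CWB* because the imposed
droughts act through summer precipitation — a prior-summer CWB coefficient
would add a confounded lag-1 legacy on top of the explicit
$\delta = -0.06$ at lags 1–3, making the legacy mechanism unidentifiable
in validation. Users can of course configure such couplings. Drought
legacies are attenuated by 0.5 for the small-young group, whose
post-drought response is intended to be weaker. Class trends $\theta$
default to gains of +0.003 log-BAI/yr in small young/mid-aged trees and
declines of −0.004 in mid-sized and large young trees after 1980.
Between-tree dispersion of each $\gamma$ coefficient defaults to SD 0.05
(within-group sensitivity variance is otherwise unconstrained by the
design, so it is an explicit free parameter).

What the generator does **not** emulate: competition and spatially
explicit stand structure, mortality and recruitment, masting, measurement
and cross-dating error, nonlinear or threshold climate responses, and
species mixtures. Passing the validation suite therefore demonstrates that
the estimators recover the statistical structure they target at realistic
noise levels — not that real beech forests satisfy that structure.

## Validation problem sizes

The test suite validates at sizes chosen to balance statistical
resolution against desk-scale runtimes: the default network (4 regions ×
4 stands × 30 trees = 480 trees) for pipeline checks; 512 trees for
size-exponent recovery (±0.05); 20 replicate networks of 96 trees for
sensitivity-ordering recovery; 20 replicate networks with 30 stands per
gradient for drought-legacy power (detection = pooled CI excluding zero
at all of lags 1–3); 500-replicate null simulations for the calibration
of the bootstrap-correlation, Mann–Kendall, SEA and ART ANOVA tests; and
100 stands × 40 years for GLMM coefficient recovery (±0.1 on a true DPI
effect of +0.5). Under the default conditions individual-tree trend tests
are deliberately low-powered (class trends of ±0.003–0.004 log-BAI/yr
against residual noise of 0.25), so tree-level direction shares are small;
class-chronology and contribution-level inference, not per-tree
significance, is the intended scale of use.

## Known limitations

* The Mann–Kendall variance correction controls but does not eliminate
  type-I inflation under strong serial correlation (see above).
* The Hargreaves PET is temperature/precipitation-based; it ignores wind,
  humidity and radiation anomalies, and the CWB is not a soil-water model.
* Back-transformation of log-scale BAI predictions omits the smearing
  factor; the ratio index cancels it only to first order.
* Meta-analytic pooling treats stands as the exchangeable unit; when
  stands share regional climate the effective replication at event scale
  is closer to regions × events, which the validation sizes respect but
  the pooled CI does not model explicitly.
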