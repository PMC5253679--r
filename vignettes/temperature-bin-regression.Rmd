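---
title: "Estimating crop yield responses to temperature-bin exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating crop yield responses to temperature-bin exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropbins)
```

## The model

County crop yields respond nonlinearly to temperature: time spent in
moderately warm intervals is beneficial, while each day above roughly 30 C
cuts yields, sharply so under rainfed conditions. `cropbins` estimates this
response with a fixed-effects panel regression of log yield on the time the
growing season spends in discrete temperature intervals:

$$
\log Y_{it} = \alpha_0 + c_i + \sum_h \gamma_h\, x_{ith} +
\delta_1 P_{it} + \delta_2 P_{it}^2 + \text{(state trends)} + \varepsilon_{it},
$$

where $x_{ith}$ is the number of season days county $i$ spends in 3 K
temperature bin $h$ in harvest year $t$ (bins $[0,3), \dots, [36,39)$, with
everything above 39 C pooled into a 39-42 bin), $P_{it}$ is season total
precipitation in mm, and each state carries linear and quadratic time trends
in the centred year to absorb technological change. $\gamma_h$ is the
log-yield effect of one additional day in bin $h$; $1-\exp(\gamma_h)$ is the
per-day fractional yield change. Time below 0 C is deliberately excluded
from the covariates — its effect is absorbed by the intercept, and its
variation is what keeps the bin columns from summing to the constant season
length (a design that would otherwise be collinear).

### Exposure from daily weather

Within each day the temperature course is modelled as a sinusoid between that
day's minimum and maximum (no cross-midnight blending). The fraction of the
day above a threshold $z$ then has the closed form
$\tfrac12 - \arcsin\!\big((z - M)/A\big)/\pi$ with $M = (T_{max}+T_{min})/2$,
$A = (T_{max}-T_{min})/2$, saturating at 1 below $T_{min}$ and 0 above
$T_{max}$. Bin times are differences of this fraction across bin edges, so
they telescope exactly to one day; summing over the season window and
land-use-weighted averaging over a county's grid cells gives the exposure
covariates. Bin edges are half-open $[a, b)$. Fixed seasons are
March 01 - August 31 for maize and soybean and October 15 - July 15 for
wheat; a season spanning the year boundary is assigned to its harvest year.
Leap days are included when the window contains them.

### Estimation and inference

County effects are absorbed by the within transformation (demeaning by
county); the estimates are identical to explicit county-dummy least squares,
which the test suite asserts against `lm()` as an independent route. Rank
deficiency after demeaning is an error naming the offending columns, not a
silent drop.

Because weather — and hence both the covariates and the residuals — is
spatially correlated across counties, conventional standard errors are far
too small. The coefficient covariance is therefore a Conley-type spatial-HAC
sandwich: score cross-products are summed over all same-year county pairs
whose centroids lie within a distance cutoff (default 3 degrees, Euclidean in
degrees, uniform kernel), with no serial term across years. Reported
covariances carry the usual small-sample scaling $n/(n-p)$ with $p$ counting
the absorbed county effects, and confidence intervals use normal critical
values (the panels have thousands of degrees of freedom). In the packaged
simulations this correction matters: plain heteroskedasticity-robust
intervals cover the truth for only 60-78% of replicates, the spatial-HAC
intervals for 91-96%.

Two fitted response curves are compared with the conservative
interval-overlap rule: a bin diverges significantly only when the two 95%
intervals are disjoint; shared endpoints count as overlapping. Yield panels
from several models are combined per county-year by the median (mean of the
two middle values for even counts) before fitting.

### Decomposition into change factors

For reporting, the response is collapsed into multiplicative change factors
per temperature range, $F_R = \exp\big(\sum_{h \in R} \gamma_h \bar E_h\big)$,
where $\bar E_h$ is the mean per-season exposure of the panel (county-years
weighted equally) over the ranges <30 C, 30-36 C and >36 C. The yield loss
attributable to a shift of exposure within the 0-36 C range between a
historical and a future climate is
$1 - (F^{fut}_{<30} F^{fut}_{30-36}) / (F^{hist}_{<30} F^{hist}_{30-36})$,
by construction independent of the >36 C factors. The package bundles the
published factors for US maize, soybean and wheat
(`reference_change_factors()`); `change_factor_table()` reproduces their
future-loss column (49%, 40%, 22%) and totals exactly.

## The synthetic study conditions

All inputs can be generated, so every stage is testable without downloads.
The generators' defaults are fixed study conditions, not tuning knobs.

**Weather** (`gen_weather()`): per cell, daily mean temperature is an annual
sinusoid peaking in mid July plus an AR(1) anomaly plus an optional uniform
warming offset; `tmin`/`tmax` sit half a lognormal diurnal range below and
above it. Anomaly innovations are spatially correlated across cells
(exponential covariance, 2-degree range) — synoptic weather systems span
several degrees, and without this the covariates would be cross-sectionally
independent and spatial error correlation would not propagate into the
sampling variance the Conley estimator exists to capture. Precipitation is
gamma-distributed on Bernoulli wet days, independent of temperature (a known
simplification: real hot spells are dry, so the real-world confounding
between heat and drought is weaker here than in observations). The climate
defaults (annual mean 11 C, amplitude 13 C, anomaly sd 4.5 C, diurnal range
10 C) were chosen so a fixed March-August season reproduces the exposure
statistics of the US maize panels this generator emulates — about 10.8 days
per season above 30 C and about one day above 36 C — which also guarantees
every pooled bin, including 39-42 C, is genuinely occupied.

**Regions** (`gen_regions()`): counties are disjoint blocks of grid cells
with Dirichlet crop-area weights, grouped into contiguous states; each
county draws a rainfed area share (trimodal by default so all three regime
classes occur: at least 90% rainfed, at least 75% irrigated, mixed
excluded).

**Statistical yields** (`gen_yields_statistical()`): log yields computed
exactly from the regression's right-hand side under a known `true_model()`,
plus Gaussian residuals with exponential spatial covariance (range 1 degree,
sd 0.1 — about 10% county-year yield variability) sampled by Cholesky
factorisation per year. With `error_sd = 0` the fit recovers every
coefficient to numerical precision; with noise, 95% interval coverage per
bin stays within [90%, 99%] over 300 replicates at 200 counties x 31 years.

**Surrogate yields** (`gen_yields_surrogate()`): a soil-water-bucket model
embodying the water-stress mechanism. Daily ET demand is a base rate plus a
slope times the day's degree-days above 25 C integrated over the same
diurnal sinusoid the exposure computation uses (a daily-mean basis is
available via `demand_basis = "tmean"`); supply is limited by a bucket
refilled by rain (or reset to capacity daily under irrigation); log yield
falls with mean seasonal stress $1 - \text{supply}/\text{demand}$.
Defaults are agronomically standard magnitudes: 4 mm/day base demand, 60 mm
plant-available water, and a stress sensitivity of 3 (full-season stress
approaches crop failure). The 25 C reference places the onset of
demand-driven stress near the observed ~30 C yield inflection without
tuning. A small lognormal observation noise (sd 0.05) makes the irrigated
panel statistically non-degenerate, as real reported yields are. Fitting the
panel model to rainfed surrogate yields gives significantly more negative
coefficients in the hottest occupied bins than fitting to irrigated
surrogate yields — the qualitative rainfed/irrigated contrast the mechanism
predicts — and the interval-overlap counter flags those bins.

## Numerical choices and degenerate inputs

* Degenerate days (`tmin == tmax`) use the indicator `tmin > threshold`.
* Edge temperatures belong to the upper bin (CDF differencing on half-open
  bins); exact-edge ties are measure-zero under the sinusoid.
* Missing season days are an error, never gap-filled; non-positive yields are
  dropped with a logged count; counties with zero regime weight are excluded
  with a warning.
* Piecewise-linear covariates are built from the fine 1 C bins as
  exposure-weighted midpoint distances from the knot (default 30 C), reusing
  the exact exposure machinery.
* The pooled-top bin's nominal upper edge (42 C) is only a label; all time
  above 39 C is pooled.
* Year centring for trends uses the panel mean year, identically in the
  generator and the fitter.
* Verification problem sizes: unit tests run on a 25-county, 8-year panel;
  the statistical properties run on 200 counties x 31 years with 300
  Monte-Carlo replicates; quadrature oracles use 4-10 million grid points so
  their discretisation error sits well below the 1e-6 tolerance they check.

## Open design points, resolved

* The spatial kernel and distance metric of the HAC estimator are not
  uniquely standard; this package uses a uniform kernel on Euclidean degree
  distance with a 3-degree cutoff, both configurable
  (`regression_spec(spatial_cutoff = )`).
* County aggregation renormalises cell weights within the chosen regime;
  with county-level shares this equals total-area weighting, and cell-level
  shares are honoured when present.
* Precipitation enters as the raw season total (linear and quadratic);
  demeaning would only shift intercept and fixed effects.
* Exposure means for change factors weight county-years equally; Table-style
  decompositions default to the rainfed panel.

## Limitations

Passing tests show the pipeline recovers known structure from data shaped
like the emulated inputs; they cannot show that real yields follow the
model. The generators omit temperature-precipitation dependence, phenology,
CO2 physiology, management variation, and real geography; the surrogate is a
one-bucket caricature of crop water balance meant to inject a controlled
mechanism, not to simulate a crop. Change-factor decompositions carry no
uncertainty propagation.
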