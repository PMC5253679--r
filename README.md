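# cropbins

Temperature-bin exposure regression for crop yield panels.

High temperatures cut crop yields: US county data show maize and soybean
losing up to several percent of yield per day spent above ~30 °C under
rainfed conditions, while irrigated yields barely respond — the signature of
temperature-induced water stress. `cropbins` is an R implementation of the
statistical pipeline behind that kind of analysis, for researchers who want
to estimate binned temperature-yield responses from county panels, compare
observed with simulated (crop-model) responses, or validate the estimator on
synthetic data with known structure.

## The model

Daily minimum and maximum temperatures define a within-day sinusoid whose
time above any threshold has a closed form; differencing across bin edges
gives the days each growing season spends in 3 K temperature bins (`[0,3)`,
…, `[36,39)`, everything >39 °C pooled into 39–42; time below 0 °C is
absorbed by the intercept). Cell exposures are aggregated to counties with
crop-area weights, and log yield is regressed on bin exposure days:

log Y_it = α₀ + c_i + Σ_h γ_h·x_ith + δ₁P_it + δ₂P_it² + state trends + ε_it

with county fixed effects (absorbed by the within transformation),
quadratic season precipitation, and per-state quadratic time trends. γ_h is
the log-yield effect of one extra day in bin h, so `1 − exp(γ_h)` is the
per-day fractional loss (γ = −0.04 ≈ 4% per day). Standard errors are
Conley-type spatial HAC: residual correlation between counties within a
distance cutoff (default 3°) in the same year enters a sandwich covariance.
Two response curves "diverge" in a bin only when their 95% confidence
intervals are disjoint. Fitted responses collapse into per-range
multiplicative change factors `exp(Σ γ_h·Ē_h)` (<30, 30–36, >36 °C), whose
historical/future ratio gives the yield loss from exposure shifts up to
36 °C.

Everything upstream is generatable: gridded daily weather (seasonal cycle,
spatially correlated AR(1) anomalies, diurnal range, gamma rain, optional
uniform warming), county maps with area weights and rainfed/irrigated
shares, and yield panels drawn either from the regression model itself
(known coefficients, spatially correlated errors) or from a mechanistic
soil-water-bucket surrogate that produces the rainfed/irrigated contrast.

## Worked example

```r
library(cropbins)

cfg     <- climate_config(grid_rows = 6, grid_cols = 6, years = 10, seed = 42)
weather <- gen_weather(cfg)
regions <- gen_regions(region_config(n_counties = 36, n_states = 4,
                                     rainfed_share_dist = "rainfed", seed = 42),
                       unique(weather[c("cell_id", "lat", "lon")]))
season    <- growing_season("maize")             # Mar 01 - Aug 31
exposures <- aggregate_to_counties(
  season_exposure(weather, season, resolution = "pooled"), regions, "rainfed")
truth  <- true_model(regions, error_sd = 0.1, seed = 42)
yields <- gen_yields_statistical(exposures, truth, regions)

fit <- bin_panel(yields, exposures, regions)
fit
#> Temperature-bin panel regression (step form)
#> 360 observations, 36 counties, 60 parameters
#> Spatial-HAC cutoff: 3 degrees; CI level 95%
#>
#> Per-day exposure effects (log yield per day):
#>        bin  estimate      se
#>    bin_0_3  0.002370 0.00910
#>    ...
#>  bin_30_33 -0.010150 0.00869
#>  bin_33_36 -0.016980 0.01030
#>  bin_36_39 -0.024060 0.01890
#>  bin_39_42 -0.110500 0.01820
```

The hot-bin estimates are negative — each day at 33–36 °C costs this
synthetic panel about 1.7% of yield (`1 − exp(−0.017)`), and the estimates
bracket the generating coefficients within their spatial-HAC intervals.
`summary()`, `confint()`, `plot()` (response curve over the exposure
histogram), `predict()` and `simulate()` behave as for other fitted-model
classes, and `ci_overlap_divergence(fit_a, fit_b)` counts significantly
diverging bins between two fits.

Change factors and the warming-loss decomposition:

```r
change_factors(fit, exposures, crop = "maize", period = "historical")
#> Yield change factors — maize (historical)
#>   <30 C: 3.51   30-36 C: 0.90   >36 C: 0.96   total: 3.03

change_factor_table()   # bundled published factors for US maize/soy/wheat
#>      crop     period factor_below30 factor_30_36 factor_above36    total future_loss_pct
#> 1   maize historical           1.80         0.73           0.96 1.261440              49
#> 2   maize     future           1.62         0.41           0.47 0.312174              NA
#> 3 soybean historical           2.84         0.88           0.95 2.374240              40
#> ...
```

The future-loss column — 49% for maize, 40% for soybean, 22% for wheat —
is the yield loss implied purely by the shift of temperature exposure within
the 0–36 °C range between the historical and end-of-century climate.

A thin command-line pipeline wraps the same functions
(`inst/cli/cropbins.R` with subcommands `simulate`, `exposure`, `fit`,
`compare`, `decompose`); every run writes a JSON manifest with its config
and seeds.

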