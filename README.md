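# stockdist

Spatial distribution indicators — and what drives them — for fish stocks
sampled by stratified-random bottom trawl surveys.

Fisheries surveys record biomass per tow at stations scattered irregularly
over a stock's survey strata. `stockdist` computes design-aware annual
indicators of where the stock is and how spread out it is, tests those
series for time trends with autocorrelation-corrected inference, and ranks
three candidate drivers of distribution change by multimodel inference.
It is aimed at fisheries and spatial ecologists working with
stratified-random survey data (NEFSC-style or similar).

## The indicators and models

Stations are weighted by their **area of influence** `w_i`: the Voronoi
(Dirichlet) cell of each station clipped to the stock's strata, so weights
always sum to the stock area. With biomass density `z_i` (kg/tow) at
location `x_i` (km, in a per-stock Euclidean frame with origin at the
strata minimum and longitude scaled by the cosine of the midpoint
latitude):

- **Center of gravity** (bivariate mean location, km):
  `CG = Σ x_i w_i z_i / Σ w_i z_i`, reported as east–west (XCG) and
  north–south (YCG) components;
- **Inertia** (km²): `I = Σ (x_i − CG)² w_i z_i / Σ w_i z_i`, decomposed
  into maximum/minimum orthogonal axes (their square roots are axis
  standard deviations in km);
- **Biomass-weighted mean depth** (m): the CG formula with depth in place
  of location;
- **Positive area** (km²): `PA = Σ w_i [z_i > 0]`, the influence area of
  stations with strictly positive biomass.

Indicator series are regressed on year (OLS; refit with AR(1) errors by
maximum likelihood when the Durbin–Watson test flags serial correlation).
Driver importance per indicator is the **summed Akaike weight** of each
predictor — log survey biomass index, log relative F (catch / index), and
stratified mean bottom temperature — across the 8-model GLS set of all
predictor subsets, with conditional and full model-averaged coefficients.

A synthetic stratified-survey generator (`scenario_config()`,
`simulate_scenario()`) provides ground truth — drifting biomass surface,
abundance-linked occupancy, temperature and fishing-pressure series — for
end-to-end validation of every stage.

## Worked example

Simulate the reference scenario — a stock whose center of gravity drifts
north at 1 km/yr across a 15-stratum, 37,500 km² survey area — then
recover the drift:

```r
library(stockdist)

cfg <- scenario_config(seed = 7)        # 50 years, ~150 stations/yr
sc  <- simulate_scenario(cfg)
ser <- annual_series(sc$survey, sc$stock, "SPRING")
head(round(ser[, c("year","xcg","ycg","inertia","depth_cg","positive_area")], 1))
#>  year  xcg   ycg inertia depth_cg positive_area
#>  1967 73.5 101.5   966.6    131.0       18285.4
#>  1968 82.0 102.9  1228.9    132.5       19464.6
#>  1969 73.5 107.9  1445.2    136.9       21900.5
#>  1970 70.3  99.0  1082.9    125.1       19192.1
#>  1971 71.7 103.7  1089.0    131.8       20222.2
#>  1972 76.8 104.7  1133.2    131.7       18748.5

trend_pipeline(ser$year, ser$ycg)
#> trend: slope 0.9544 (se 0.0227), p = 1.5e-39, n = 50
```

The YCG series recovers the planted 1 km/yr northward drift (0.95 ± 0.02
km/yr; inertia fluctuates around its 1250 km² target). Planting a
fishing-pressure effect on the east–west center instead
(`beta_relf = c(8, 0)`, contemporaneous coupling) and running the
importance analysis:

```r
cfg2 <- scenario_config(beta_relf = c(8, 0), relf_lag = 0,
                        temp_anom_sd = 0, seed = 7)
sc2 <- simulate_scenario(cfg2)
importance_pipeline(sc2$survey, sc2$stock, "SPRING", indicators = "xcg")$xcg
#> importance_result (AIC, n = 50)
#>     predictor summed_weight rank avg_coef_conditional avg_coef_full
#> 1     biomass        0.2701    2             -0.09577      -0.02587
#> 2        relF        1.0000    1              7.92875       7.92875
#> 3 temperature        0.2699    3              -1.52489     -0.41151
```

Relative F takes essentially all the Akaike weight and its model-averaged
coefficient (7.9 km per log-unit) recovers the planted effect; the two
inert predictors sit near the 0.27 baseline weight an uninformative
predictor gets from its four models.

For file-based workflows, `run_simulate()` / `run_indicators()` /
`run_trends()` / `run_importance()` read and write canonical CSV/GeoJSON
formats, and `inst/cli/stockdist.R` wraps them as a command-line tool with
subcommands `simulate | indicators | trends | importance | all`.

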