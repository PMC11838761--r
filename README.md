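# afrimob

Seasonal human mobility across a continent-scale administrative hierarchy,
estimated from aggregated, differentially private origin–destination (OD)
flows. Much of Africa lacks longitudinal mobility records: aggregated
smartphone location data cover some countries nearly completely and others
barely at all, and the published counts arrive with Laplace noise and
suppression of small cells. This package implements the full analysis
pipeline for that setting — for epidemiologists, demographers and planners
who need monthly, province-level estimates of how mobility moves through
the seasons, including for places with no usable data.

## What it computes

The response is the **relative mobility change ratio**: for unit *a*,
month *m*, year *y*, and a flow direction (outflow FR or inflow TO),

```
R_{a,m,y} = x_{a,m,y} / x_{a,Jan,y},        log10 R as the model scale,
```

so every unit-year is anchored at January (R = 1, log R = 0). Two
spatiotemporal hierarchical Gaussian models are fitted to log R:

- **Country pathway** (per country c):
  `logR_{c,a,m} = A_{c,a} + B_{c,m} + C_{c,a,m} + X_{c,a,m} β_c + ε_{c,a,m}`
- **Regional pathway** (per region r, pooling its countries):
  `logR_{r,a,m} = Σ_{s=1..3} A^(s)_{r,a} + B_{r,m} + C_{r,a,m} + X_{r,a,m} β_r + ε_{r,a,m}`

where `A` are BYM2 spatial effects (the regional model uses three scales:
country-level over the region, province-level within countries, and
province-level across the whole regional graph), `B` is a stationary AR1
over the 24 concatenated study months, `C` a space×time interaction
(exchangeable or Kronecker-structured), and `X β` fixed covariate effects
selected by a three-stage stepwise OLS procedure (bidirectional AIC over
main effects, AIC over two-way interactions of the selected mains, backward
pruning of marginally significant terms).

Inference is **empirical Bayes on an exact sparse-precision engine**: for a
Gaussian response the latent posterior given hyperparameters is exactly
Gaussian, so the package maximizes the exact log marginal likelihood (plus
hyperpriors) over the hyperparameters and reports the exact conditional
posterior at the mode. Sum-to-zero constraints of the intrinsic CAR blocks
are eliminated by null-space reparametrization, making every solve proper
and stable. Model fit is assessed by the calibration metrics *bias* (mean
residual), *imprecision* (residual SD), *inaccuracy* (mean |residual|) and
*capture* (% of observations inside their 95% credible interval).

Because the real data source is access-restricted, the package ships a
first-class synthetic generator: a seeded planar admin hierarchy, monthly
covariates drawn on the documented ranges, OD counts driven by the model
above, the Laplace-noise + suppress-below-100 privacy mechanism, and
country-block missingness.

## Worked example

```r
library(afrimob)

geo  <- generate_geography(n_regions = 1, countries_per_region = 2,
                           provinces_per_country = 4, seed = 7)
covs <- center_and_scale(
  generate_covariates(geo, codes = c("TEMP", "GDPC"), seed = 7))

sim <- simulate_flows(geo, covs, truth = list(
  beta  = c(GDPC = 0.15),
  hyper = list(tau_eps = 400,
               spatial = list(tau = 50, phi = 0.5),
               temporal = list(tau = 25, rho = 0.6))), seed = 7)
flows <- apply_privacy(sim$flows, privacy_params(), seed = 7)

series <- compute_relative_mobility(
  directional_totals(flows, "FR"), "FR", min_january = 100)

sel <- select_terms(
  series$logR[series$observed & series$month != 1],
  covariate_matrix(covs, series[series$observed & series$month != 1,
                                c("unit", "year", "month")],
                   c("TEMP", "GDPC")))

model <- build_country_model(geo, covs, series,
  model_spec("R1.C01", "FR", sel$terms, interaction_type = "IV"))
fit <- fit_mobility_model(model)
summarize_fixed_effects(fit)[, c("term", "mean", "sd", "significant")]
#>          term         mean          sd significant
#> 1 (Intercept)  0.094457386 0.047846974        TRUE
#> 2        GDPC  0.138005548 0.012502553        TRUE
#> 3        TEMP -0.002572988 0.002540023       FALSE
calibrate_fit(fit)
#> <calibration> n=96 bias=4.89e-09 imprecision=0.0611 inaccuracy=0.0482 capture95=99.0%
```

The stepwise stage keeps both candidate covariates; the Bayesian fit then
recovers the generating GDP-per-capita effect (truth 0.15, estimate
0.138 ± 0.013, interval covering the truth) and correctly flags the null
temperature effect as non-significant. The calibration line says the model
is essentially unbiased on the log scale with 99% of observed cells inside
their 95% predictive intervals.

The numbered drivers under `analysis/` run the whole study end to end on a
two-region synthetic dataset — simulate and privatize (`01`), descriptive
month-rank and country-flow tables (`02`), country-pathway fits (`03`),
regional-pathway fits with prediction of data-missing countries (`04`), and
the simulation studies (`05`) — writing tables under `results/`. Each takes
an optional seed argument: `Rscript analysis/01_simulate.R 1`.

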