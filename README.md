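# lagattr

Attributable risk from distributed lag non-linear models.

## The problem

How many deaths (or hospitalisations, or any counted events) are
attributable to an exposure whose effect is *delayed* and *non-linear*?
Daily outdoor temperature is the canonical case: a cold day raises
mortality for weeks afterwards, a hot day kills within days and may then be
followed by a deficit as the most frail have already died ("harvesting"),
and the risk curve is U-shaped around an optimum temperature. Classical
attributable-fraction formulas ignore this temporal structure.

`lagattr` implements attributable fractions (AF) and numbers (AN) inside
the distributed lag non-linear model (DLNM) framework, for epidemiologists
and biostatisticians analysing daily time series of exposure and event
counts. It provides the whole chain: cross-basis construction,
quasi-Poisson fitting, effect-summary grids, minimum-risk centering,
backward/forward attribution with exposure-range components, Monte Carlo
empirical confidence intervals, and a synthetic-data generator with
brute-force ground truth for validation.

## The model and measures

The log event rate at day *t* cumulates contributions from the exposures of
the preceding lag window ℓ = ℓ₀,…,L through a bivariate
exposure-lag-response surface, parameterised by a **cross-basis**: the
tensor product of an exposure basis f(x) (here, a quadratic B-spline) and a
lag basis w(ℓ) (a natural cubic spline with knots equally spaced on the
log(ℓ+1) scale),

  s(x,t; η) = Σ_ℓ f·w(x_{t−ℓ}, ℓ) = **w**ₓₜᵀ **η**.

The fitted coefficients are re-expressed as a grid of contributions
β_{x,ℓ}, each the log relative rate of exposure *x* at lag ℓ versus a
reference x₀ (the minimum-risk exposure). Attribution then takes two
complementary perspectives:

- **backward** — the cases of day *t* attributed to the exposures
  experienced over the past window:
  b-AF_t = 1 − exp(−Σ_ℓ β_{x_{t−ℓ},ℓ}), b-AN_t = b-AF_t · n_t;
- **forward** — the future cases attributed to today's exposure:
  f-AF_t = 1 − exp(−Σ_ℓ β_{x_t,ℓ}), with f-AN_t scaling the mean count of
  the coming window.

Components for exposure ranges (cold/heat, mild/extreme) select the
relevant contributions inside the exponent; forward components are exactly
additive across disjoint ranges, backward ones sub-additive. Totals sum
the daily numbers; uncertainty comes from recomputing the totals under
multivariate-normal draws of **η** and taking the 2.5th/97.5th percentiles
(empirical confidence intervals, eCI). Daily backward numbers may
legitimately be negative after a run of harm-then-harvesting exposures;
they are never truncated.

## Worked example

Five years of synthetic daily data from a known U-shaped exposure-response
(optimum at 20) with exponentially decaying lag weights over lags 0–25:

```r
library(lagattr)
surface <- u_shaped_surface()                      # g(x,l) = 2e-4 (x-20)^2 exp(-l/5)
series  <- simulate_series(surface, simulation_config(n_days = 1826, seed = 42))
res <- run_pipeline(run_config(series = series, seed = 42, n_sim = 1000,
                               df_per_year = 7, weekday_indicators = FALSE,
                               components = "cold_heat"))
res$x0                                             # estimated minimum-risk exposure
#> [1] 21.0273
res$summaries[["backward.overall"]]
#> <attribution_summary> backward, range: overall
#>   AN total: 21340 (95% eCI 11380 to 30490)
#>   AF total: 0.07226 (95% eCI 0.03852 to 0.1032)
#>   over 1801 days, 295369 cases; 1000 MC draws, seed 42
res$summaries[["backward.cold"]]
#> <attribution_summary> backward, range: cold
#>   AN total: 19950 (95% eCI 9797 to 29470)
#>   AF total: 0.06755 (95% eCI 0.03317 to 0.09978)
#>   over 1801 days, 295369 cases; 1000 MC draws, seed 42
true_total_attribution(surface, series)[["af_tot"]]  # brute-force truth
#> [1] 0.08554795
```

Reading: about 7.2% of the 295,369 events on days with complete lag
history are attributable to the exposure departing from its optimum
(95% eCI 3.9–10.3%), almost all of it from the cold side — and the
interval covers the brute-force true fraction of 8.6% computed directly
from the generating surface. The forward totals (`forward.*`) are slightly
smaller, reflecting the count-averaging approximation of that perspective.

With real data, replace the simulated series by
`read_series("city.csv")` (columns `date`, `exposure`, `count`) or run the
thin CLI in `inst/cli/lagattr`.

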