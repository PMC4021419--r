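---
title: "Attributable risk for delayed exposure-response associations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable risk for delayed exposure-response associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagattr)
```

## The model

`lagattr` works with daily time series of an exposure $x_t$ and an event
count $n_t$. The log event rate is modelled as

$$\log \mu_t \;=\; \text{confounders}_t \;+\;
  \sum_{\ell=\ell_0}^{L} f\!\cdot\! w(x_{t-\ell}, \ell),$$

where $f\!\cdot\! w(x,\ell)$ is a bivariate *exposure-lag-response* surface:
the contribution (log relative rate) of exposure intensity $x$ experienced
$\ell$ days ago, relative to a reference exposure $x_0$. The surface is
parameterised through a **cross-basis** — the tensor product of a spline
basis over the exposure axis and a spline basis over the lag axis — so a
single coefficient vector $\eta$ fitted by ordinary GLM machinery encodes
the whole surface. Counts are assumed conditionally Poisson with
overdispersion (variance $\phi\mu_t$): the model is fitted by quasi-Poisson
regression, with $\phi$ estimated as Pearson $\chi^2$ over residual degrees
of freedom and the coefficient covariance scaled by it.

Assumptions worth keeping in view: the series is equally spaced (daily)
with no structural breaks; confounding by season, long-term trend and
day-of-week is adequately captured by a smooth time spline plus indicator
variables; the exposure effect is stationary over the study period; and the
lagged contributions combine additively on the log scale.

### Attributable fractions and numbers

From the fitted surface the package derives $\beta_{x,\ell}$, the
contribution grid relative to $x_0$, and two families of attributable
measures:

* **Backward**: $\text{b-AF}_t = 1 - \exp(-\sum_\ell
  \beta_{x_{t-\ell},\ell})$ attributes the cases of day $t$ to the exposure
  history of its lag window, versus the counterfactual of that window held
  at $x_0$; $\text{b-AN}_t = \text{b-AF}_t\, n_t$.
* **Forward**: $\text{f-AF}_t = 1 - \exp(-\sum_\ell \beta_{x_t,\ell})$
  attributes future cases to the single exposure of day $t$;
  $\text{f-AN}_t$ multiplies it by the *mean* count over the coming window,
  an approximation that makes forward totals mildly conservative.

Range components restrict which exposures contribute: backward selection
happens inside the exponent (hence components are sub-additive), forward
selection is an indicator on $x_t$ (components over disjoint ranges are
exactly additive). Totals sum daily numbers over days with defined values,
and the total fraction divides by the cases of those same days.

Negative daily backward numbers are legitimate output: when the lag
profile of a harmful exposure turns protective at long lags (harvesting —
depletion of the susceptible pool), a day following a stress period can
have an observed risk *below* its counterfactual. The package never
truncates these at zero; totals over the whole series account for the
discount automatically.

### Uncertainty

Analytic intervals for these nonlinear functionals are intractable, so the
package recomputes every total under draws
$\eta^{(j)} \sim \text{MVN}(\hat\eta, V(\hat\eta))$ and reports the
2.5th/97.5th percentiles (the 95% *empirical confidence interval*). The
default is 5000 draws; 1000 give visually indistinguishable intervals in
the package's validation studies and are used there for speed. Because the
cumulated exponent is linear in $\eta$, all draws are evaluated through a
single matrix product per summary, which keeps even 5000 draws on a
decade-long series below a second.

Sampling uses an eigendecomposition of the (symmetrized) covariance rather
than a plain Cholesky factor: rank-deficient covariances — including the
exactly-zero covariance used to represent a fit treated as known — are then
handled exactly, producing degenerate intervals equal to the point
estimate. A covariance with asymmetry or negative eigenvalues beyond
1e-8 (relative) is rejected rather than repaired.

## Tunable parameters and their defaults

| Parameter | Default | Why |
|---|---|---|
| lag window | 0–25 days | long enough for delayed cold effects and harvesting to play out in daily environmental series |
| exposure basis | quadratic B-spline, 2 internal knots | the smallest basis that captures a U-shape with asymmetric arms |
| exposure knot placement | equally spaced over the observed range | literal value-scale spacing; percentile placement can be emulated by passing explicit knots |
| lag basis | natural cubic spline, 3 internal knots, intercept | natural splines keep the lag tails linear, avoiding wild extrapolation at long lags |
| lag knot placement | equally spaced in $\log(\ell+1)$ | concentrates flexibility at short lags where lag-response curves change fastest; the $+1$ shift keeps lag 0 in the domain |
| seasonal control | natural spline, 10 df/year + day-of-week | the conventional degree of smoothness for daily mortality series |
| centering | minimum-risk exposure (grid search, step 0.1) | the least-harmful observed exposure is the natural counterfactual when "no exposure" is undefined (e.g. temperature) |
| extreme cut-offs | 1st / 99th percentiles | the conventional split of extreme from mild temperatures |
| Monte Carlo draws | 5000 | conventional; the percentile estimates are stable well below this |

Centering is implemented as subtraction of the basis row at $x_0$, which
is exactly the reparameterisation $\beta_x^* = \beta_x - \beta_{x_0}$: the
fit itself is invariant (the shift is absorbed by the model intercept), so
re-centering after the minimum-risk search requires no refit.

## Numerical and boundary choices

* **Incomplete lag histories.** The first $L$ days have no complete
  exposure history; their cross-basis rows, daily backward measures, and
  contribution to backward totals (numerator *and* denominator) are
  dropped. No imputation or partial summation is attempted.
* **Series tail, forward perspective.** The last days lack a full forward
  count window. By default the available counts are averaged with a
  correspondingly reduced divisor (`tail = "truncate"`); `tail = "missing"`
  drops them instead. The difference is confined to at most $L$ days.
* **Missing exposures** propagate: any lag window touching an `NA`
  exposure yields a missing cross-basis row / daily measure, and
  complete-case fitting and totalling apply throughout.
* **Range endpoints.** Cold/heat components split at $x_0$ with open
  endpoints; since $\beta_{x_0,\ell} = 0$ exactly, endpoint membership at
  the split is numerically immaterial. Extreme components are closed at
  the percentile cut-off.
* **Minimum-risk search** scans the full observed exposure range at step
  0.1 (whole-degree optima are typical for temperature, so this is well
  below the reporting resolution). Ties are broken toward the smallest
  value with a warning. When the generating curve is shallow near its
  optimum, the located minimum is weakly identified — its sampling spread
  across replicates is several exposure units — but this has little effect
  on totals, since contributions near the optimum are near zero.
* **Out-of-boundary exposures** in prediction warn and extrapolate by the
  basis rules (linear beyond the boundary for natural splines), or error
  when `extrapolate = FALSE`.

## What the synthetic-data generator emulates

`simulate_series()` produces an exposure resembling daily temperature — an
annual sinusoid (mean 15, amplitude 8, peaking mid-July) plus AR(1) noise
(lag-1 correlation 0.8, innovation sd 2) — and counts resembling daily
all-cause mortality of a large city: baseline about 150 events/day with a
winter-peaking seasonal component of amplitude 0.1 on the log scale, and
negative-binomial noise with variance 1.2× the mean. The default true
surface, `u_shaped_surface()`, is a quadratic in $(x-20)$ times
exponentially decaying lag weights ($e^{-\ell/5}$, lags 0–25), scaled so
the cumulative relative rate reaches about 1.3 at 15 units from the
optimum — the order of magnitude seen in temperature-mortality studies.

The generator deliberately omits several features of real data: day-of-week
effects, influenza epidemics and heat-wave clusters, long-term mortality
trends, measurement error in the exposure, and any exposure-modifier
interaction. Passing recovery tests on these data therefore demonstrates
that the estimation and attribution chain is *internally correct and
calibrated under the stated model*, not that the model is adequate for any
particular real series.

Ground truth for validation comes from `true_total_attribution()`, which
applies the backward formulas with the generating surface in place of
estimates — a plain day-by-day loop sharing no code with the estimation
path.

## Validation design

The test suite checks, besides unit-level contracts: exact algebraic
identities (centering, additivity, sub-additivity, constant-series
equality of the two perspectives); agreement of every vectorised
computation with naive brute-force loops to 1e-10; and a parameter-recovery
study — 200 series of 3000 days from the default surface, fitted with the
default bases and 7 df/year seasonal control, requiring the 95% eCI
(1000 draws) to cover the true total backward fraction in 90–99% of
replicates and the mean estimate to sit within 10% of the mean truth.
These sizes keep the full suite around two minutes on one core while
leaving the binomial tolerance of the coverage check meaningful.

## Known limitations

* Only time-series (daily count) designs; no cohort/case-crossover
  exposure-history matrices.
* No penalised or automatically selected bases; knots are chosen a priori.
* No pointwise confidence bands for the curves themselves — only the
  attribution totals carry intervals.
* Backward components over overlapping stimuli are reported without
  overlap corrections.
* The forward attributable number inherits the count-averaging bias
  discussed above; on the package's synthetic conditions it is visible as
  a slightly smaller total than the backward one.
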