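---
title: "Modelling the climate sensitivity of riverine nitrogen loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the climate sensitivity of riverine nitrogen loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nloadgam)
```

## The scientific problem

Riverine nitrogen loading drives inland and coastal eutrophication.
Precipitation and temperature pull loads in opposite directions: wetter
conditions flush more nitrogen off the landscape, while warmer conditions
remove more nitrogen before it reaches the river (denitrification and
related processes) and reduce discharge. Quantifying both responses from
long monitoring records, and propagating them through bias-corrected
climate-model ensembles, tells us whether future warming offsets or
compounds future precipitation change. `nloadgam` implements that chain
as a tested R package.

## The load model

For catchment-years with annual load `Q_TN` (kg N yr⁻¹) we fit

$$\ln Q_{TN} = \beta_0 + f_P(P_{annual}) + \beta_E\,P_{MAM,p>0.95} +
f_T(T_{annual}) + \beta_S \ln N_{surplus} + \beta_L \ln N_{surplus,-1\&-2}
+ \text{land-use terms} + \varepsilon,\qquad \varepsilon \sim N(0,\sigma^2).$$

Gaussian errors on the log scale mean `Q_TN` is conditionally lognormal,
so the exponential back-transform of the linear predictor is the
conditional **median** load — all predictions and projected changes in
the package are median-based, which keeps them invariant to the residual
variance.

**Assumptions.** Additivity on the log scale (no precipitation ×
temperature interaction term; the apparent cross-dependence of *absolute*
sensitivities arises from the exponential back-transform alone);
homoscedastic residuals with no temporal or spatial autocorrelation;
land-use treated as time-invariant; covariates measured without error.
Whether a tensor interaction belongs in the model is genuinely open; we
default to the additive form because it is identifiable with far fewer
degrees of freedom and reproduces the qualitative tradeoff structure, and
the term-specification interface (`term_smooth()`, `term_linear()`)
accepts any covariate set, so an interaction surface could be added as a
derived covariate if a user needs one.

### Spline machinery and numerical choices

* **Basis**: cubic B-splines, default `basis_size` 10 per smooth, interior
  knots at covariate quantiles (robust to the skewness of precipitation).
* **Identifiability**: each smooth is constrained to sum to zero over the
  training data; the constraint is absorbed by a QR reparametrization, so
  a `basis_size`-10 smooth contributes 9 columns.
* **Penalty**: second-order *divided* differences of the basis
  coefficients with respect to the Greville abscissae. With uniform knots
  this is the familiar P-spline penalty; with quantile knots the divided
  differences keep the null space exactly `{1, x}`, so `lambda -> Inf`
  collapses a smooth to a straight line rather than to a knot-dependent
  curve.
* **Smoothness selection**: generalized cross-validation, minimized over
  log-smoothing-parameters (golden-section for one smooth, Nelder–Mead
  with several starts for more), with the search window centred on the
  ratio of design to penalty magnitudes and clamped to avoid numerical
  overflow. GCV was chosen over REML because it is the framework's
  long-standing default and fully reproducible here; the fitting interface
  also accepts fixed `lambda` for oracle comparisons.
* **Complexity and scoring**: effective degrees of freedom are the trace
  of the influence matrix; `BIC = -2 logLik + ln(n) (edf + 1)`, the `+1`
  counting the Gaussian scale parameter.
* **Extrapolation**: beyond the boundary knots the basis is extended
  linearly (continuous value and first derivative). Predictions outside
  the training range are flagged, not forbidden — future warming exceeds
  the historical maximum in late-century scenarios, and a flat clamp
  would artificially damp the temperature effect there.
* **Degenerate inputs**: smooths on covariates with too few distinct
  values degrade to linear terms with a warning; non-positive loads are a
  hard error (the log link is undefined); a singular penalized system
  reports the offending dimensions.

### Model selection

Candidate covariates are grouped into categories (annual precipitation
metrics, extreme precipitation metrics, temperature metrics, surplus
terms, land-use terms, tile drainage), each with a maximum allowed count;
`enumerate_candidates()` forms every admissible combination (the count is
the product of per-category subset counts) and `select_model()` fits each
one and ranks by BIC. Two models are treated as distinguishable only when
ΔBIC > 2; near-ties are reported alongside the winner rather than hidden.
Two policy choices were open and are resolved as follows: every category
may contribute zero covariates *except* that a candidate model must
contain at least one nitrogen-surplus term (`min_allowed = 1`), because a
load model without a nitrogen source is physically meaningless; and
candidate fits that fail (e.g., exactly collinear duplicates) are logged
and excluded instead of aborting the search.

## Sensitivities

Following the "% change per unit" convention, the relative sensitivity at
a point is the central finite difference of `100 · ln(median prediction)`
with step `h = 1` (1 mm or 1 °C), so a log-linear term with coefficient
β reports exactly `100 β`, directly interpretable as percent per unit.
The absolute sensitivity is the same finite difference of the median
itself (load per unit). `average_sensitivity()` averages the relative
slopes over the training records with uniform weights — each record
conditions the other covariates at its own values — and reports the
min–max range across baselines. Record-level averaging was chosen over
grid- or catchment-level averaging because the training distribution is
the natural weight for a "across the observed range" summary.

## The synthetic generator

The generator produces the study conditions end to end: 258 catchments
observed 1981–2017 (9,546 catchment-year records), with

* land-use percentages from a Dirichlet allocation (developed,
  cultivated, forest+shrub, wetland, other) and tile drainage positively
  tied to the cultivated fraction;
* daily precipitation from a two-state wet/dry Markov chain (stationary
  wet-day probability per catchment, persistence 0.3) with
  gamma-distributed wet-day amounts (shape 0.6–1.1, heavy-tailed) shifted
  just above the 0.1 mm wet-day threshold;
* monthly temperature as an annual-cycle sinusoid plus shared interannual
  anomalies (SD 0.6 °C) and monthly noise (SD 1.5 °C);
* nitrogen-surplus components (deposition, fertilizer, fixation, manure,
  human waste, crop uptake) as stationary AR(1) processes (coefficient
  0.7, CV 0.15) around land-use-dependent means, assembled by the budget
  identity and floored at 1 kg N ha⁻¹ yr⁻¹ so the log is defined;
* loads drawn lognormally (default residual SD 0.5) around an additive
  log-link response.

**Calibration.** The response constants are set to the reported average
sensitivities: the temperature slope is −0.064 (−6.4 % per °C), the
extreme-precipitation slope 0.0012 (0.12 % per mm), and the saturating
precipitation effect is a scaled asymptotic exponential
`A (1 − exp(−P/800 mm))` whose amplitude is calibrated on the generated
covariate sample so its record-averaged finite-difference sensitivity is
exactly 0.17 % per mm. The 800 mm e-folding scale makes the response
near-linear at low precipitation and clearly saturated above 1,500 mm.
Surplus elasticities (0.8 current, 0.3 lagged) and small positive
land-use slopes complete the response; the intercept (6.0) puts the
median yield near 15 % of the median surplus, which in turn places the
implied denitrification Q10 close to 1.1. These constants were chosen
once, from the published summary values and field-plausible magnitudes,
and are not adjusted per analysis.

**Lagged surplus.** The combination rule for "surplus of the previous two
years" is not fully determined (mean and sum are equally defensible); we
use `ln` of the *mean* of the two previous years, which keeps the
covariate on the same scale as the current-year term.

**What the generator does not emulate**: spatial correlation between
catchments, hydrologic routing and discharge, precipitation seasonality,
measurement error in loads (real loads are themselves regression
estimates), incomplete records (real catchments average ~17 annual
observations, not a complete panel), and any area-dependence of loads —
loads are generated at a common ~1,000 km² scale because the
nine-covariate model has no area term, and catchment area enters only the
yield conversion in the Q10 module. Passing tests therefore demonstrate
that the chain recovers known truth under its own assumptions, not that
those assumptions hold for any particular river network.

**Ensembles.** Members re-run the climate generator with a multiplicative
precipitation bias (lognormal, SD(log) 0.2) and an additive temperature
bias (normal, SD 1.5 °C) — magnitudes typical of raw GCM output — plus
scenario trends ramping linearly from the baseline midpoint to the
late-century midpoint (warming 1.8/3.0/5.0 °C and wet-day-mean increases
4/7/12 % for the sustainability, middle-of-the-road, and
fossil-fuel-development scenarios). A bias-free twin of each member with
identical weather noise is retained as ground truth for bias-correction
tests.

## Bias correction (SDM)

Biases are fitted on the 1981–2010 reference period: gamma fits to wet-day
amounts plus wet-day frequencies for precipitation (whole-series), normal
fits to linearly detrended monthly values per calendar month for
temperature. Correction is quantile-wise and *scaled*: each raw value is
multiplied by (precipitation) or shifted by (temperature) the
observed-vs-modelled reference bias at its own quantile, where the
quantile is taken under the distribution of the segment being corrected.
This preserves the model-projected relative change of precipitation
quantiles and absolute change of temperature quantiles — the property
that distinguishes SDM from plain quantile mapping. Numerical choices:
CDF values are clamped to `[1/(2n), 1 − 1/(2n)]` so tails never map to
infinite corrections; wet-day frequency is adjusted toward the observed
frequency scaled by the model-projected frequency change (days are
removed smallest-first; days are never invented); corrected
precipitation is kept non-negative and rank-preserving. Precipitation is
corrected whole-series with monthly resolution only for temperature,
matching the monthly resolution of the temperature data; fewer than 20
years of reference overlap is refused as unreliable.

## Projection, decomposition, ensembles, regions

`derive_covariates()` computes `P_annual` (calendar-year sum), `T_annual`
(mean of 12 monthly values) and the extreme metric as the **full amount**
of March–May days exceeding the reference-period 95th wet-day percentile
(not the excess above the threshold), with the empirical quantile fixed
to linear interpolation of order statistics (type 7) because the
threshold value depends on the convention. Projected change is
`100 · (future 30-y mean of yearly median predictions − baseline mean) /
baseline mean`, with nitrogen surplus and land use pinned at current
values so the number isolates the climate effect. The decomposition runs
the same projection with only precipitation (total + extreme) or only
temperature taking future values; in log-additive single-year form the
combined change factors exactly into the product of the two.

Windows are 30 years: baseline 1988–2017, mid-century 2030–2059,
late-century 2070–2099 (where two mid-century definitions circulate, the
2030–2059 one is the default and the window is an argument). Ensemble
summaries use the member median; a watershed is "robust" when at least
80 % of members share the sign of the median combined change, and
tradeoff classes are: *offset* (precipitation alone would raise loading
but the combined median falls), *compound-decrease* (both fall),
*net-increase* (combined median rises). Sign agreement is counted against
the ensemble median's sign (rather than a pairwise majority), which is
well-defined for even member counts. Regional changes are load-weighted
by construction: the change in summed loading with baseline predicted
loads as weights.

## Q10

Treating all nitrogen losses (surplus − loading) as denitrification, the
loss curve `L(t)` is evaluated on `t ∈ [−2, 24] °C` (0.5 °C grid) with
other covariates at training medians, loading converted to a yield
(kg N ha⁻¹ yr⁻¹) with the median catchment area — surplus is areal, so
the subtraction needs commensurate units; whether the original
computation used yields or total mass is unstated, and areal yield is the
dimensionally consistent reading. Then `Q10(t) = L(t+5)/L(t−5)` for
`t ∈ [3, 19]`, and the summary value is the mean of `Q10(t)` weighted by
a histogram density (1 °C bins) of the training annual temperatures,
integrated by the trapezoid rule; the uncertainty range is
`(Q10(19 °C), Q10(3 °C))`. Non-positive losses anywhere on the grid are
refused rather than silently truncated.

## Monte-Carlo uncertainty

Residual model uncertainty is propagated by sampling the conditional
lognormal distribution: `load = median · exp(σ̂ z)`, with the fitted
model's single global σ̂² (the Gaussian model has one scale parameter;
nothing supports per-watershed variances), draws independent across
watersheds, members, years and repetitions (the model has no residual
autocorrelation structure; sampling is per-year, then period-averaged),
1,000 repetitions by default. Because deviations from the median largely
cancel in regional sums, regional medians with sampling on and off agree
to Monte-Carlo error — one of the package's invariant tests.

## Problem sizes and precision

The test suite exercises reduced configurations (20–40 catchments,
15–20 years, 8–16 ensemble members, 100 selection replicates at
n = 2,000) chosen to probe every contract at comfortable precision; the
acceptance script runs the full default scale (258 catchments × 37 years).
Of the three calibrated sensitivities, the springtime-extreme term is by
far the smallest signal (0.0012 per mm on the log scale, against a
skewed, zero-inflated covariate), so its recovery is the least precise —
at the default noise level its sampling variability is of the same order
as a ±10 % recovery band, and individual realizations can fall just
outside it while temperature and annual precipitation recover within a
few percent.

## Known limitations

Single global residual variance (no heteroscedasticity across catchment
sizes); no parameter (coefficient) uncertainty propagation — only
residual-distribution uncertainty; no spatial downscaling or joint
precipitation–temperature bias correction; the generator's simplifications
listed above. The package deliberately excludes load estimation from raw
concentration data, catchment delineation, and retrieval of the external
climate and land-cover products.
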