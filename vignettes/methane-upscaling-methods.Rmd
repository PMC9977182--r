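---
title: "Methods: chamber-to-landscape methane upscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber-to-landscape methane upscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prairieCH4 models methane (CH4) emissions from depressional prairie wetlands
across three scales: the chamber (plot) scale, a 30-m raster landscape, and
climate-scenario ensembles of future emissions. This vignette describes the
models, the synthetic data they are tested against, the tunable parameters,
and the numerical choices that a user extending the package should know about.

## Chamber fluxes, WFPS, and Q10

`compute_flux()` converts a static-chamber headspace concentration series to
an areal flux. The concentration change is assumed linear over the deployment
(the field protocol being emulated collects an ambient sample at closure and a
headspace sample at 30 minutes); the slope is estimated by ordinary least
squares, which reduces to the two-point difference quotient for two samples
but extends unchanged to longer series. The mass conversion uses the ideal gas
law: one ppm of a gas with molar mass $M$ (g mol$^{-1}$) at pressure $P$ and
temperature $T$ corresponds to $M P / (R T) \times 10^{-6}$ g m$^{-3}$, and
the areal flux is the volumetric rate times the effective chamber height
(volume over basal area):

$$F \;=\; \underbrace{\frac{dC}{dt}}_{\text{ppm h}^{-1}}
  \times \frac{M P}{R T} \times 10^{-6}
  \times \frac{V}{A} \quad \text{(g m}^{-2}\text{ h}^{-1}\text{)}.$$

Deployment-level air pressure is rarely recorded; the default is the standard
atmosphere (101,325 Pa) and both temperature and pressure are explicit
arguments. `compute_wfps()` is the ratio of volumetric water content to soil
porosity, as a percent, clamped at 100% with a warning (field probes can
report VWC slightly above the nominal porosity).

`compute_q10()` estimates the temperature sensitivity of flux from field
data: records are binned into 1 °C increments, fluxes are averaged per bin,
and $\log(\text{mean flux})$ is regressed on bin midpoint; $Q_{10} =
\exp(10\,\hat\beta)$. Regression across bins is more robust to bin noise than
an endpoint ratio and coincides with it when only two bins are available. For
rates generated exactly as $R_0 Q^{T/10}$ the estimator recovers $Q$ to float
precision, which the tests exploit.

## The plot-scale additive model

Positive chamber fluxes are modelled as log-normal: `fit_plot_model()` fits a
Gaussian penalized additive model to $\log(\text{flux})$ with thin-plate
smooths for WFPS, soil temperature, NDVI, wetland size, hydroperiod and the
first-order (previous biweekly step) lags of WFPS, temperature and NDVI;
fixed effects for surrounding land cover (grassland/cropland) and growing
season interval (early/late); and random intercepts for wetland and chamber
within wetland, implemented as ridge-penalized spline terms. Non-positive
fluxes (chambers can measure small uptake) are dropped before fitting, with
the count reported. Fitting uses mgcv's fast REML with covariate
discretization; the double-penalty selection criterion (`selection_penalty =
TRUE`) lets the optimizer shrink entire smooth terms out of the model, while
categorical terms are never subject to removal.

Parameters that matter:

* `basis_dim` (default 10 per smooth) bounds each term's flexibility. The
  generating curves used in testing need at most ~6 effective degrees of
  freedom, so 10 leaves headroom; interpolation tests of noise-free data use
  12 because the residual there is pure basis truncation error.
* "Removed by selection" is operationalized as effective degrees of freedom
  below 0.1 for the `terms_removed` set. In selection tests we additionally
  treat a term as effectively removed when its EDF is below 1 *and* its
  partial-effect amplitude is under 10% of the strongest signal term: the
  double penalty reliably crushes a pure-noise term's contribution to a few
  percent of the signal but does not always drive its EDF to literal zero.
* Predictions are strictly positive (exponential of the fitted log-scale
  mean, i.e. the conditional median of the log-normal). No variance
  back-correction is applied; the landscape model is trained and
  back-transformed the same way, so ratios (fold changes) are unaffected.
* Covariates beyond the training range are clamped to the range boundary at
  prediction time — smooths are held at their boundary values — and the count
  of clamped values is reported. Warmer-future prediction needs extrapolation;
  clamping is conservative and flagged rather than refused.
* With a degenerate constant response, REML smoothness selection is
  numerically unstable; the fit falls back to fixed, very large penalties,
  which yields the correct flat fit with zero deviance explained.

## The synthetic generating truth

The real campaign the package emulates (roughly 19,000 wetland-zone
growing-season measurements from ~143 wetlands sampled biweekly) is not
shipped; instead `generate_chamber_dataset()` draws from a documented
closed-form truth (`true_response()`) so that every fitted quantity has a
known target:

* logistic WFPS term with inflection at 80% — flux collapses as surface soil
  aerates below that point;
* exponential temperature term $\log(Q_{10})/10 \cdot (T - 15)$ with
  `q10 = 3` by default, so a +10 °C contrast multiplies expected flux by
  exactly $Q_{10}$;
* smooth NDVI step at 0 — the open-water to emergent-vegetation transition;
* log-quadratic wetland-size term peaking at 3 ha — medium wetlands combine
  long hydroperiods with emergent vegetation, while the smallest dry out and
  the largest are more lake-like per unit area;
* saturating hydroperiod term; a positive grassland offset; a negative
  late-season offset; and lag terms entering as down-weighted (0.25) copies
  of the parent curves.

All terms are centered at a reference record (WFPS 80%, 15 °C, NDVI 0, 3 ha,
180 d, cropland, early season), so the reference evaluates to exactly
`exp(intercept)`. Covariate trajectories follow a seasonal temperature
sinusoid, wetland-specific soil-moisture drawdown, and an NDVI green-up;
wetland size is log-normal with hydroperiod increasing in size. Noise has
three log-scale components: wetland intercepts (SD 0.15), chamber intercepts
(SD 0.12), and residual (SD 1.15). The residual SD was calibrated once so
that the fixed signal explains ~60% of log-flux variance under the default
covariate process — the regime the recovery bands for the additive and
tree-ensemble models are designed around. First-step lags equal current
values (no prior step exists); the early/late season boundary is the midpoint
of the frost-free window.

What the generator does *not* emulate: ebullition and other heavy-tailed flux
events beyond log-normal noise, within-season autocorrelated weather,
salinity gradients, measured-covariate error, and the real campaign's
unbalanced sampling. Passing recovery tests therefore demonstrate that the
estimators recover the *assumed* structure, not that the structure is what
real chambers produce.

## The synthetic wetlandscape

`generate_wetlandscape()` places disjoint, roughly elliptical depressions
(largest first, with a one-pixel moat so components never touch even at
8-connectivity; placement retries are bounded and failure is an error) on a
30-m grid. Areas are drawn log-normal (median 0.54 ha, `sdlog = 1.4`)
truncated at 22.5 ha: the majority of wetlands fall under 1 ha, roughly 2%
exceed 10 ha and carry a large share of extent, and the rare lake-sized
waterbodies are excluded from the default scene (the truncation also keeps
total-extent summaries stable across seeds, which the distributional tests
rely on). Each wetland gets a monotone seasonal drawdown of wetted fraction
(convex decline from a full step-1 extent toward a size-dependent minimum),
and pixels are wetted in order of depth, so per-pixel wet masks are nested
across steps. A `wetness` multiplier rescales every trajectory: regenerating
the same seed at lower wetness yields a drier bookend of the *same* landscape
whose wet extents are subsets of the wetter one. Temperature is a seasonal
sinusoid plus a latitudinal gradient and a smooth random field; NDVI is
negative over the open-water core, elevated in the emergent ring, moderate
upland; land cover is a blocky two-class mosaic.

The biweekly step count is tied to the frost-free window:
`ceiling(length / 14)`, e.g. 19 steps for the default 266-day season and 24
for a 323-day future season.

## Landscape predictors and the tree ensemble

`delineate_wetlands()` labels connected components of the union (wet at any
step) water mask — the union defines the wetland object and its size, while
per-step masks define inundated extent. 8-connectivity is the default
(depressions are roughly convex; diagonal splits are raster artifacts), with
4-connectivity available. `derive_predictor_stack()` maps rasters onto the
chamber covariate schema: WFPS surrogate 100% for wet pixels and 50% for
currently-dry wetland pixels (no observational anchor exists for the dry
value; it is a single configurable number), hydroperiod as wet-step count
times step length, size from component area, and lags referencing the
previous step (step 1 self-referential, matching the chamber convention).

`fit_landscape_model()` is a random-forest regression of log flux: 500 trees,
each grown on a ~2/3 subsample drawn without replacement with `ceiling(p/3)`
predictors tried per split, evaluated on its out-of-bag third. Out-of-bag
variance explained is reported on the log-flux training scale. Training pairs
chamber fluxes with the chamber covariates directly — on synthetic data the
chamber and pixel schemas coincide by construction, which emulates co-locating
chambers on the landscape. Prediction streams over row chunks and is
invariant to the tiling.

## Annual integration and summaries

`integrate_annual()` charges each within-window step with
$\text{rate} \times \text{pixel area} \times 336\ \text{h}$, and charges
winter at boundary rates: the hours before the window at the first-step rate
and the hours after at the last-step rate (nongrowing-season chamber fluxes
over frozen soils are near zero but not structurally different, so boundary
rates are the least-assumption extension). The year is fixed at 365 days; a
constant rate $r$ therefore integrates to exactly $r \times \text{area}
\times 8760$ h, a closed form the tests verify. Regional summaries report
totals in Gg, inundated area as the maximum per-step wet extent (per-step
mean also emitted), and a pixel-hour-weighted mean flux rate over inundated
pixel-steps — the weighting is stated explicitly because summary tables of
this kind often leave it ambiguous. Size-class tables bin wetlands by
maximum area into left-closed 1-ha classes up to 10 ha plus an open top
class; shares are exact decompositions of the total.

## Scenarios

`apply_scenario()` implements a delta-method emulation of downscaled climate
projections: each ensemble member carries twelve monthly temperature deltas
(applied additively to the month containing each step's midpoint) and a
future frost-free-window length. Window extension days are placed after the
historical window while the calendar allows, then before it; new shoulder
steps replicate the boundary step's water mask and NDVI — consistent with the
winter boundary-rate assumption — and its pre-delta temperature. Water and
NDVI otherwise stay those of the historical extent bookend; future hydrology
is bracketed by running every pathway against both a dry and a wet bookend
rather than modelled. An optional NDVI response to warming is deliberately
out of scope. `run_ensemble()` reports per-member summaries, the ensemble
mean, the CV ($100 \cdot \mathrm{sd}/\mathrm{mean}$) and range across
members, and aborts identifying the member on any failure. `fold_change()`
divides mean future totals by the mean of the historical dry and wet totals,
reporting per-bookend ratios alongside to avoid masking extent effects.

`make_ensemble_members()` draws a 13-member ensemble by default: member mean
warming around the pathway mean (SD 0.5 °C), a seasonal cycle with stronger
cold-month warming, and window lengths clamped to at least the historical
season.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; `run_pipeline()` derives a
sub-seed per stage from its global seed, and a rerun with the same
configuration reproduces every numeric output bit for bit (fits are
single-threaded). The test suite exercises: chamber-model recovery on 20
replicate datasets of ~10,400 rows (40 wetlands, 4 chambers, 5 years);
landscape truth-recovery on grids from 96 x 96 to 512 x 512 with up to 1,800
wetlands; aggregation exactness against a brute-force loop on a 256 x 256
scene; and the end-to-end pipeline on a 128 x 128, 200-wetland demo
configuration. These sizes are the package's chosen testing scale — large
enough that the recovery bands are statistically meaningful, small enough to
keep the suite routine to run.

## Known limitations

* The plot model predicts the log-scale mean (log-normal median); absolute
  totals therefore carry a multiplicative bias of up to
  $\exp(\sigma^2/2)$ relative to the arithmetic mean if interpreted as such.
  Both scales are internally consistent, and ratios are unaffected.
* The WFPS surrogate collapses soil-moisture variation to two values (wet
  100%, dry 50%); within-wetland moisture gradients are not represented.
* Extrapolation clamping means strong warming beyond the training
  temperature range saturates rather than extrapolates the temperature
  response — projected fold changes are conservative in that regime.
* The delineation treats any-step-wet pixels as wetland; merged or split
  components under extreme drawdown configurations are delineation artifacts
  the union mask cannot distinguish.
* Scenario members perturb temperature and season length only; precipitation,
  extent dynamics, and land-use change are bracketed or excluded by design.
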