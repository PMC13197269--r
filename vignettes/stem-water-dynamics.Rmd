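---
title: "Stem water dynamics: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem water dynamics: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemwater)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the sensor calibration model, the storage and strain statistics, the
soil-moisture breakpoint rule, the inference machinery, and — because the
whole pipeline is exercised against simulated data with embedded ground
truth — what the synthetic scenario generator does and does not emulate.

## The measurement model

Frequency-domain reflectometry (FDR) probes measure the dielectric
permittivity $\varepsilon_{stem}$ of woody tissue, which rises with water
content, together with stem temperature $T_{stem}$. Volumetric water
content follows a square-root calibration line,

$$\theta_{stem} = a\sqrt{\varepsilon_{stem}} + b,
  \qquad a = 0.2227,\; b = -0.396,$$

a published general calibration spanning dicot sapwood and palm stem
tissue. Because the dielectric response weakens as thermal motion
increases, raw readings drift with temperature; the correction is affine,

$$\theta_T = \theta_{stem} + (T_{stem} - T_{ref})\,\beta,
  \qquad \beta = -0.000974\ \mathrm{m^3\,m^{-3}\,^{\circ}C^{-1}},\;
  T_{ref} = 25\,^{\circ}\mathrm{C}.$$

All four coefficients are arguments of `calibration_model()`: the
published values are defaults, not constants, since users may re-fit the
line for a specific sensor batch or species. `invert_calibration()` is the
exact algebraic inverse and is what the scenario generator uses to turn a
known water-content series back into raw permittivity; the round trip is
tested to $10^{-12}$.

Two deliberate choices here:

* $\Delta T$ is $T_{stem} - T_{ref}$, exactly as the correction is usually
  stated, even though one could argue the physical sign convention either
  way. Changing the convention is equivalent to flipping the sign of
  $\beta$, which the user controls.
* Calibrated values outside $[0, 1]$ are **flagged, not clipped**
  (`out_of_range` column; `clip = TRUE` opts in). Silent clipping hides a
  mis-applied calibration; nothing downstream requires boundedness.
* Missing raw samples stay missing. The calibration stage does no
  interpolation — gap policy belongs to the daily aggregation, which owns
  a completeness rule (below).

## Storage and discharge statistics

All percentile summaries share one convention: linear interpolation
between order statistics (`stats::quantile()` type 7), fixed in
`percentile()`. The choice matters little at $n \approx 15{,}000$ samples
per season, but fixing it package-wide keeps every stage mutually
consistent.

Per tree, over the full record:

* turgid water content $\theta_t$ — the seasonal 99th percentile, a
  trimmed maximum robust to spikes;
* dry water content $\theta_d$ — the 1st percentile. Summaries of this
  kind are sometimes printed against a "0.01st" percentile; we read that
  as a typographical slip for the 1st and expose `p_lo` so either can be
  used;
* seasonal discharge magnitude $\Delta\theta = \theta_t - \theta_d$ and
  the water deficit $(\theta_t - \theta_d)/\theta_t \times 100\,\%$;
* maximum diurnal discharge capacity — the 99th percentile of within-day
  ranges (within-day 99th minus 1st percentile).

Days are calendar days (local site time; timestamps are stored naive-UTC
and never shifted, since every analysis is day-boundary based). A day is
retained only if at least 80% of its expected samples are present: at
15-min cadence the within-day 99th percentile is essentially the daily
maximum, and heavily gapped days would bias ranges low.

Relative water content, $RWC = \theta_T / \theta_t$, is **not capped at
1**: values slightly above 1 occur by construction for samples above the
99th percentile and are retained (high-hydration days are excluded from
strain statistics anyway, see below).

Total active storage uses the geometry appropriate to each growth form.
Palms lack secondary growth and conduct through the whole stem, so the
stem is treated as a cylinder, $S = \pi (DBH/2)^2 H \theta$. Dicots store
active water in the sapwood annulus,
$A_s = \pi[(DBH/2)^2 - (DBH/2 - d_s)^2]$, tapered over the bole with
factor $f = 0.5$: $S = f A_s H \theta$. When sapwood depth was not
measured, a linear DBH allometry is used, anchored by default at 3.5 cm
depth for a 0.22 m DBH subcanopy tree; the anchor is a default argument
of `sapwood_depth_allometry()`, not a hidden constant, because sapwood
allometries are site-specific.

## Hydraulic strain and critical RWC

Daily relative discharge capacity is the day's range expressed as a
percentage of the tree's maximum diurnal discharge capacity. Strain
classes bin that capacity: severe $[0, 5)\%$, high $[5, 10)\%$, moderate
$[10, 20)\%$, none at or above 20%. Bins are lower-inclusive — the
phrasing "dropped to 10–20%" and "below 5%" implies the lower edge
belongs to the more severe bin, and exact boundary hits are measure-zero
on real data.

Days with daily-maximum RWC above 0.95 are excluded from strain
statistics: near saturation, a small amplitude reflects water abundance
(nothing to mobilise beyond demand), not hydraulic limitation. The
exclusion cutoff is an argument (`rwc_exclude`).

Per tree:

* $RWC_{crit}$ — mean daily-max RWC over non-excluded days with capacity
  below 10%: the hydration level at which diurnal mobilisation is
  critically impaired. If no day dropped below 10% the threshold was
  never reached; the result is **censored**, reported as an upper bound
  at the minimum observed daily-max RWC with a machine-readable flag and
  a `"< x"` label. A censored bound is information, not failure: it says
  the tree stayed comfortably above its critical level all season.
* $RWC_{mrc}$ — mean daily-max RWC over days with capacity above 75%,
  computed over the **entire** record including high-hydration days:
  near-optimal functioning sits mostly in the wet season, so excluding
  wet days would bias it.
* $RWC_{min}$ is the minimum of the daily maxima (not of all samples):
  the daily maximum is the hydration-status proxy throughout, so its
  minimum is the comparable extreme. A different convention would mix
  night-time status with mid-day transients.

The VPD check asks whether reduced discharge under drought tracks
atmospheric demand: Pearson correlation between daily maximum VPD (the
within-day 99th percentile of VPD) and capacity, over stress days only
(daily-max RWC $\le$ 0.95). Weak or negative correlations implicate
internal regulation (stomatal closure) rather than a non-demanding
atmosphere. VPD uses the Tetens saturation curve,
$e_{sat} = 0.6108\,e^{17.27 t/(t+237.3)}$ kPa — fully specified here
rather than delegated to a package default, at the cost of
coefficient-level agreement with other formulations (differences are
$<1\%$ over 0–45 °C).

## The soil-moisture breakpoint

The coupling analysis pairs, per calendar day, the daily maximum soil VWC
at one depth (100 cm by default — the headline depth; others via
`depth_cm`) with each tree's daily maximum stem RWC, then fits a
penalized cubic regression spline (basis dimension $k = 6$, REML
smoothing selection, Gaussian response with identity link) through the
pooled cloud. $k = 6$ keeps the smooth flexible enough for one knee while
resisting overfit; the response is bounded but observed well inside
$(0,1)$, so a Gaussian family is standard practice. Group smooths
("palm", "dicot") and an F-type model comparison of pooled vs
group-specific smooths (`compare_groups()`) answer whether the two growth
forms share a response curve. A full random-smooth (per-tree) structure
is deliberately out of scope; per-group fixed smooths provide the
derivative the threshold rule needs.

The derivative of the fitted smooth is evaluated on a uniform grid of 200
points, with pointwise 95% CIs from 1000 draws of the coefficient
posterior (Gaussian approximation, seeded). Both sizes are arguments;
the defaults give stable quartile and CI estimates at negligible cost.

The breakpoint rule works **in the drying direction**. As soil dries, a
rapid stem-water decline appears as a strongly negative drying-direction
derivative $D = -\,d\widehat{RWC}/d\,VWC$ (equivalently, a strongly
*positive* VWC-direction derivative). A grid point qualifies when the
decline is

* **significant** — the upper confidence limit of $D$ is below zero, and
* **pronounced** — $D$ lies within the strongest negative quartile (at or
  below the 25th percentile of all grid values of $D$),

and the threshold is the soil VWC of the first point, scanning from wet
to dry, that opens a run of at least five consecutive qualifying points.
Five points guard against isolated significant wiggles; absence of any
such run is a valid result, reported as `NA`. The rule is invariant to
affine rescaling of the response, and the detection trace (per-point
booleans) is kept on the result object so a threshold can always be
audited.

## Group inference

With two palms and five dicots, classical two-sample machinery is
fragile, so two complementary tests are provided. The one-sample $t$
treats the palm mean as the hypothesised value for the dicot sample
(`stats::t.test()` underneath). The permutation test uses the difference
in group means; with $\binom{7}{2} = 21$ label arrangements, the
implementation enumerates **exhaustively** whenever the arrangement count
is at most `n_perm` (default 5000), making the test exact at study-scale
sample sizes — Monte-Carlo sampling is reserved for larger groups, with
the observed arrangement counted in numerator and denominator so $p > 0$
always. At $n = 2$ vs 5 the smallest attainable two-sided $p$ is
$1/21 \approx 0.048$: agreement between a significant $t$-test and the
permutation floor is exactly the behaviour expected at these sizes.

## What the synthetic generator emulates

`generate_scenario()` builds a complete, internally consistent data set
with known ground truth, so every stage — and the pipeline end-to-end —
is testable without field data. Default conditions emulate a 163-day
seasonal dry-down at 15-min resolution: a wet month, a long rainless
decline, and a rewetting phase, for seven trees (two palms, five dicots)
whose storage magnitudes mirror the published study-site values.

The construction, per tree:

* **Soil** (hourly, three depths, deeper horizons scaled slower): VWC
  decays exponentially toward a residual between rain events and
  recharges in proportion to event depth, capped at a wet-season maximum
  (defaults 0.30 initial, 0.32 cap, 0.12 residual, 0.014 day$^{-1}$,
  0.0015 m$^3$m$^{-3}$mm$^{-1}$). Rain is a Poisson process (0.7 events
  day$^{-1}$, mean depth 10 mm) active in the wet phases only.
* **Nightly-maximum baseline**: equal to $\theta_t$ while soil VWC is
  above the refill cutoff (0.19 m$^3$m$^{-3}$); once below, it declines
  along a logistic curve in accumulated severity-days toward $\theta_d$,
  producing the threshold-like knee the coupling analysis is designed to
  find with a single controllable parameter. Above the cutoff the
  baseline relaxes back toward $\theta_t$ at 0.25 day$^{-1}$ — the sharp
  rehydration response FDR sensors are known for.
* **Diurnal cycle**: a Gaussian-shaped midday discharge dip (centre 13:30,
  width 3 h), flat through the night, so the pre-dawn plateau is the
  nightly maximum. Daily amplitude is the tree's maximum amplitude times
  a day-to-day variability factor (uniform on [0.8, 1]) times a logistic
  gate that shuts discharge down to a 3% residual as nightly-maximum RWC
  crosses the tree's $RWC_{crit}$ (width 0.004 RWC units).
* **Sensor signal**: the water-content series is pushed through the exact
  inverse calibration at a shared stem-temperature sinusoid (24–32 °C,
  peak 15:00) and Gaussian permittivity noise (SD 0.005) is added —
  instrument-class precision, small against even the smallest dicot
  diurnal amplitude. A single seeded RNG stream drives the scenario, with
  per-tree sub-streams derived from it, so output is bit-reproducible.

What it does **not** emulate — and what passing tests therefore do not
show about real data: no mechanistic soil–plant–atmosphere transport, no
sap flow or leaf water potential, no hysteresis or time lags between soil
recharge and stem refill beyond the first-order relaxation, no
heteroscedastic or drifting sensor error, no multi-tree microclimate
differences, and rain that rehydrates instantaneously at the hour it
falls. Parameter-recovery results certify the *estimators* under known
dynamics, not the field realism of those dynamics.

Recovery under default conditions (checked across 25 seeds in the test
suite): $\theta_t$ within $\pm 0.01$ m$^3$m$^{-3}$, diurnal amplitude
within $\pm 15\%$, $RWC_{crit}$ within $\pm 0.05$ for trees that cross
it, and the soil breakpoint within $\pm 0.02$ m$^3$m$^{-3}$ of the 0.19
refill cutoff. Two known, deliberate biases: $RWC_{crit}$ estimates sit
slightly below truth (days qualifying for the mean lie below the gate's
10% crossing), and the detected breakpoint sits slightly above the
refill cutoff (the spline spreads the knee toward the wet side). Both
are within the stated tolerances and are properties of the estimators,
not bugs.

## Numerical choices and degenerate inputs

* Percentiles: type-7 linear interpolation everywhere.
* Day retention: $\ge 80\%$ of expected samples; boundary at local
  midnight.
* Spline derivative: centred difference at $10^{-6}$ of the soil range on
  the basis — exact for cubic splines to rounding; the derivative
  integrates back to the fitted curve to $10^{-6}$ relative.
* REML non-convergence falls back to GCV with a warning.
* Strain bins are lower-inclusive; the class partition covers $[0,
  \infty)$ with no gaps.
* Degenerate inputs error loudly and early: empty series, all-missing
  permittivity, zero diurnal amplitude (capacity undefined), non-positive
  reference maxima, sapwood depth at or beyond the stem radius, fewer
  distinct soil values than basis functions.
* Problem sizes in the shipped tests: full-length 163-day scenarios for
  recovery checks (25 seeds), 2000 replicates for permutation type-I
  calibration, 200-point derivative grids with up to 1000 posterior
  draws — all chosen as the defaults the analyses themselves use.

## A worked run

```{r pipeline, eval = FALSE}
sc <- generate_scenario(scenario_config(seed = 42))
res <- run_pipeline(sc, seed = 42)
res$metrics |> select(tree_id, theta_turgid, seasonal_delta, diurnal_delta)
res$strain |> select(tree_id, rwc_crit_label, d_crit_10, d_mod)
glance(detect_threshold(res$derivatives))
autoplot(res$threshold)
```

## Known limitations

The censored-$RWC_{crit}$ bound depends on the observed season: a longer
or deeper drought would move it. The breakpoint detector assumes a single
dominant knee; multiple thresholds (e.g. per depth) require running it
per depth. Group smooths share a single smoothing parameter per group but
not per tree, so a tree with idiosyncratic coupling can pull its group's
curve. And the permutation test's exactness at $n = 2 + 5$ comes with a
hard $p$-value floor of $1/21$ — no amount of effect size can push below
it at these sample sizes.
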