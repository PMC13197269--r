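# stemwater

Analysis of continuous stem water content in trees and palms measured with
frequency-domain reflectometry (FDR) sensors.

Arborescent palms store water in parenchyma-rich stems and are hypothesised
to act as hydraulic capacitors, buffering transpiration against drought.
Testing that idea requires turning raw dielectric-permittivity time series
into physiologically meaningful quantities: how much water a stem holds,
how much it mobilises daily and seasonally, at what hydration level daily
mobilisation collapses, and at what soil moisture the stem disconnects from
the soil. `stemwater` implements that pipeline for ecophysiologists working
with sub-daily FDR records, with palm-vs-dicot contrasts built in.

## The models at its core

**Calibration.** Volumetric stem water content from permittivity,
θ_stem = 0.2227 √ε_stem − 0.396, with the affine temperature correction
θ_T = θ_stem + (T_stem − T_ref)·β, β = −0.000974 m³ m⁻³ °C⁻¹, T_ref = 25 °C.
Coefficients are arguments, the published general calibration is the
default.

**Storage statistics.** Per tree: turgid water content θ_t (seasonal 99th
percentile), dry content θ_d (1st percentile), seasonal discharge
Δθ = θ_t − θ_d, water deficit (θ_t − θ_d)/θ_t × 100 %, maximum diurnal
discharge capacity (99th percentile of within-day ranges), and total active
storage S (cylinder × θ for palms; tapered sapwood annulus × θ for dicots,
taper f = 0.5).

**Hydraulic strain.** Daily relative discharge capacity (% of the tree's
maximum) classified into strain bins — severe [0,5)%, high [5,10)%,
moderate [10,20)% — over days with daily-max RWC ≤ 0.95. RWC_crit is the
mean daily-max RWC over days below 10 % capacity (censored as "< min" when
never reached); RWC_mrc the mean over days above 75 % capacity on the full
record.

**Soil coupling.** Daily-max stem RWC against daily-max soil VWC, fitted
with a penalized cubic regression spline (k = 6, REML). The breakpoint is
the first soil VWC, scanning wet → dry, where the drying-direction
derivative of the smooth is significantly negative (95 % simulation CI)
*and* within its strongest negative quartile, sustained for ≥ 5 consecutive
grid points.

**Inference.** One-sample t-tests of dicot values against the palm mean,
and an exact (exhaustively enumerated) permutation test on the difference
in group means — 21 arrangements at the study's n = 2 palms vs 5 dicots.

A synthetic scenario generator (`generate_scenario()`) builds full sensor /
soil / meteorology data sets with known ground truth (storage magnitudes,
critical RWC, refill cutoff), so the entire pipeline is testable without
field data.

## Worked example

Simulate the default 163-day dry-down (two palms, five dicots, 15-min
cadence) and run the full pipeline:

```r
library(stemwater)
library(dplyr)

sc  <- generate_scenario(scenario_config(seed = 42))
res <- run_pipeline(sc, seed = 42)
res
#> <stem_pipeline>
#>   7 trees, 1141 days retained
#>   soil threshold: 0.205 m^3 m^-3

res$metrics |> select(tree_id, group, theta_turgid, seasonal_delta, diurnal_delta)
#> # A tibble: 7 × 5
#>   tree_id group theta_turgid seasonal_delta diurnal_delta
#> 1 palm_a  palm         0.673         0.239         0.0576
#> 2 palm_b  palm         0.728         0.238         0.0380
#> 3 dicot_a dicot        0.459         0.102         0.0279
#> 4 dicot_b dicot        0.391         0.0989        0.0252
#> 5 dicot_c dicot        0.485         0.0947        0.0122
#> 6 dicot_d dicot        0.366         0.0733        0.0162
#> 7 dicot_e dicot        0.352         0.0707        0.0133
```

Palms recover their embedded turgid contents (0.673 / 0.728 m³ m⁻³) and
carry roughly twice the dicots' diurnal discharge. Strain thresholds show
the same split the field data show — one palm and two dicots cross their
critical RWC during the drought, the others never do and get censored
bounds:

```r
res$strain |> select(tree_id, rwc_crit_label, rwc_min, d_crit_10, d_crit_5)
#> # A tibble: 7 × 5
#>   tree_id rwc_crit_label rwc_min d_crit_10 d_crit_5
#> 1 dicot_a 0.78             0.780        27       25
#> 2 dicot_b 0.75             0.750        27       21
#> 3 dicot_c < 0.82           0.825         0        0
#> 4 dicot_d < 0.84           0.836         0        0
#> 5 dicot_e < 0.83           0.829         0        0
#> 6 palm_a  0.65             0.648        26       25
#> 7 palm_b  < 0.72           0.716         0        0
```

The detected soil-moisture breakpoint sits at 0.205 m³ m⁻³, just above the
generator's 0.19 refill cutoff (the spline spreads the knee slightly
wetward — see the vignette). On the published per-tree reference table the
group contrast machinery reproduces the field study's headline numbers:

```r
group_contrast(reference_storage_table(), "theta_t") |>
  select(palm_mean, palm_sd, dicot_mean, dicot_sd, t_p_value, perm_p_value)
#> # A tibble: 1 × 6
#>   palm_mean palm_sd dicot_mean dicot_sd t_p_value perm_p_value
#> 1     0.700  0.0389      0.411   0.0585  0.000377       0.0476
```

i.e. palm θ_t = 0.700 ± 0.039 vs dicot 0.411 ± 0.058 m³ m⁻³ (t-test
p < 0.001; the permutation p of 1/21 is the smallest attainable at these
sample sizes) — a ~70 % storage advantage for the palms.

## Package tour

| area | functions |
|---|---|
| calibration | `calibration_model()`, `calibrate_theta()`, `temperature_correct()`, `invert_calibration()`, `calibrate_series()` |
| meteorology | `vpd()`, `esat_tetens()`, `daily_max_vpd()` |
| storage metrics | `percentile()`, `summarise_days()`, `storage_metrics()`, `sapwood_area()`, `active_storage()`, `relative_soil_water()` |
| strain | `capacity_series()`, `classify_strain()`, `strain_thresholds()`, `vpd_capacity_correlation()` |
| soil coupling | `daily_pairs()`, `fit_smooth()`, `derivative_with_ci()`, `detect_threshold()`, `compare_groups()` |
| inference | `group_means()`, `one_sample_t()`, `permutation_test()`, `group_contrast()` |
| synthetic data | `scenario_config()`, `scenario_trees()`, `generate_scenario()`, `write_scenario()` |
| I/O & orchestration | `read_sensor_csv()` and friends, `run_pipeline()` |
| results as tibbles / plots | `tidy()`, `glance()`, `augment()`, `autoplot()`, `plot_series()`, `plot_strain()` |

The vignette (`vignettes/stem-water-dynamics.Rmd`) documents the models,
the threshold rules, every tunable default, and what the synthetic
generator does and does not emulate.
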