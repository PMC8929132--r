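---
title: "Methods: water and heat stress envirotyping for sorghum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water and heat stress envirotyping for sorghum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Breeding programs need to know *which* stress environments their target
region actually throws at a crop, and how often. For grain sorghum in the
US Great Plains the two dominant abiotic stressors are water deficit and
heat around flowering. `sorghumTPE` characterizes a target population of
environments (TPE) by simulating many seasons, summarizing each season as a
pair of stress-index trajectories, clustering those trajectories into
recurring *water stress patterns* (WSP) and *heat stress patterns* (HSP),
and regrouping the cross of the two into four *environment category groups*
(ECG): no stress, heat, water, and combined heat and water stress. A second
stage classifies independent trial site-years into those patterns and asks
how much of the observed yield variance the categories explain.

## The season model

The daily simulator is deliberately minimal: the pipeline consumes only the
two stress indices and yield, so the fidelity target is trajectory *shape*,
not absolute agronomic accuracy.

**Phenology.** Development runs on thermal time computed from the daily
mean temperature with a broken-stick response between cardinal temperatures
(`t_base` 11, `t_opt` 30, `t_max` 42 °C — conventional sorghum values,
configurable). Milestones are thermal-time sums from emergence:
`tt_anthesis` 700 °Cd and `tt_maturity` 1250 °Cd for the reference hybrid
(the second bundled hybrid is ~1 relative-maturity unit later). These were
chosen once so that all four regional sowing dates (May 15 through July 1)
mature inside the bundled synthetic climates; a crop that has not matured
after `max_days = 210` days fails as an incomplete season and is excluded
with a count.

**Canopy and growth.** Leaf area index is a logistic in thermal time
(`lai_max` 4 at the 28 plants m⁻² reference density, midpoint 400 °Cd),
scaled linearly by plant density; no senescence or tillering. Daily biomass
gain is the radiation-limited gain (radiation-use efficiency
`rue` = 1.25 g MJ⁻¹ on intercepted radiation, interception
`1 − exp(−0.55·LAI)`) multiplied by the day's water stress index.

**Water supply, demand, and RT.** The soil is a cascading bucket of layers
(thickness, lower limit, drained upper limit, extraction fraction `kl`).
Demand converts the radiation-limited gain to water through the
transpiration-efficiency coefficient (`te_coeff` = 9 g m⁻² kPa mm⁻¹) at the
daytime vapour-pressure deficit, `0.75·(svp(Tmax) − svp(Tmin))`. Supply sums
`kl`-weighted extractable water over rooted layers (root front at
1.2 mm °Cd⁻¹). The **relative transpiration index** is
`RT = min(1, supply/demand)` (1 when demand is zero): 1 means no stress,
0 complete stress. The daily bucket order is rain infiltration (cascade to
each layer's drained upper limit, surplus below the profile leaving as
drainage), then root uptake proportional to each layer's share of
extractable supply, then stage-one soil evaporation from the top layer.
Uptake after infiltration guarantees that a transpiration cap computed on
the pre-step state is always honoured, and mass balance closes to machine
precision every step (a property the tests sweep over 500 random seasons).

**Heat and GT.** Seed set is sensitive from 50 °Cd before anthesis to
100 °Cd after. The seed-set factor is `1 − f`, where `f` is the
thermal-time-weighted fraction of that window falling on days with
Tmax > 32 °C. Whether the source model weights window days by days or by
°Cd is not documented; °Cd weighting is the default and day weighting is
available via `weighting = "days"`. The *daily* heat index used for
trajectories is binary — 0 on window days above the threshold, 1 elsewhere
— because only the windowed fraction, not a daily form, is defined.

**Yield.** Grain number is proportional to the mean crop growth rate over
the seed-set window (1600 grains per g m⁻² d⁻¹); yield is the smaller of
grain number × potential grain weight (25 mg) and 95% of post-anthesis
biomass gain, multiplied by the GT factor. Nitrogen is *not* simulated: the
two management levels enter only through their paired plant densities
(28 and 14 plants m⁻²); the nitrate initial condition is accepted in
configuration and ignored, for compatibility.

## From seasons to patterns

Each season's daily RT and GT series are averaged into consecutive
100 °Cd bins from emergence (`bin_trajectory`). All environments are put on
a fixed grid of `n_bins = floor(tt_maturity/100) = 12` bins — k-means needs
equal-length vectors; shorter seasons are right-padded with their final
bin's value. Water and heat matrices are clustered independently with
Euclidean k-means on the raw [0, 1] bins (no standardization: bins share
units and scale), 25 restarts, seeded and fully deterministic. The number
of clusters is chosen by a majority vote of three internal validity indices
— mean silhouette width, Calinski–Harabasz, Davies–Bouldin — with ties
broken toward the smaller k; any k can be forced from the configuration
(`clustering$k_wsp`, `clustering$k_hsp`). On the bundled synthetic
climates the vote tends to favour k = 2 for both indices (the synthetic
stress gradient is smoother than a real station network), while the demo
runs the published-style configuration k_wsp = 4, k_hsp = 3.

Cluster ids are assigned by descending frequency for reporting stability.
Semantic names ("terminal stress with recovery" etc.) are attached by
inspecting centroid shape (`name_wsp_centroids`), never hard-coded. New
seasons are classified by minimum sum of squared differences to the
centroids, ties toward the lowest id.

The four ECG categories are the cross of a *non-stress* WSP set and a
*low-heat* HSP set. Both sets are data-driven: a cluster counts as
unstressed when its mean simulated yield is within 90% of the best
cluster's mean (`ecg_yield_frac`). With four water and three heat patterns
the defaults reduce to the ({WSP2}, {HSP1}) convention.

## Trial analysis

Observed trial yields (site × year × hybrid) are joined to the ECG of
their site-year, classified from one reference-cultivar simulation each.
Variance components come from the REML mixed model
`yield ~ 1 + (1|site) + (1|site:ecg)` (lme4); a hybrid intercept is
available behind `include_hybrid`. The hybrid × site-year matrix is
completed by iterative rank-2 SVD imputation — initialize gaps with column
means, then repeat {column-center, rank-2 SVD, rebuild, overwrite only the
gaps} to convergence; observed cells are never modified. Rank 2 matches the
two-axis biplot and is configurable. The biplot is the column-centered SVD
of the hybrid × ECG mean matrix, with loadings scaled by the singular
values so the cosine between category vectors approximates their
correlation over hybrids (≈180° = negatively correlated, ≈90° =
uncorrelated).

Agreement statistics (`agreement`) follow the textbook forms: RMSE; NRMSE
normalized by the observed mean × 100 (the normalizer is stated here
prominently because several conventions circulate); Nash–Sutcliffe
efficiency with 1 = perfect and 0 = predicting the observed mean; Pearson
correlation. Degenerate inputs (zero observed mean or variance) return `NA`
with a flag rather than an error.

## The synthetic generators

**Weather** (`gen_weather`): monthly climatological Tmax/Tmin interpolated
to day-of-year plus a shared AR(1) residual (lag-1 ρ ≈ 0.6, sd ≈ 3–4 °C)
and smaller independent disturbances; Bernoulli rain occurrence per day with
monthly probability and exponential wet-day depths; clear-sky sinusoidal
radiation (16 ± amplitude MJ m⁻² d⁻¹, peak at the solstice) reduced 25% on
wet days. Three presets span a west–east gradient: `dry_west` (~300 mm
annual rain, hot summer), `intermediate` (~550 mm), `wet_east` (~850 mm,
milder). What it does **not** emulate: rain-spell persistence (no Markov
chain — occurrence independence suffices for seasonal totals), spatial
correlation between sites, radiation–temperature coupling beyond the wet-day
discount, and trends. Passing tests therefore show the *machinery* recovers
known structure, not that real station data would yield the published
pattern frequencies. One visible consequence: with the 32 °C threshold the
synthetic July-anthesis seasons are heat-stressed more often than the
region-wide shares reported from station data.

**Trials** (`gen_trial_table`): yields are
`grand mean + site + ECG(site) + hybrid + residual`, each effect Gaussian
with its stated variance; categories cycle across years within site so the
nested effect is estimable; a fraction of records is deleted at random to
emulate unbalanced public trial archives. True effects are returned for
recovery tests.

## Numerical choices and degenerate inputs

- All randomness flows from one explicit integer seed (`withr::with_seed`);
  no hidden global state. Per-site weather seeds are derived arithmetically
  from the run seed.
- k-means with fewer distinct rows than k returns a non-empty split with
  zero inertia and variance-explained defined as 0 when total SS is 0.
- `rt_index(supply, 0) = 1` by convention (no demand, no stress).
- `impute_gaps` defaults to an absolute tolerance of 1e-6 and flags
  non-convergence with a warning carrying the last delta. The pipeline calls
  it with tol = 2 kg/ha and a high iteration cap: EM-SVD converges linearly
  with a rate near 1 on small noisy matrices, so micro-tolerances on a
  kg/ha scale cost thousands of iterations for no information.
- Variance components at the REML boundary are reported as zero; a design
  with one category per site is flagged as confounded.
- Output files are written sorted (site, year, sowing, management) so
  re-running a configuration with the same seed reproduces every CSV/JSON
  byte-identically. The run manifest carries a wall-clock timestamp and is
  the one file excluded from that guarantee.

## Problem sizes

The test suite works at deliberately small scale: toy 2-layer soils and
short-cycle cultivars for property sweeps (500 random 120-day seasons for
mass balance, 1000 random seasons for the GT oracle), 100-row prototype
matrices for cluster recovery, 30 sites × 20 years × 50 seeds for
variance-component recovery, and a 3-site × 8-year demo for end-to-end
determinism. The acceptance script runs 3 sites × 15 years × 4 sowing
dates × 2 managements × 2 cultivars (720 scenario seasons before
exclusions). These sizes were chosen as the smallest at which the checked
properties are statistically meaningful.

## Known limitations

No tillering, senescence, stay-green, night-temperature or grain-size heat
response; no nitrogen dynamics; no CO₂ response; thermal time from daily
means rather than sub-daily interpolation; binary daily heat index;
independent-occurrence rainfall. The simulator is a purpose-built stand-in
whose job is to produce realistic *stress trajectory shapes* and yield
orderings for exercising the envirotyping machinery end to end.
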