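---
title: "Modeling and projecting compound ozone-temperature events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and projecting compound ozone-temperature events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ground-level ozone and air temperature are strongly coupled in large parts
of Europe: photochemical ozone production accelerates with temperature, and
the synoptic situations that bring heat also favor ozone accumulation. Days
on which both are simultaneously high — compound o-t-events — carry a
health burden beyond either stressor alone. `otevents` implements a
region-aware statistical chain for such events: define them at monitoring
stations, group stations into regions of homogeneous joint variability, fit
station-level statistical downscaling models on large-scale meteorological
and synoptic predictors, and drive those models with (bias-corrected)
Earth-System-Model output to project how event frequencies shift in a
warming climate.

This vignette documents the modeling choices, tunable parameters, and
numerical conventions, and states precisely what the synthetic experiments
in the test suite do and do not demonstrate.

## Event definition

A day is a compound event when both components strictly surpass their
thresholds:

* **Ozone**: MDA8O3 > 100 μg/m³. MDA8O3 is the maximum over a day's 8-hour
  running means, computed from valid hours only. A window is attached to
  its *ending hour* h ∈ 1..24, so windows ending in hours 1–7 reach into
  the previous calendar day (the EU air-quality convention; an
  interior-only mode is available). A window is valid with ≥ 6 of 8 valid
  hours; a day's MDA8O3 exists only with ≥ 18 valid windows. Both cutoffs
  are arguments of `compute_mda8()`.
* **Temperature**: TX > ^80TX(d), the calendar-day 80th percentile of TX
  pooled over a 31-day window centred on d across all base-period years.
  Percentiles use linear interpolation between order statistics
  (`quantile(type = 7)`); the percentile, window width, and a minimum pool
  size (default 100 values) are arguments of `tx_thresholds()`. Near the
  season edges the window simply extends into out-of-season days when the
  series contains them; the calendar is not wrapped. Feb 29 pools are
  merged into Feb 28.

The percentile construction forces t-events onto ~20% of days at every
station, which makes event counts comparable across climatically different
regions; what varies regionally is how often the ozone exceedance coincides.

A sampling caveat worth stating explicitly: a 31-day x 15-year pool holds
465 values, so the 80th-percentile estimate carries a sampling sd of about
0.066 standardized units (delta method). Individual calendar-day thresholds
therefore scatter around the true quantile by more than ±0.1 on roughly one
day in eight, and because neighbouring days share 30/31 of their pool these
errors are strongly serially correlated. The event *rate* is far more
stable than any individual day's threshold.

## Station pairing

Ozone stations are assigned their nearest temperature station within 15 km
and 200 m altitude difference (great-circle distances, Earth radius
6371 km). Pairs must exceed 75% joint seasonal coverage (both variables
present), strictly. When two ozone stations claim one temperature station,
the higher-coverage pair wins, so no temperature series is duplicated.
Among several eligible temperature stations the selection is nearest-first
with deterministic tie-breaks (smaller altitude difference, then
lexicographic id); the coverage rule is applied jointly to both variables.
Pair location metadata is the ozone site's.

## Regionalization

Stations are clustered on the concatenation of their standardized seasonal
TX and MDA8O3 series (each block centred and scaled per station), after
missing values are filled with the cross-station same-date mean. The
network-wise daily mean was chosen over the per-station calendar-day mean
because it preserves the day-to-day synoptic signal that the clustering is
meant to group; the calendar-day variant is available
(`impute_daily_means(method = "calendar")`). Imputation precedes
standardization.

Ward's variance-minimization linkage on Euclidean distances does the
agglomeration (`stats::hclust(method = "ward.D2")`; heights equal
√(2·ΔESS)). The cluster count is chosen by an explicit elbow rule — the k
in `k_min..k_max` whose cut removes the largest gap between successive
merge heights — with `k_min = 4` so that broad geographical contrasts are
always resolved; dendrogram inspection, which the rule operationalizes,
cannot be automated faithfully, and on featureless data the rule falls back
to `k_min`. New stations are assigned by the Ward criterion in its
size-weighted centroid form, n_c/(n_c+1)·‖x − c‖². Within each region, the
station of each type (urban/suburban/rural) closest to the centroid becomes
a representative, ranked by distance.

## Weather typing

Daily MSLP fields are standardized per grid cell over time (the
preprocessing parameters are stored and reused for ESM data; daily-anomaly
or area-weighted alternatives could be slotted in, but per-cell
standardization keeps every cell on equal footing for the Euclidean
metric). A rectangular SOM is trained online with a Gaussian neighborhood;
sigma and the learning rate decay as x/(1 + t/(T/2)). Weights are
initialized from randomly drawn training days; everything is deterministic
given the seed. Nodes are numbered row-major and 1-based so weather-type
codes are stable.

Grid size is selected over candidate shapes (node counts 4–20) by the
Bauer–Pawelzik topographic product, taking the model with the smallest
|TP|: zero indicates ideal topology preservation, and the sign only
indicates in which direction the map dimensionality mismatches the data.
Each day's weather type is the index of its nearest node; ties take the
lowest index. The fraction of empty nodes under new (e.g. ESM) data is
observable from the assignment table.

## Predictors and ESM preprocessing

Station predictor series are the daily means of the 3×3 grid-cell block
centred on the cell containing the station, for 850-hPa geopotential
height, temperature, and specific humidity plus surface solar radiation;
at domain edges the block is clipped to available cells rather than padded.
Series are standardized over the reference period with stored parameters.
Within-region predictor agreement is checked by pairwise Spearman rank
correlations with a 0.5 flag level; flags are reported, never enforced.

ESM fields are regridded to the reference grid by bilinear interpolation
(no extrapolation), then bias-corrected by monthly linear scaling: the
per-month mean difference to the reference over the historical overlap is
added to every value of that month, historical and scenario alike. The
correction is additive for all variables including SSRD (a multiplicative
mode exists behind a flag); it is exact on monthly means by construction,
which the test suite asserts at 1e-9. Offsets are estimated from all twelve
months of the overlap. MSLP is corrected cell by cell before weather types
are assigned. Distributional similarity after correction is summarized by
two-sample Kolmogorov–Smirnov tests, reported but never used as a gate.
For projections, historical and scenario series are concatenated and
standardized jointly, so a scenario's mean change survives the transform.

## Downscaling models

Each representative station gets a logistic regression of its o-t-event
indicator on the five standardized predictors (GH, MT, SH, SSRD, and the
weather-type code as a single standardized numeric covariate — a one-hot
encoding would spend ~8 extra degrees of freedom and break the single-
coefficient driver ranking). Training sets are rebalanced with SMOTE to
exact class parity (k = 5 minority neighbors, originals preserved).
Predictors are then pruned by Wald backward elimination: drop the single
worst predictor with p > 0.05, refit, repeat. Drivers are ranked by
|standardized coefficient| (ties broken by the fixed order GH, MT, SH,
SSRD, WT); the top three are the MID/SMID/TMID.

Evaluation is a stratified outer ten-fold cross-validation; within every
training fold the full pipeline (SMOTE → elimination → fit) is refit and an
inner ten-fold calibration picks the probability threshold p\* minimizing
the fold-mean |precision − recall| over the grid 0.01..0.99 (ties resolve
toward 0.5, then smaller). Thresholds that predict no event in a fold carry
no precision information and are excluded from the search — treating their
undefined metrics as zero would make "predict nothing" a degenerate
optimum. Validation folds contain only original samples; synthetic SMOTE
points never leak into scoring. McFadden's pseudo-R² (1 − lnL/lnL₀) is
reported from the training fit, precision/recall/F1 from the untouched
validation folds.

Two honesty notes. First, coefficients fit on SMOTE-balanced data are
systematically somewhat larger in magnitude than the data-generating values
(the intercept shifts by construction; slopes inflate mildly), so
coefficient-recovery checks use the raw maximum-likelihood fit. Second,
Wald p-values computed after SMOTE are anti-conservative — interpolated
minority duplicates overstate the effective sample size — so a pure-noise
predictor survives elimination noticeably more often on rebalanced than on
raw data. The pipeline follows the rebalance-then-eliminate order because
the modeled probabilities must be calibrated on balanced data, but
significance statements after SMOTE should be read as heuristic screening,
not inference.

Perfect separation is flagged and returns the capped-iteration fit with a
warning rather than a penalized fit, keeping coefficients interpretable.

## Projection

Only stations whose cross-validated F1 reaches a quality gate (default
0.5) are projected — regions without a substantial predictor linkage are
excluded, as low-skill models would only propagate noise. A day is a
projected event when the modeled probability reaches the station's p\*;
counts are accumulated over the April–September season in three 20-year
slices (1995–2014, 2041–2060, 2081–2100) and expressed as percent changes
relative to the historical slice. Percent changes are computed per ESM and
then averaged (matching a multi-model mean of changes, not a change of
pooled counts); the ensemble summary reports mean/median/min/max and the
number of models agreeing with the majority sign — signed means are used,
with sign agreement reported rather than filtering. Raw (un-standardized)
850-hPa temperature anomalies between future and historical slices are
reported as a stationarity diagnostic, flagged at 2.7 °C (warning) and
4.0 °C (severe): where the projected climate leaves the range the model was
fit on, the stationarity assumption behind statistical downscaling weakens.

## The synthetic system

The generator emulates the statistical structure the pipeline assumes,
with known ground truth:

* **TX**: region mean + seasonal cosine (peak mid-July) + a shared
  region-level AR(1) synoptic term (coefficient 0.7, innovation sd 1.5 °C)
  + station noise (sd 0.8 °C). The shared synoptic term is what the
  regionalization must find; region means default to a 14–27 °C gradient.
* **MDA8O3**: intercept + 3 (μg/m³ per °C) × TX + noise (sd 8 μg/m³) —
  the approximately linear warm-season ozone response, with slope and noise
  per region. Missingness is injected completely at random at 5%,
  emulating the high-coverage regime that the pairing rules enforce.
* **Grids**: MSLP days are noisy copies of n smooth planted basis patterns
  (default 9, the recovered weather types); the MT field follows the
  nearest region's TX signal (offset −10 °C for the 850-hPa level); GH,
  SSRD follow the standardized synoptic anomaly positively, SH negatively.
* **Pseudo-ESMs**: the same process re-drawn per model on a coarser native
  grid (2°), plus planted per-month additive biases (~1–2 °C amplitude for
  MT) and, from 2015 onward, a linear MT trend per scenario. Defaults of
  0.33 and 0.60 °C/decade give late-century warmings near 2.5 and 4.5 °C —
  a moderate and a strong forcing pathway.

What passing tests show: the implementation recovers planted structure
(regions, patterns, coefficients, biases, trends) at realistic noise, and
the end-to-end chain responds monotonically and honestly to planted
warming. What they do not show: skill on real data. The generator has no
ozone chemistry (no precursor limitation, no plateau at extreme heat), no
informative missingness, spatially white noise, and a linear o-t link by
construction — so real-data performance claims cannot be transferred.

## Problem sizes and determinism

The test suite and the acceptance script run deliberately compact
configurations chosen as the package's own benchmark sizes: 60-station
networks for regionalization recovery, 15 base years (2004–2018), a 2×2 SOM
against 4 planted patterns, n = 2700 days with 25–50 replicate seeds for
coefficient recovery, and a 4-region / 12-station / 2-pseudo-ESM network
for the full projection chain with planted late-century warmings of
0–3 °C. All randomness flows from explicit seeds; identical configuration
and seed give bitwise-identical synthetic data and reports.

## Known limitations

* SMOTE-based Wald screening is anti-conservative (see above).
* Individual calendar-day ^80TX thresholds carry ±0.07 standardized units
  of sampling noise at 15 base years; event rates are robust, single-day
  thresholds are not.
* The elbow rule is a deterministic stand-in for expert dendrogram
  reading; on weakly structured networks it returns `k_min` by design.
* Percent changes are undefined at stations with zero historical projected
  events; such stations are reported with an explicit flag, not silently
  dropped.
* Gridded I/O uses a long-format CSV interchange plus in-memory arrays;
  fields from external NetCDF sources must be converted upstream.
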