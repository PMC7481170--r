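---
title: "Selecting and preparing regional-climate forcing for ecotron experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and preparing regional-climate forcing for ecotron experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climforce)
```

## The problem

Controlled-environment (ecotron) facilities can impose a complete
atmospheric boundary condition — air temperature, precipitation, humidity,
wind, pressure, greenhouse-gas concentrations — on intact ecosystem
monoliths. To study ecosystem responses across a gradient of global
warming levels, each experimental unit should be driven with weather that
is *physically consistent*: variables must co-vary as they do in a real
atmosphere, and extremes must arrive with realistic frequency, intensity
and duration. Averaging over model ensembles or climatological years
destroys exactly those properties, so the approach implemented here uses a
**single regional climate model (RCM) simulation, from a single grid
cell**, chosen carefully, and samples it at the times when the driving
global model reaches prescribed global-mean-temperature (GMT) anomalies.

The pipeline has three stages:

1. **Select** the best-performing RCM/GCM simulation from an ensemble,
   by (i) skill against station observations for four variables
   (air temperature, precipitation, relative humidity, wind speed) and
   (ii) representativeness of the ensemble-mean future anomaly.
2. **Sample** the scenario in time: smooth the driving GCM's annual GMT
   with a 30-year running mean, find the first year each warming threshold
   (0, +1, +1.5, +2, +3, +4 °C) is attained, and take an
   experiment-length window centred on it.
3. **Extract and condition** the 3-hourly model output for those windows
   into a 30-minute forcing table the facility's controllers can follow.

## Skill metrics and ranking

For reanalysis-driven (evaluation) runs, where day-by-day correspondence
with observations is meaningful, the package computes per variable: mean
bias, Perkins skill score (PSS; overlap of binned empirical
distributions), seasonal-cycle mean absolute error (MAE over the twelve
monthly climatological means), percentile MAE (over the 1st, 10th, 90th
and 99th percentiles), RMSE, Spearman rank correlation, and a Brier skill
score (BSS). For GCM-driven runs the internal variability of a coupled
model is not synchronized with the real atmosphere, so RMSE, Spearman and
BSS are omitted. Cross-variable Pearson correlations (annual, DJF, JJA)
compare the modelled co-variability structure against the observed one.

Choices the metric definitions leave open, fixed here:

* **PSS bins.** Defaults of 1 °C (temperature), 1 mm/day with a separate
  [0, 0.1) mm drizzle/dry bin (precipitation), 5 % (humidity) and 1 m/s
  (wind); shared edges anchored at a multiple of the bin width below the
  pooled minimum. All are configurable.
* **BSS events.** The observed climatology is split into K = 3
  equiprobable categories bounded by the observed quantiles; each day's
  event is its observed category, and the deterministic model forecast
  puts probability 1 on its own category. The reference forecast is the
  uniform 1/K. A value falling exactly on a category bound belongs to the
  lower category. This is one defensible construction of a categorical
  verification for a deterministic series; BSS = 1 iff the model
  reproduces every observed category, 0 for the uniform forecast.
* **Percentiles** use linear interpolation between order statistics
  (the type-7 convention), fixed and documented.
* **Precipitation bias** is also reported as an annual total using
  365.25-day years.
* **DJF** groups December with the following January–February; the final
  year's December is dropped.

Ranking assigns 1-best to N-worst per (variable, metric) column: biases
and diagnostic differences rank by absolute value, error metrics by
value, skill scores by negated value. Ties take the smallest available
rank in stable input order. Runs missing a variable are ranked only in
their available columns, and their composite mean rank renormalizes the
weights accordingly (unit weights by default — the ensemble's expert
weighting is unknown, so all weights are user-configurable).

The final decision is **precipitation-bias decisive**: among shortlisted
candidates whose ensemble percentile positions for the future anomaly fall
inside a central band (default [25, 75]), the run with the smallest
absolute precipitation bias wins. Water availability is the variable most
likely to constrain the ecosystem, and precipitation biases across RCMs
(up to a factor ~2.4) dwarf the temperature biases. If the band is empty
it widens symmetrically in 5-point steps, and the widening is recorded in
the selection object.

## Warming windows

The climatological GMT anomaly is a centred 30-year running mean minus the
plain mean over the reference years (1951–1955 by default). For the even
30-year window the extra year lies toward the past (year *y* averages
*y*−15 … *y*+14); a trailing alignment is available behind a flag. Years
without a complete window are dropped, never padded. Crossing uses
attainment (first anomaly ≥ threshold), not interpolation; the 0 °C
"historical" window is the reference period itself. Windows of length
*L* are centred on the crossing year with the even-length surplus toward
the past. A window reaching outside the scenario years raises an error —
silent truncation would quietly change the experiment's climate.

For a noise-free linear GMT trend *a* this machinery is analytically
invertible: the anomaly at year *y* is *a*(*y* − 0.5 − 1953), so the
detected crossing of threshold *T* is ⌈1953.5 + *T*/*a*⌉, which the test
suite verifies to within a year. Under interannual noise the reference
mean is itself a noisy 5-year average, so individual trajectories scatter
by several years at shallow trends; the detector is therefore judged on
its seed-ensemble mean, which stays well within ±3 years in the shipped
checks. `window_length_sensitivity()` recomputes every gradient index for
window lengths 1–20 years, with the reference for each length being the
0 °C window of that same length, so longer windows can be shown to yield
more monotone gradients.

## Forcing assembly

State variables (temperature, pressure, humidity, wind) are linearly
interpolated from 3-hourly to 30-minute resolution; original knots are
preserved exactly, and beyond the final knot the last segment is held so
every day keeps 48 steps. Precipitation is **never interpolated**:
interpolating an accumulation destroys mass conservation. Each 3-hour
amount is split uniformly over its six sub-steps, then passed through the
drizzle filter: amounts accumulate in a carry-over buffer and are released
in full at the first step where buffer + amount ≥ 1 mm (irrigation
hardware cannot deliver sub-millimetre events). Release happens at the
step where the threshold is first reached — the accumulation end, one of
the two readings of the rule and the one that never releases early. The
terminal buffer is reported on the forcing table, never dropped, so
released + buffer equals the input total to machine precision.

Surface pressure comes from mean sea level pressure via the isothermal
hydrostatic reduction p = mslp · exp(−g z / (R_d T_K)) with the
concurrent interpolated air temperature, g = 9.80665 m s⁻²,
R_d = 287.05 J kg⁻¹ K⁻¹ and the default site elevation of 43 m — over
such heights the difference from a lapse-rate formula is below 1 Pa.
Relative humidity derives from specific humidity through the Magnus
saturation pressure over water, e_s(T) = 611.2 · exp(17.62 T / (243.12 +
T)) Pa (the conversion feeds a controlled chamber, so no ice branch);
results are clipped to [0, 100] % and the clip count is recorded. The two
conversions are exact algebraic inverses, verified to 10⁻⁶ %. Greenhouse
gases attach as annual step functions — the concentration pathway is an
annual table, and inventing sub-annual structure would be false precision.
Latent and sensible heat fluxes, where present, pass through step-constant
at their native 3-hour resolution rather than being interpolated.

## Calendars and missing data

Model calendars (standard, 365-day, 360-day) are metadata carried on every
series and never silently coerced; day-of-year logic (July 1 for the
growing season, year lengths for day-count indices) uses each calendar's
own structure, and a 360-day date such as February 30 is never forced onto
a Gregorian axis. Metrics drop pairwise-missing days and refuse to run
when more than 20 % of the comparison days are missing (configurable) —
a skill score resting on a gappy record inherits the gap structure.
Annual indices require whole calendar years unless partial years are
explicitly allowed.

## The synthetic generator

Every stage of the pipeline is testable without external archives through
a seeded single-site weather generator: an annual harmonic plus AR(1)
anomalies for temperature (defaults: 10 °C mean, 7 °C amplitude, lag-1
autocorrelation 0.7, innovation sd 1.5 °C), tmin/tmax at ∓ half a noisy
diurnal range (8 ± 1.5 °C), a two-state Markov chain for precipitation
occurrence (p01 = 0.35, p11 = 0.65, stationary wet fraction 0.5) with
gamma amounts on wet days (shape 0.8, scale 5.3 mm, giving roughly
770 mm/yr with a realistic drizzle fraction), harmonic relative humidity
peaking in winter (80 ± 8 %) and Weibull winds (shape 1.9, scale
4.5 m/s). These defaults emulate a temperate maritime lowland climate of
the kind the reference stations record; they were chosen once from
climatological orders of magnitude and are not tuned to any test.

Pseudo-model runs reuse the generator with an independent noise
realization plus a bias specification (additive temperature/humidity
offsets, multiplicative precipitation/wind factors, temperature variance
inflation) and an optional linear warming trend — so every bias the
pipeline recovers downstream is known by construction. Each variable
draws from its own fixed substream of the run's seed, so adding a variable
never perturbs another's draws. The generator makes no attempt at
multi-site spatial correlation, compound-event physics, or reproducing any
particular station's statistics beyond orders of magnitude: passing tests
demonstrate the *bookkeeping* (metrics, rankings, windows, conservation)
on data with realistic structure, not that any real RCM would be ranked
correctly.

## Numerical choices and test scales

Metric and index implementations are pinned against independent
brute-force oracles (explicit loops and scans) on 200 random synthetic
instances of up to three years, at 10⁻¹² absolute tolerance. Forcing
conservation is checked on 100 synthetic multi-day windows (mass balance
to 10⁻¹², no released event below 1 mm, knots preserved exactly, humidity
round trip below 10⁻⁶ %). The end-to-end recovery test plants a
zero-bias, median-trend run in a ten-member ensemble of 90-year daily
runs and requires the pipeline to rank it first and select it. These
problem sizes keep the full suite around ten seconds while leaving the
statistical margins (3 standard errors for moment recovery) intact.

## Worked example

```{r example, eval = FALSE}
spec <- climate_spec(seed = 1, n_years = 30, start_year = 1977)
obs <- gen_station_obs(spec)
runs <- list(
  gen_model_run(spec, bias_spec(t_bias = 1.5, p_factor = 1.6), seed = 11),
  gen_model_run(spec, bias_spec(), seed = 12),
  gen_model_run(spec, bias_spec(t_bias = -1, p_factor = 2.2), seed = 13))
scores <- aggregate_ranks(rank_table(skill_table(runs, obs)))

gmt <- gen_gmt(gmt_spec(seed = 1, trend = 0.035))
ww <- warming_windows(gmt, reference = c(1951, 1955))

scen <- gen_model_run(spec, bias_spec(), seed = 12, experiment = "rcp85",
                      trend = 0.04, start_year = 1951, n_years = 150,
                      subdaily = TRUE)
ghg <- ghg_table(1951:2100, co2 = seq(310, 936, length.out = 150),
                 ch4 = seq(1100, 3750, length.out = 150),
                 n2o = seq(290, 435, length.out = 150))
forcing <- assemble_forcing(scen, ww, ghg)
summary(forcing[["+4C"]])
```

## Known limitations

* Selection reproduces a documented elimination; the original choice
  involved expert judgement whose implicit weighting is unknowable, so the
  composite uses unit weights unless told otherwise.
* The drizzle filter shifts sub-millimetre precipitation later in time by
  construction; over a window the displacement is bounded by the
  inter-event spacing, but sub-daily timing statistics of light rain are
  deliberately altered.
* Nearest-cell extraction is a point sample: it preserves extremes but
  carries the full local internal variability; gradient indices need not
  be monotone across warming levels for short windows (the window-length
  sensitivity table quantifies this).
* Incoming shortwave radiation and soil state are not part of the forcing
  surface here; facilities typically control those from local real-time
  observations.
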