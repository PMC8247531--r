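---
title: "Methods: wildfire-smoke health impact assessment with firehia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wildfire-smoke health impact assessment with firehia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firehia)
```

## The model and its assumptions

`firehia` estimates hospital admissions attributable to fire-originated
fine particulate matter (PM2.5) during a wildfire episode. The health
impact function is the standard log-linear form used in air-pollution
burden assessment:

$$\Delta Y(s,t) = Y_{NF}(s)\,\bigl(e^{\beta\,\Delta X(s,t)} - 1\bigr)\,Pop(s),
\qquad \beta = \frac{\ln RR}{10\ \mu g/m^3},$$

per grid cell $s$ and day $t$. Its assumptions are worth stating
explicitly:

* **The CRF transfers.** The rate ratio $RR$ (per 10 µg/m³ of 2-day
  average PM2.5) comes from prior epidemiology and is assumed to apply to
  the assessed population and smoke mixture. Both wildfire-specific and
  ambient (non-wildfire) CRF tables ship with the package
  (`crf_table()`); comparing them is one axis of the sensitivity design.
* **Impacts are relative to long-term background rates.** $Y_{NF}$ is the
  county annual admission rate divided by 100,000 and by 365. No
  seasonality or fire-period elevation of the baseline is modelled, and
  leap years are ignored.
* **Exposure is residential.** $Pop(s)$ is the census-tract population
  regridded to cells; evacuation and time-activity patterns are not
  modelled.
* **Exposure metric matches the CRF.** The CRFs are defined on 2-day
  average PM2.5, so $\Delta X$ is 2-day averaged (day $t$ averaged with
  day $t-1$). The first day of the window has no predecessor and keeps
  its own value rather than being dropped; this choice retains the first
  assessment day and is flagged in the result provenance.

## Isolating fire-originated PM2.5

Two background methods are implemented:

* **Model ratio ("zero-out")**: the non-fire share is taken from paired
  chemical-transport-model runs with and without fire emissions,
  $X_{NF}(s,t) = X(s,t)\,\mathrm{CMAQ_{back}}/\mathrm{CMAQ_{fire}}$, and
  $\Delta X = X - X_{NF}$.
* **Baseline subtraction**: a static non-fire-period surface is
  subtracted, $\Delta X = X - X_{NF}(s)$.

In both, $\Delta X$ is clamped at zero where the background exceeds the
total; the number of clamped cell-days is recorded on the result. Two
numerical choices needed a decision:

* **Order of averaging and clamping.** The clamp is nonlinear, so
  clamping daily differences and then 2-day averaging differs from
  averaging first. We 2-day average $X$ and $X_{NF}$ separately,
  difference, then clamp — consistent with defining the impact function on
  2-day-averaged inputs. The alternative order is available via
  `clamp_timing = "before"`; on smoke-dominated cells the two agree, and
  they diverge only where concentrations straddle the background.
* **Division guard.** The ratio is evaluated only where the with-fire
  model field exceeds 1e-6 µg/m³; below that both model fields are
  effectively zero and $\Delta X$ is set to 0.

Percentiles everywhere (exposure summaries, Monte Carlo CIs) use type-7
linear interpolation, R's default empirical quantile.

## Uncertainty propagation

Monte Carlo simulation (default 100,000 iterations) propagates two
sources:

* **Exposure surface.** Each cell-day's total PM2.5 is lognormal with
  moments matched to the surface's mean and estimation variance:
  $\sigma^2 = \ln(1 + v/m^2)$, $\mu = \ln m - \sigma^2/2$. Cells with
  zero mean but positive variance cannot carry a lognormal and are held
  at zero (counted and reported). The full pipeline — isolation, 2-day
  averaging, clamping, impact function — is re-run per draw, so the
  clamp's nonlinearity is propagated, not linearised.
* **CRF.** The rate ratio is lognormal: $\ln RR$ is normal with mean
  $\ln RR$ and sd $(\ln RR_{hi} - \ln RR_{lo})/(2 z_{0.975})$. A literally
  lognormal $\beta$ could never produce negative draws, yet subgroup CRFs
  with CIs straddling the null require them (they produce the negative
  lower bounds on attributable admissions); parameterising the *rate
  ratio* as lognormal resolves this and is the adopted reading.

Design choices that were genuinely open:

* **Spatial correlation of exposure draws.** Whether exposure error
  should be sampled independently per cell or jointly is not determined
  by the estimation variance alone. Independent sampling makes the
  exposure contribution to a *regional sum* vanish by averaging
  ($\mathrm{sd} \propto \sqrt{\sum v_s}$ rather than $\sum \sqrt{v_s}$),
  which contradicts the empirical finding that noisy surfaces dominate
  the uncertainty of regional admission totals. The default is therefore
  **comonotonic**: one standard-normal deviate per draw drives every
  cell-day through its own lognormal quantile, preserving full spatial
  correlation of the error field. Independent mode is retained
  (`exposure_sampling_mode = "independent"`) for study; it narrows
  regional CIs severalfold.
* **Point estimate.** The deterministic run at mean inputs, not the
  Monte Carlo mean — reported central values sit asymmetrically inside
  their CIs, as expected from a plug-in estimate under skewed sampling
  distributions.
* **Background fields are held fixed.** Uncertainty in the background
  (ratio or baseline) estimation is not propagated.
* Population and baseline-rate uncertainty are neglected (small, not
  time-varying). Cells with zero population or zero baseline rate
  contribute exactly zero and are skipped in the compiled inner loop.

`decompose_uncertainty()` re-runs the simulation with both sources, the
CRF alone, and the exposure surface alone (same seed), tabulating CI
widths. Accounting for a single source always understates the overall
width.

## The synthetic scenario generator

The generator produces every input the pipeline needs, with the
statistical structure the analysis assumes, so all behaviour is testable
without external data. What it emulates:

* **Truth fields.** Non-fire PM2.5 varies smoothly around a regional
  background (default 7 µg/m³; log-scale spatial sd 0.12, daily sd 0.05).
  The fire field is a sum of 2-D Gaussian plumes with linear drift and a
  fixed daily intensity decay of 0.85; the defaults (three plumes on a
  40 × 40 grid of 1-km cells over a 13-day window, peaks 60–120 µg/m³)
  give a multi-day episode with two exposure peaks, the desk-scale
  analogue of a two-week fire period. The Gaussian-plume form was chosen
  because it is realistic enough at this scale and admits closed-form
  oracles; no atmospheric-physics fidelity is claimed.
* **Three estimation methods.** Each method's surface is truth plus
  spatially correlated noise (smoothed white noise, correlation scale 3
  cells) whose generating variance is declared as the surface's variance
  grid. The per-cell error sd is
  $\sqrt{f_m}\,(0.5 + 0.1\,\mathrm{truth})$ µg/m³ — heteroscedastic, as
  real estimation error is in plumes. The method factors $f_m$ (data
  fusion 0.4, kriging 2.5, CTM 8) set the error to roughly 10%, 25% and
  40% of the local concentration, spanning the three regimes of interest:
  CRF-dominant uncertainty with a precise surface, comparable
  contributions, and exposure-dominant uncertainty with a noisy surface.
  A factor of 0 yields a noise-free surface for known-truth tests.
* **Backgrounds.** The ratio pair applies day-consistent multiplicative
  lognormal noise (log-sd 0.1) to the true with/without-fire fields; the
  static baseline is the time-averaged non-fire truth plus a smooth
  1 µg/m³ perturbation, emulating year-to-year drift of ambient levels.
* **Counties, rates, population.** Counties are a contiguous
  nearest-seed partition. Annual admission rates per 100,000 are drawn
  log-uniformly within respiratory 800–4000, cardiovascular 1000–5000,
  asthma 40–400 — spanning roughly an order of magnitude around plausible
  county rates. Population lives in census-tract-like units (~0.4 per
  cell) clustered around a few dense centres with ~30% scattered rural
  tracts, totalling ~3 million — metro-region scale, so admission totals
  land in the tens-to-hundreds like a real episode. Tract populations
  are split across covered cells in whole persons, so grid totals match
  table totals exactly.

What the generator does **not** emulate: AOD retrieval, kriging
internals, bias correction, plume chemistry, evacuation, or any spatial
covariance structure of real estimation errors beyond a single smoothing
scale (the spatial correlation length of the noise is a free parameter of
the generator, not an inference about any real surface). Tests passing on
synthetic data therefore demonstrate the *pipeline's* correctness and the
qualitative uncertainty structure, not the accuracy of any real-world
exposure product.

## Numerical choices and degenerate inputs

* Rounding for presentation is half-away-from-zero (`round_half_up`):
  whole admissions, one decimal for county shares, whole percent for
  change summaries. Full precision is retained internally and in all
  returned objects.
* Negative point estimates (RR < 1 subgroups) are reported, not clamped.
* Ties in county rankings break by county id.
* Zero-variance cells sample degenerately at their mean; an all-zero
  population rejects population-weighted statistics with a clear error.
* All generators derive independent sub-streams from the scenario seed
  and restore the caller's RNG state, so outputs are pure functions of
  the spec and never perturb the session.

## Problem sizes used in the tests

The default scenario (40 × 40 × 13, ~3 M people) runs the full
100,000-draw Monte Carlo in well under a minute thanks to the compiled
inner loop; the test suite exercises it at full draw count for the
degenerate-collapse, source-nesting and decomposition properties, and
uses 10 × 10 × 5 instances for the bit-exact scalar-loop oracle
comparisons. The acceptance script runs the base case and decomposition
at 100,000 draws and the 11-row sensitivity matrix at 50,000.

## Known limitations

* The two clamp orders are both available but only the default is used
  in the shipped analyses; on data where concentrations hover near the
  background the choice matters.
* The comonotonic exposure-sampling default is a modelling decision, not
  an estimated spatial error model; real error fields have partial
  correlation, so true regional CIs lie between the independent and
  comonotonic extremes.
* County-level rates are assumed homogeneous within counties, and the
  /365 daily-rate conversion ignores admission seasonality.
* No mortality endpoints, no elevated fire-period baselines, and no
  uncertainty on the background surfaces, population, or baseline rates.
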