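---
title: "Reconstructing catch and effort data and standardizing CPUE for a longline fishery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing catch and effort data and standardizing CPUE for a longline fishery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Catch-per-unit-effort (CPUE) — here, fish caught per fishing day per
trip — is the main relative-abundance signal available for many
assessed stocks. For a seasonal bluefin tuna longline fishery where
logbook coverage was negligible before a catch-documentation scheme
came into force, neither the catch (fish numbers) nor the effort
(fishing days) exists directly in the historical record. What does
exist is indirect: market landing weights, port entry/exit logs kept
for security purposes, and high-frequency vessel geolocation from
voyage data recorders. `recatch` implements the chain of
reconstructions that turns those sources into a standardized annual
abundance index, together with a seeded synthetic-fleet generator so
that every stage can be validated against known ground truth — the
real data of fisheries like this one are confidential.

The pipeline has four stages:

1. **Fish numbers from landing weights.** Landing records inside the
   single-fish market range (80–350 kg) define an empirical
   weight-per-fish (WPF) distribution, assuming each such record is one
   fish. For each count $k = 1..50$, $k$ weights are drawn with
   replacement and summed, 10,000 times, giving a simulated
   total-weight band per count. A record with a missing count and
   weight $w$ receives count $k$ with probability proportional to the
   number of simulated $k$-fish totals inside $[w - b/2, w + b/2)$.
2. **Fishing days from vessel tracks.** Hourly vessel-days are
   classified fishing/non-fishing by three criterion families — any
   speed at or below $x$ knots; within-day path length below $x$ km;
   maximum heading change at resampled intervals of at least $x$
   degrees — each tuned by grid search against labelled days, scoring
   with the sum (SSS) and absolute difference (DSS) of sensitivity and
   specificity.
3. **Fishing days from trip logs.** For years without geolocation,
   fishing days are predicted from at-sea days by zero-intercept
   regressions $y = \beta x$ per port × vessel-class group
   ($\hat\beta = \sum xy / \sum x^2$), justified by a sequential ANOVA
   on `fishing ~ at_sea + port + class`.
4. **Delta-lognormal standardization.** Trip-level CPUE is modelled in
   two parts: a binomial model for the probability of a positive catch
   (ZPM) over all trips and a lognormal model for the positive catch
   rate (PCM); year-by-categorical interactions enter as random
   intercepts. The annual index is
   $\hat I_y = \hat p_y \exp(\hat\mu_y + \hat\sigma^2/2)$, the product
   of the ZPM year effect and the bias-corrected back-transform of the
   PCM year least-squares mean; the relative index is scaled to its
   series mean.

Model evaluation follows two stages: AIC/BIC stepwise selection of the
variable set per component, then repeated random-split cross-validation
with stochastic delta predictions, comparing area-separated against
area-combined standardization by the overall $R^2$ (squared Pearson
correlation of observed and predicted CPUE on the held-out set).

## A worked run

```{r}
library(recatch)

cfg <- sim_config(seed = 1)

# stage 1: impute missing fish counts
L <- gen_landings(cfg)
wpf <- build_wpf(L$landings)
choose_wpf_model(wpf)$label # "lognormal" for the default generator
wbc <- simulate_weight_by_count(wpf, n_rep = 10000, seed = 2)
imputed <- assign_fish_counts(L$landings, wbc, seed = 3)

# stage 2: tune and apply the fishing-day criterion
T <- gen_tracks(cfg)
days <- split_days(T$points)
gs <- grid_search(days, T$labels, "direction")
flags <- apply_criterion(days, gs$best)

# stage 3: effort regressions
tr <- gen_trips(cfg)
screened <- trips_to_at_sea_days(tr$trips)

# stage 4: standardization and CV
cp <- gen_cpue(cfg)
std <- standardize_cpue(cp, criterion = "BIC")
std$index
```

## What the generator emulates — and what it does not

The generator's defaults are the study conditions every test runs
under; they are fixed once and are not tuning knobs.

* **Landings.** Counts per record follow a truncated geometric
  favouring $k = 1$ (single-fish landings are the common case in this
  fishery, where the catch is sparse and valuable); per-fish weights
  are lognormal, `meanlog = log(190)`, `sdlog = 0.25`, truncated to
  80–350 kg; 30 % of counts are masked. The lognormal choice mirrors
  the elongated right tail of large-fish weight data; the diagnostic
  `choose_wpf_model()` exists precisely because normal and lognormal
  fits are close on such data and the decision should be made by the
  KS D statistic, not by eye.
* **Tracks.** Fishing days have the longline geometry described by
  onboard observers: a deployment leg at ~5.5 kn on a base heading, a
  soak drift, and a long retrieval leg near the reciprocal heading at
  ~2.2 kn — so every fishing day contains both a slow-speed instance
  and a turn-around. Non-fishing days are either straight transits at
  9 kn (optionally with drift hours and a 25–70° waypoint course
  change) or port arrival/departure days with a short steaming leg and
  hours moored with ~30 m GPS jitter. Real tracks are messier: sea
  current drift, broken gear, partial days and position dropouts are
  not modelled, so a perfect SSS on synthetic days does **not** mean
  the criterion is perfect at sea — only that the implementation ranks
  and scores criteria correctly when the truth is known.
* **Trips.** Fishing days per trip are `slope × at-sea days` plus
  truncated-normal noise (SD 0.5 days), clipped to `[0, at_sea]`. The
  default slopes (0.69–0.83 by port and class) encode a fleet that
  spends roughly two of every ten at-sea days in transit, more from
  the southernmost port. The small noise relative to the slope is what
  makes the zero-intercept regressions fit with $R^2 > 0.9$, as such
  port-log data do.
* **CPUE.** A delta-lognormal process with multiplicative
  year/month/area/class effects; defaults: a declining 8-year trend,
  month effects peaking mid-season, no vessel-class effect (so
  selection should drop the term), `p_zero = 0.35`, `pcm_logsd = 0.6`.
  `year_effects` accepts a `(year, area, effect)` frame and `pcm_logsd`
  an area-named vector to create divergent area dynamics for the
  design-comparison experiments. Catch is carried as
  `cpue × fishing_days` and may be fractional: a continuous catch-rate
  process does not produce integers, and rounding would break the
  exact recovery contracts of the deterministic configurations.

## Numerical and design choices

* **Speed criterion = "≤ x knots".** A literal equality test on a
  continuous speed is measure-zero; slow instances are what signal
  hook retrieval. The comparison is configurable.
* **Direction criterion = "max heading change ≥ x".** The literal
  "change within x degrees" reading would classify a straight transit
  (change ≈ 0°) as fishing. Retrieval requires a turn-around, and a
  large-angle optimum is exactly what a turn detector produces, so the
  detector form is the default; the flipped comparison is available
  for fidelity experiments.
* **Bearings need ≥ 1 km of displacement.** The bearing of a 30-m
  GPS-jitter displacement is noise, not heading; segments below 1 km
  contribute no azimuth. A day with fewer than two usable azimuths
  (e.g. fully moored) is unclassifiable by direction.
* **Within-day distance = cumulative path length**, not net
  displacement: an out-and-back fishing day has near-zero displacement
  but a real path, and "moving distance within a day" reads as path.
* **Day boundary at local midnight (UTC+8), ≥ 3 points to classify.**
  The fishery operates in a single time zone.
* **Grid-search ties.** Cells within 0.01 SSS of the maximum are tied
  and resolved by minimum DSS, operationalizing "similar SSS".
* **Weight bands are 10-kg bins** of simulated totals; the band plot's
  bin width is not stated anywhere authoritative, so it is a
  configurable parameter with a default on the scale of market
  rounding. Count sampling uses the empirical WPF distribution
  (bootstrap), not the fitted lognormal — the fitted model serves only
  the normal-vs-lognormal diagnostic. Records below one minimum fish
  or without simulated support in their bin are flagged
  `unassignable`, never silently dropped.
* **Trip screening** drops inverted intervals, durations over 60 days,
  and overlapping trips per vessel; the cap and overlap rule are this
  package's substitute for unstated "screened for accuracy" rules.
  At-sea days are calendar dates intersected, matching port-log
  granularity.
* **Both R² conventions are reported** for the zero-intercept fits:
  the uncentered version ($1 - SSE/\sum y^2$) that the zero-intercept
  model implies — and which overstates fit — and the centered one.
  The uncentered value is never below the centered one.
* **Bias correction defaults to $\exp(\sigma^2/2)$** with the PCM
  residual variance. Finite-sample corrections exist, but the simple
  lognormal-mean correction is the transparent default; confidence
  limits combine the LSmean variance and the binomial component by the
  delta method on the log scale.
* **LSmeans weighting**: year predictions are averaged over the other
  factor levels with weights proportional to those levels' observation
  counts, the same margins for every year (`emmeans`,
  `weights = "proportional"`), so unbalanced sampling does not leak
  into the year contrast.
* **Selection under ML, final mixed PCM refit by REML.**
  Likelihood-based criteria are not comparable across REML fits with
  different fixed effects, so stepwise comparisons use ML throughout
  and only the final reported PCM is refit by restricted likelihood.
  Nonconvergent candidates are skipped with a message, never silently
  accepted.
* **Cross-validation** splits 50/50 (the split fraction is not dictated
  by anything stronger than symmetry), stratified over
  year × month × area × class; intervals over replicates are
  percentile-based. Each replicate refits the *fixed-effect* final
  formulations (glm/lm): the design comparison needs the systematic
  part of each design, and refitting random-interaction GLMMs hundreds
  of times adds cost and convergence fragility without changing the
  ranking question. One uniform draw per validation record decides the
  zero/positive indicator, seeded per replicate.

## Problem sizes

The validation suite uses 500 vessel-days for classifier tuning,
5,000 trips for effort-slope recovery, 10,000 trips for
standardization recovery, and 20 seeds × 50 replicates for the
cross-validated design comparison; these sizes give comfortable
sampling margins for every tolerance asserted while keeping a full run
on one CPU in minutes.

## Known limitations

* The generator's track geometry is cleaner than real voyage-recorder
  data; classifier scores on synthetic days are upper bounds.
* The imputation validates totals, not record-level counts; with a
  contaminated WPF sample (multi-fish records that fall inside the
  single-fish range — an assumption the method itself makes) a small
  negative bias in totals is expected and observed (≈ 1–2 % at the
  defaults).
* The standardization assumes lognormal positive catches; count-based
  alternatives (zero-inflated Poisson/negative binomial) are out of
  scope, as is any downstream stock-assessment modelling.
* Area assignment for years without geolocation is a port proxy and is
  only as good as the port–ground association it encodes.
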