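# recatch

Catch and effort data reconstruction and CPUE standardization for
longline fisheries.

## What this solves, and for whom

Stock assessments of seasonal longline targets (the motivating case is
a Pacific bluefin tuna fleet) hinge on a catch-per-unit-effort (CPUE)
index — fish per fishing day per trip — yet for many fleets the
historical record contains neither fish numbers nor fishing days.
`recatch` is aimed at quantitative fisheries scientists who must
rebuild both from indirect sources and defend the result:

1. **Fish numbers from landing weights** (Monte Carlo): records inside
   the single-fish range (80–350 kg) form an empirical weight-per-fish
   (WPF) distribution; sums of *k* draws (10,000 replicates per *k* =
   1..50) give weight bands per count, and a missing count is sampled
   with probability proportional to the simulated band frequencies in
   the record's 10-kg weight bin. Normal vs lognormal WPF families are
   compared by the two-sample Kolmogorov–Smirnov *D*.
2. **Fishing days from hourly vessel tracks**: vessel-days are
   classified by three criterion families — any speed ≤ *x* kn,
   within-day path length < *x* km, or maximum heading change ≥ *x*°
   at an *h*-hour resampling — scored against labelled days with
   SSS = TPR + TNR (larger is better) and DSS = |TPR − TNR| (smaller
   breaks ties), and tuned by grid search.
3. **Fishing days from port logs**: zero-intercept regressions
   `fishing = β · at_sea` per port × vessel class
   (β̂ = Σxy / Σx², both centered and uncentered R² reported), with a
   sequential ANOVA, predict effort for years with no geolocation.
4. **Delta-lognormal standardization**: a binomial model for the
   probability of a positive catch (ZPM) and a lognormal model for the
   positive catch rate (PCM), with year × month / year × class random
   interactions, AIC/BIC stepwise selection, observation-weighted year
   LSmeans, and the bias-corrected annual index
   `I_y = p_y · exp(μ_y + σ²/2)`, plus repeated-split cross-validation
   comparing area-separated vs area-combined designs by overall R².

Because data of this kind are confidential, the package ships a seeded
synthetic-fleet generator (`sim_config()`, `gen_landings()`,
`gen_tracks()`, `gen_trips()`, `gen_cpue()`) that emulates the fishery
with known ground truth; every stage is validated against it.

## Worked example

```r
library(recatch)
cfg <- sim_config(seed = 1)

## fish numbers from landing weights
L   <- gen_landings(cfg)            # 500 records, 30% counts masked
wpf <- build_wpf(L$landings)
#> <wpf_sample> 294 fish in [80, 350] kg; mean 213.4, sd 62.7
choose_wpf_model(wpf, seed = 2)$label
#> "lognormal"   (KS D 0.048 vs 0.109 for the normal fit)
wbc <- simulate_weight_by_count(wpf, n_rep = 10000, seed = 2)
imp <- assign_fish_counts(L$landings, wbc, seed = 3)
#> imputed 179 records; estimated total 1026 vs true 1033 (-0.7%)

## fishing-day criterion from labelled tracks
T    <- gen_tracks(cfg)
days <- split_days(T$points)
grid_search(days, T$labels, "direction")$best
#> direction-change >= 70 deg, SSS 2.000, DSS 0.000
#> (speed and distance optima on the same fleet: SSS 1.29 and 1.47)

## standardized index
std <- standardize_cpue(gen_cpue(cfg), criterion = "BIC")
std$index
#>  year p_pos index relative_index
#>  2001 0.685 0.694          1.374
#>  2002 0.702 0.735          1.456
#>  ...
#>  2008 0.632 0.303          0.600
```

The imputation recovers the masked annual fish total to within a
percent; the turn-detecting direction criterion dominates the speed
and distance rules (slow drift hours and short port days fool those,
as they do in real fleets); and the relative index tracks the
generator's declining year-effect series (r ≈ 0.98 at 10⁴ trips), with
`p_pos` hovering at the generating positive-trip probability 0.65.

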