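# antbridge

Stochastic models and analyses of self-assembled army ant bridges.

Army ants (*Eciton hamatum*) build living bridges across gaps in their
foraging trails. When the terrain under a bridge shifts — the gap growing
by 1 mm every 30 s up to 30 mm, then shrinking back — the structure adjusts
through individual decisions to join or leave, and does so hysteretically:
at a given gap size, bridges hold more ants while the gap contracts than
while it expands. `antbridge` implements the computational side of studying
this control problem, for behavioural ecologists and collective-behaviour
modellers:

* **Three discrete-time event models** of the ant count `N(t)` over 30-s
  gap intervals, with joining/leaving counts drawn from negative binomial
  distributions (mean µ, dispersion θ, variance µ + µ²/θ):
  * *baseline* — fixed per-phase rates;
  * *delay* — leave decisions execute `d` intervals after being drawn,
    with delay-consistent refits of the leaving distributions;
  * *accumulator* — rates log-linear in the deficit
    `Δ(t) = ρ* g(t) − N(t)` from the equilibrium packing density
    `ρ* = 0.51` ants/mm: stretched bridges recruit, slack bridges shed.
* **Fitting procedures** that ground the models in per-interval event
  data: per-trial NB maximum likelihood with across-trial medians,
  logistic regressions locating the equilibrium packing density, and NB
  regressions of counts on the deficit.
* **A hysteresis-extent statistic**: the area between LOESS-smoothed
  expansion and contraction response curves, normalized by the larger area
  under a curve — a signed, unitless proportion in [−1, 1], negative when
  the expansion curve dominates — plus the across-trial t-test.
* **Resampling tests of individual cues**: whether bridge performance
  (optical-flow residuals) or tautness in the seconds before
  joining/leaving events differs from a 10,000-draw permutation null.
* **A synthetic trial generator** emulating the field data streams
  (structural metrics, event times, optical flow, broken periods) so the
  entire pipeline is testable end to end.

## Worked example

Simulate the baseline model at the field-estimated parameters and measure
its hysteresis:

```r
library(antbridge)

eciton_event_params()
#> # A tibble: 4 × 4
#>   phase       kind     mu theta
#>   <chr>       <chr> <dbl> <dbl>
#> 1 expansion   join   1.13  1.33
#> 2 expansion   leave  0.67  1.98
#> 3 contraction join   0.33  0.65
#> 4 contraction leave  1.04  8.1

ex <- run_experiment(baseline_model(), build_schedule(),
                     n_sims = 10000, seed = 1, keep_trajectories = FALSE)
ex
#> <bridge_experiment: baseline model, 10000 simulations, 61 intervals>
#>   mean extent of hysteresis: -0.239 (66.0% negative)
```

The mean extent of −0.24 says the baseline model's bridges are, on
average, *larger during expansion than contraction* — hysteresis opposite
in direction to real bridges, which show positive extents. The
accumulator model flips the sign:

```r
acc <- run_experiment(eciton_accumulator_model(), build_schedule(),
                      n_sims = 10000, seed = 2, keep_trajectories = FALSE)
round(glance(acc)[c("mean_extent", "frac_positive")], 3)
#> # A tibble: 1 × 2
#>   mean_extent frac_positive
#>         <dbl>         <dbl>
#> 1       0.476         0.906
```

and, unlike the linear models, stays stable when the gap vibrates by 1 mm:

```r
vib <- run_experiment(baseline_model(), build_schedule("vibration"),
                      n_sims = 1000, seed = 2, compute_extents = FALSE)
vib
#> <bridge_experiment: baseline model, 1000 simulations, 121 intervals>
#>   vibration (60 intervals): 83.0% extreme, 40.0% reached zero
```

(an "extreme" run leaves the 5–25 ant band at some point during the
vibration block; about 40% of baseline bridges fail outright.)

The full pipeline runs on synthetic trials:

```r
ds  <- generate_dataset(synth_config(seed = 1))        # ten trials
fit <- fit_deficit_regression(ds$trials, rho_star = 0.51, kind = "join")
glance(fit)
r   <- resample_null(ds$trials, kind = "join", phase = "expansion",
                     n_resamples = 10000, seed = 3)
autoplot(r)
```

See `vignette("antbridge-methods")` for the models, their assumptions and
every tunable parameter.

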