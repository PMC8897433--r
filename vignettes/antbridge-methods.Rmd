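---
title: "Models and methods for dynamically controlled ant bridges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dynamically controlled ant bridges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antbridge)
```

Army ants (*Eciton hamatum*) self-assemble living bridges across gaps in
their foraging trails. When the gap under a bridge is repeatedly stretched
and shrunk — 1 mm every 30 s up to 30 mm and back in the field protocol this
package models — the structures adjust by individual ants joining and
leaving. The adjustment is hysteretic: at the same gap size, bridges hold
more ants while the gap is contracting than while it is expanding. This
vignette describes the stochastic models, estimators and resampling tests
the package implements, the choices made where the methods were genuinely
open, and what the synthetic data generator can and cannot stand in for.

## The discrete-time event models

All three models share a skeleton. Time advances in *gap intervals* — the
30-s periods between 1-mm gap adjustments. At each interval the number of
joining events $J(t)$ and leaving events $L(t)$ are drawn from negative
binomial (NB) distributions, and the bridge state updates as
$N(t+1) = N(t) + J(t) - L(t)$, starting from $N(0) = 0$ at gap 0. Counts are
NB rather than Poisson because the field event data are overdispersed; the
package fixes the ecology parameterization (mean $\mu$, dispersion
$\theta$, variance $\mu + \mu^2/\theta$) everywhere. Leaving is clamped so
the bridge never holds a negative number of ants. Traffic is not an
explicit state variable.

**Baseline** (`baseline_model()`): fixed probabilities per phase. Each of
the four (kind × phase) distributions has its own $(\mu, \theta)$. The
field-estimated set ships as `eciton_event_params()`: joins dominate during
expansion ($\mu = 1.13$ vs $0.67$, net $+0.46$ ants per interval) and
leaves dominate during contraction ($0.33$ vs $1.04$, net $-0.71$). The
asymmetry between $+0.46$ and $-0.71$ is what drives this model's
*negative* hysteresis — opposite in sign to real bridges.

**Delay** (`delay_model()`): as baseline, but leave *decisions* drawn at
interval $t$ execute at $t + d$, $d \in \{1,\dots,6\}$. If real ants
delayed leaving, events recorded early in the contraction would reflect
expansion-phase decisions, so the leaving distributions must be refit after
reassigning the first $d$ contraction intervals' leaves to the expansion
(`apply_delay_reassignment()`); `delay_model()` refuses parameter sets refit
for a different $d$. The decision queue starts empty — there are no phantom
pre-trial decisions.

**Accumulator** (`accumulator_model()`): dynamic probabilities driven by
the deficit
$$\Delta(t) = \rho^* g(t) - N(t),$$
the difference between the equilibrium ant count for the current gap
$g(t)$ and the actual count at the start of the interval. The equilibrium
packing density $\rho^* = 0.51$ ants/mm is the density at which joining and
leaving are equally probable per interval. Expected counts are log-linear
in the deficit, $\mu_{\text{join}}(\Delta) = e^{\alpha_j + \beta_j\Delta}$
with $\beta_j = 0.049$ and $\mu_{\text{leave}}(\Delta) =
e^{\alpha_l + \beta_l\Delta}$ with $\beta_l = -0.067$: a stretched bridge
(positive deficit) recruits and retains, a slack one sheds. The model is
self-correcting — an overshoot in leaving raises the deficit and suppresses
further leaving — which is what lets it ignore 1-mm vibrations while still
tracking lasting shifts.

### Within-interval ordering and clamping

Only the non-negativity constraint is inherent to the system; how to order
joins and leaves within an interval is an implementation choice. The
default applies joins first and clamps executed leaves at
$N(t) + J(t)$, the least restrictive rule consistent with non-negativity; a
stricter `clamp = "start"` variant caps leaves at $N(t)$ alone. Both the
raw draws and the executed counts are recorded in every trajectory
(`joins_drawn`, `leaves_drawn` vs `joins`, `leaves`), so either rule can be
replayed from a saved run.

### Vibration intervals

The vibration protocol alternates the gap between 29 and 30 mm between the
expansion and contraction phases. The linear models are defined only per
phase, so vibration intervals borrow contraction parameters when the gap
just decreased and expansion parameters when it increased — the reading
under which every 1-mm shift is equally likely to provoke a response. The
accumulator needs no such mapping; it responds to the deficit alone. The
duration of the vibration phase is not pinned down by the field protocol;
the package defaults to 60 intervals (30 min), and the acceptance checks
also probe longer phases to confirm the qualitative picture (fragility of
the linear models) is not an artifact of that choice.

### Scalability and rate protocols

`build_schedule()` also covers the scalability and rate-sensitivity
designs: a larger `max_gap` (30, 60, 90 mm) scales the protocol while
keeping 1-mm steps, and the rate of gap change is varied through `step`
(mm per interval) with the models' per-interval semantics held fixed,
since all three models are defined per gap interval. Changing the
`interval` duration instead varies the real-time rate while leaving the
event distributions untouched — the two knobs make either reading of "rate"
available.

## Parameter estimation

`fit_nb_counts()` reproduces the estimation pipeline for the linear models:
per-trial maximum-likelihood NB fits of per-interval event counts (the mean
MLE is the sample mean; $\theta$ is the profile MLE via `MASS::theta.ml`),
then the across-trial *median* of $\mu$ and $\theta$. Medians make the
estimate robust to the occasional degenerate trial; a trial whose counts
are all zero carries no information about $\theta$ and is dropped from the
dispersion median with a warning. Underdispersed samples push $\theta$
towards the Poisson boundary and are capped at $10^6$. Intervals
overlapping a broken-bridge period are excluded everywhere, and a trial
broken for most of its duration is excluded entirely, mirroring the field
analysis.

`estimate_equilibrium_density()` fits two binomial GLMs of per-interval
event *occurrence* (at least one event, not the count) on packing density
$\rho = N/g$, excluding zero-gap intervals where density is undefined, and
solves for the density at which the two fitted probabilities cross. Because
both logits are linear in $\rho$, the crossing is found by root-solving the
difference of linear predictors, bracketed in the observed density range;
the solver tolerance keeps $|p_{\text{join}}(\rho^*) -
p_{\text{leave}}(\rho^*)|$ below $10^{-6}$.

`fit_deficit_regression()` fits the accumulator's NB regressions of counts
on the deficit with `MASS::glm.nb`, one global $\theta$ per kind.
Constancy of the dispersion across deficits is an assumption; the
`deficit_dispersion_profile()` diagnostic bins Pearson residuals by deficit
so it can be checked. The equilibrium count $\rho^* g$ is kept real-valued
— deficits need not be integers.

### The unprinted accumulator intercepts

The published parameter set pins down the deficit-regression slopes and
dispersions but not the intercepts $\alpha_j, \alpha_l$; these must come
from data. When only the per-phase mean rates are available,
`derive_deficit_intercepts()` closes the gap by moment matching: writing
each phase mean as the rate at a typical phase lag,
$\mu^{\text{exp}} = e^{\alpha + \beta \bar\Delta_e}$ and
$\mu^{\text{con}} = e^{\alpha + \beta \bar\Delta_c}$, and assuming the lags
are symmetric about equilibrium ($\bar\Delta_e + \bar\Delta_c = 0$), the
least-squares solution is $\alpha = \tfrac12(\log\mu^{\text{exp}} +
\log\mu^{\text{con}})$ — the log geometric mean of the two phase rates, per
kind. The symmetry assumption is the weak link: the four phase means
overdetermine the two lags and disagree about their magnitude, so the
*scale* of the intercepts (how busy the bridge is overall, and hence how
tightly it tracks $\rho^* g$) is genuinely unidentifiable from phase means
alone. Statistics that depend mostly on the *shape* of the response (the
hysteresis extent, the sign composition) are robust to this; statistics
that depend on the absolute ant count — most visibly the fraction of
vibration-phase bridges staying inside a fixed 5–25 ant band — are not,
and should be read accordingly wherever the intercepts were derived rather
than fitted. `eciton_accumulator_model()` bundles the derived intercepts
with the published slopes; fitting $\alpha$ from per-interval data with
`fit_deficit_regression()` is always preferable when event records are
available.

## The extent of hysteresis

For one trial or simulation, `smooth_phase_curves()` fits a LOESS local
regression of the response metric (ant count, volume, cross-section,
tautness) on gap size separately per phase and evaluates both fits on a
common grid covering only gaps observed in both phases; gaps visited in a
single phase contribute nothing. `extent_of_hysteresis()` then computes

$$\text{extent} = \pm\,
\frac{\int |c(g) - e(g)|\, dg}{\max\left(\int e(g)\,dg, \int c(g)\,dg\right)},$$

the area between the curves normalized by the area under the higher curve —
a unitless proportion in $[-1, 1]$, negative when the expansion curve is
the larger one. Integrals are trapezoidal on the grid. If both curves
enclose zero area the extent is undefined and returned as `NA` with a
reason rather than a number. The statistic is scale-invariant
(multiplying the metric by $k > 0$ changes nothing), which is what makes
extents comparable across metrics with different units.

Numerical choices: LOESS span 0.75, degree 2, grid spacing 0.5 mm. The
span is not dictated by the method's definition, so it is exposed as an
argument; the simulation reproduction checks run at two spans (0.75 and
0.5) to confirm the headline statistics do not hinge on it. Simulated
trajectories have one value per integer gap per phase; they are smoothed
through the same pipeline for comparability, with an unsmoothed
interpolating variant (`hysteresis_extent(..., smooth = FALSE)`) available.

`hysteresis_ttest()` is the across-trial one-sample, two-tailed $t$-test of
per-trial extents against zero.

## Individual cues: performance and tautness

Bridge *performance* is the signed residual of bridge optical flow from a
per-trial least-squares regression on adjacent-platform optical flow, so
that overall traffic fluctuations cancel. The field description of the
regression ("bridge flow on the flow of both platforms") is compatible with
one pooled predictor or two covariates; the package defaults to the summed
platform flows and offers `predictor = "both"`, asserting neither as
canonical.

`resample_null()` asks whether the cue in the `window` seconds before
events differs from chance: the observed mean pre-event cue is compared
with 10,000 pseudo-experiments in which event times are redrawn uniformly —
without replacement, within each trial and phase, keeping per-trial event
counts fixed — from the non-broken seconds of that phase. Phases are
analyzed separately to remove phase as a confound. Significance follows
the central-95% rule (observed outside the null's 2.5–97.5% quantiles);
the two-tailed $p$ is twice the smaller tail fraction, clipped at 1.
Performance values are attached to seconds by inheritance from their 10-s
flow interval; an event's window is the whole seconds preceding it, and
events whose window touches a broken period are dropped, matching the
global exclusion rule. Drawing without replacement prevents two resampled
events from colliding on one second. `window_sensitivity()` repeats the
test across window lengths, and `event_timing_uniformity()` checks the
premise that events are uniform within gap intervals via a
Kolmogorov–Smirnov distance.

## The synthetic trial generator

`generate_trial()` exists so the whole pipeline — fitting, hysteresis,
cue analysis — can be exercised end to end with no external download. It
simulates a configured bridge model over the schedule, scatters each
interval's events at uniform within-interval offsets, and derives the
three data streams of a field trial from the resulting ant-count series:

* **Structural**: volume is $v$ mm³ per ant (default 57, consistent with
  bridges of roughly a thousand mm³ at around 19 ants) plus Gaussian noise
  whose sd is solved from a target volume–ant correlation (default 0.93,
  the midpoint of the observed 0.88–0.98 range); infeasible targets are
  rejected with the feasible range. Tautness decreases linearly in the
  excess of ants plus noise — a deliberately minimal monotone model,
  sufficient to test the tautness resampler without asserting mechanics
  the field study declined to fit. Cross-section is volume over the
  (floored) gap.
* **Flow**: AR(1) platform traffic, bridge flow linear in the summed
  platform flows plus residual noise. A configurable elevation is added to
  bridge flow in the window before each joining event (default on,
  mirroring the joining cue found in the field); a pre-leave tautness
  depression is available and off by default (none was found).
* **Broken periods**: Poisson number per trial (default 0.8), uniform
  20–60 s durations — brief, as in the field where longer outages ended a
  trial.

Real trials balance joining and leaving totals because every bridge starts
and ends empty; a simulation may end with ants still in place, so the
generator appends a forced disassembly tail (one leave per second) after
the schedule and flags those seconds broken, which keeps the balance
invariant while excluding the tail from every statistic. The default
generating model is the accumulator — the model the field data support —
so the default dataset behaves like hysteretic real trials.

What the generator does *not* emulate: bridge breaks have no structural
signature (volume spikes) beyond the flag; tautness has no spatial or
mechanical structure; traffic does not feed back on joining beyond the
injected cue; and event counts inherit whatever lack of fit the generating
model has. Tests passing on synthetic data therefore validate the
*estimators and statistics*, not the models' fidelity to real colonies.

## Problem sizes and reproducibility

The reproduction checks use the study-scale designs: 10,000 simulations
for the expansion–contraction experiments, 1,000 for vibration, 10
synthetic trials for trial-level statistics, and 10,000 resamples for cue
tests (reduced in unit tests where only correctness, not precision, is at
stake). Every stochastic entry point takes a seed; identical (seed, model,
schedule) triples give bit-identical trajectories, and the generator is
byte-identical under a fixed configuration.

## Known limitations

* The accumulator intercepts derived from phase means inherit the symmetry
  assumption above; absolute-count statistics under derived intercepts are
  indicative only.
* LOESS behaviour at the support edges can leak small negative values into
  smoothed count curves; areas are integrated as-is rather than clipped.
* The extent statistic's $[-1, 1]$ bound is guaranteed for curves that do
  not cross; strongly crossing curves (rare in practice) can exceed it,
  and the sign convention then reflects total areas only.
* Vibration-phase parameter mapping for the linear models is a modelling
  extension, not a fitted behaviour; it is configurable but untestable
  against field data that contain no vibration phases.
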