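---
title: "Model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmodrift)
```

`salmodrift` is an hourly individual-based model of juvenile Atlantic
salmon (*Salmo salar*) and brown trout (*Salmo trutta*) in a lowland chalk
stream, built to ask how habitat selection behaviour shapes growth and
distribution when the flow regime changes. This vignette is the package's
account of the model: the structure and the equations, the parameters that
matter, what the synthetic environment emulates (and deliberately does
not), the numerical choices, and the design decisions that were genuinely
open.

## The virtual stream

Space is hierarchical. **Global** state — hour of day, daylight flag,
water temperature (°C) and discharge (m³·s⁻¹) — applies everywhere.
**Stretches** (~80 m) carry drift prey densities in ten categories (five
length classes, 1–3 to 9–12 mm, by aquatic vs. terrestrial origin) and
pike densities in two gape classes (*small*, fork length < 220 mm;
*large*, > 396 mm). **Patches** (~40 m²) form a single linear chain; each
has an area, a flowing fraction (vs. slack water), and rectangular-channel
hydraulic geometry.

Field-style inputs are sparse: per-day global samples, roughly monthly
invertebrate samples, seasonal vegetation cover. `prepare_environment()`
turns them into hourly series by linear interpolation between samples,
holding the nearest endpoint outside the sampled range (linear
extrapolation could go negative). Between-day prey bases are evaluated at
the integer calendar day, so they are flat within a day; aquatic
categories are additionally modulated by a within-day profile that is
piecewise linear through multiplicative anchors at dawn, midday and dusk,
with the dusk value held overnight. The anchor shape (default 1.6 / 0.7 /
1.7) encodes the classic crepuscular drift peak; terrestrial input has no
diel structure. Daylight uses a half-open `[sunrise, sunset)` convention.

Patch depth and velocity come from a quasi-1-D Manning uniform-flow
balance per patch: `Q = w·d·v` with `v = d^(2/3)·sqrt(S)/n_eff` and
vegetation-scaled roughness `n_eff = n_base·(1 + k_veg·cover)`, so
seasonal *Ranunculus* growth slows and deepens the flow. For a rectangular
channel this has the closed-form root `d = (Q·n_eff/(w·sqrt(S)))^(3/5)`;
the test suite checks it against an independent bisection solver and
verifies continuity to 1 part in 10⁶. A `k_slack` coefficient can couple
vegetation to the flowing fraction; it defaults to 0.

## The fish

A fish carries species, cohort (YOY or 1+), fork length, wet mass, a fixed
feeding territory size, a tagged flag, and its patch. Everything else is
derived per hour.

**Drift feeding.** A feeding fish holds station and intercepts prey
crossing a square capture window. Reaction distance is
`RD = α·FL·(1 + β·m)` for prey midpoint `m`; the window side is
`min(2·RD, depth, width/n_fish)` so it never exceeds the wetted
cross-section or the fish's share of the channel. Encounter rate is the
drift flux `density·v·CA·3600`; capture success declines with velocity,
`PCS = clip(1 − γ·v/Vmax, 0, 1)`; handling time is a pursuit at maximum
swimming speed plus a return with the current,
`HT = RD/(Vmax − v) + RD/max(v, v_floor)`, infinite when the current
outruns the fish. Per category the capture rate is
`min(RE·PCS, 3600/HT)`; summing `CR·drymass·energy` over the gape window
(`midpoint ∈ [δ_min·FL, δ_max·FL]`) gives the *potential* hourly intake.
Prey are not depleted by feeding: drift densities are exogenous at the
stretch scale, consistent with the productivity of chalk streams.

**Bioenergetics.** Gross intake is clamped at the physiological maximum
`Cmax = a_C·M^b_C·φ(T)` with a piecewise-linear thermal response anchored
at `T_low`, `T_opt`, `T_high`. A constant 31% of gross intake is lost to
faeces and urea. Costs are standard respiration
`Rs = a_R·M^b_R·e^(c_R·T)`, a convex swimming cost `a_S·M^b_S·speed²`
with speed equal to the patch velocity while feeding and half of it while
resting, and a digestion cost (SDA) proportional to intake; the total is
capped at `Rmax = rmax_mult·Rs`. Growth is net energy divided by the
fish's energy density (`ΔM = (0.69·GEI − R)/ε`), fork length follows the
inverted length–mass relation and never shrinks, and a fish whose mass
falls below 1 g is removed. The per-step identity
`ΔM·ε = 0.69·GEI − R` is asserted exactly (to float tolerance) in the
tests — the model cannot leak energy.

**Time allocation.** Within an hour a fish feeds a fraction `f` and rests
the remainder, choosing the `f` that maximises that step's net energy.
Because intake is clamped, the optimum is analytic: feed up to
`f* = min(1, Cmax/potential)` when the marginal gain
`(1 − loss − sda)·potential − (SC_feed − SC_rest)` is positive, otherwise
rest. A grid-search oracle in the tests confirms the closed form.

**Territories.** A patch's available feeding area (AFA) is its flowing
area minus the territories of fish already feeding there. Feeding requires
daylight, flowing water, and `AFA ≥ TS`; a fish that cannot establish a
territory may still occupy the patch but only rest. Fish are processed
sequentially — all 1+ fish (size-dominant) in random order, then all YOY
in random order — and each fish sees the choices already committed this
step, so first-comers hold the space.

## Habitat selection

Each daylight hour a fish evaluates its patch and the immediate up- and
downstream neighbours (one patch-distance of movement per step) under one
of four rules:

* **RANDOM** — uniform over the candidates.
* **MCR** — maximise the consumption rate.
* **MPR** — minimise the patch predator:prey ratio (gape-applicable pike
  count divided by the fish count including the evaluator).
* **CR>PR** — if any candidate's consumption reaches Cmax, take the
  lowest-ratio candidate among those; otherwise behave like MCR.

Two design choices here were genuinely open and matter:

1. *The MCR score is the uncapped potential intake*, not the Cmax-capped
   realised intake (with feasibility honoured: an unfeedable patch scores
   0). A capped score would tie at Cmax across all rich patches, reducing
   MCR to a random walk and erasing its signature: MCR fish sit in
   higher-potential patches and therefore reach their consumption ceiling
   in less feeding time than CR>PR fish.
2. *CR>PR breaks ratio ties by consumption first*, then uniformly at
   random. Pure random ratio tie-breaking would make the rule behave
   randomly wherever predators are absent — contradicting its
   consumption-prioritising definition — and it is what makes CR>PR
   collapse onto MCR *bit-exactly* (same RNG draws) when predator
   densities are zero everywhere, a property the test suite asserts on
   whole trajectories.

All remaining exact score ties break uniformly at random. At night fish
rest in place: they are obligate diurnal feeders, every rule's consumption
score would be identically zero, and hourly nocturnal tie-breaking would
amount to an unintended random walk.

## Scheduling, randomness, observation

Each step updates global → stretch → patch state, then processes foragers
(selection, time allocation, intake, respiration, growth) sequentially;
deaths are applied at the end of the step. A master seed deterministically
spawns one child seed per replicate for initialisation and one for the
step loop, so outputs are a pure function of the configuration and adding
observation steps never perturbs trajectories. Surveys record end-of-step
state into fish/patch snapshot tables at configurable steps, mirroring
electric-fishing and PIT-tracking occasions; `generate_observations()`
thins tagged-fish records with independent detection (default 45%,
imitating portable-detector inefficiency) to produce observation tables in
the same schema.

## The synthetic chalk stream

`synth_spec()` defaults emulate the study conditions: 7 stretches, 75
patches (areas 39.6 ± 14.15 m², truncated at 8 m²), a 68-day natural-flow
period at ~1.8 m³·s⁻¹ followed by a 17-day experimental drawdown, summer
temperatures declining 17.5 → 13.8 °C, daylight contracting from ~16 to
~11 h, monthly prey sampling, seasonal vegetation peaking mid-run. The
initial population (12 YOY salmon, 4 YOY trout and 2 1+ trout per stretch,
about half tagged; masses 3.5 ± 1, 5 ± 1.5 and 30 ± 8 g) is a scaled-down
plausible population chosen so the default four-rule, five-replicate
experiment runs in a few minutes on one CPU; the tests and the acceptance
script state the sizes they use.

Four generator choices place the system in the intended regime, and were
made once as part of parameterisation:

* **Drift densities** default to measured-drift magnitudes (aquatic base
  5/2.5/1.2/0.5/0.25 prey·m⁻³ by size class, terrestrial a fifth of
  that). Together with `rd_alpha = 0.001` this puts potential intake in
  good natural-flow patches at roughly 2–4 × Cmax: prey is not limiting,
  fish feed a sub-unit fraction of daylight, and intake is
  consumption-capped — but marginal patches exist.
* **About 35% of patches are slack** (flowing fraction 0). Feeding is
  impossible there, which is what makes undirected movement costly.
* **Pike occupy ~3 of 7 stretches.** Pike are lentic ambush predators and
  patchy at this scale; in pike-free stretches every predator:prey ratio
  ties at zero, so pure risk minimisation degenerates into a random walk —
  the mechanism behind MPR fish losing weight.
* **The drawdown is severe (0.2 m³·s⁻¹).** Shallower, slower water
  shrinks capture windows until some patches fall below Cmax; growth then
  depends on where a fish is, which is what raises the spread of growth
  rates in the low-flow period relative to natural flow.

What the generator does *not* emulate: measured field series (the real
environment data are not reconstructable from summary statistics), benthic
feeding, prey depletion, turbidity, 2-D hydraulics, immigration,
reproduction, nocturnal foraging, aggression costs, overwintering or
smoltification energetics, or prey-density-dependent territory size.
Passing tests on this environment show the behavioural and bioenergetic
machinery reproduces the *qualitative* contrasts (which rules grow, which
starve, how feeding time and growth-rate spread respond to the drawdown) —
not that the package reproduces any particular field measurement.

## Species parameters

All coefficients live in `species_params_default()` (one row per
species × cohort) and can be edited or read from file. The defaults are
round literature-magnitude values for juvenile salmonids, chosen once:
consumption `a_C = 0.11, b_C = 0.75` (kJ·h⁻¹ at the 16 °C optimum; a
~30% body-mass daily maximum ration for a 3.5 g parr), standard
respiration `a_R = 0.006, b_R = 0.8, c_R = 0.07`, swimming cost
`a_S = 0.1` with a squared speed law, SDA 0.14, losses 0.31, energy
density 5.9–6.0 kJ·g⁻¹ wet, length–mass `M = 10⁻⁵·FL³`, territories
0.25–0.3 m² (YOY) and 1.4 m² (1+) from the territory–size allometry,
`Vmax` of 12 body lengths·s⁻¹, gape window `[0.015·FL, 0.12·FL]`. Under
these values a YOY salmon feeding to Cmax through a natural-flow summer
day grows ~1–2% body mass per day, and a fish denied feeding loses
~1% — the regime within which the movement-rule contrasts are meaningful.

## Pattern-oriented validation

`sgr_from_recaptures()` computes specific growth rates
(`100·Δln M/Δt`, %·day⁻¹) from first-to-last captures of tagged fish;
`stretch_distribution()` computes percentage distributions after removing
stretches with capture probability below 0.2; `patch_occupancy()`
averages tagged counts per patch over tracking surveys and replicates,
keeping never-occupied patches as zeros. `match_patterns()` scores a
pattern with Pearson's r and MAE across aligned units and a seeded
bootstrap percentile interval (10⁴ resamples) on the difference of mean
SGRs — the decision criterion is whether zero falls inside the 95%
interval. The bootstrap replaces a Bayesian estimator of the same
difference; it implements the same decision rule with no external
sampler, and its coverage is checked by simulation in the tests.
`sensitivity_analysis()` re-runs the model under one-at-a-time ±5%
parameter perturbations at matched seeds.

## Numerical notes and limitations

* Hourly Euler bookkeeping: energy flows within a step are evaluated at
  start-of-step mass; this is the standard explicit treatment and exact
  with respect to the model's own definition.
* The Manning depth is closed-form; no iteration, no tolerance beyond
  float precision. Zero discharge gives zero depth and velocity.
* `v_floor` (0.05 m·s⁻¹) prevents a division by zero on the return leg
  of handling time in near-still water.
* Initial masses are redrawn until above the 1 g death threshold; a
  configuration whose mean is below the threshold with zero SD errors.
* Survey snapshots record end-of-step state; step 0 records the initial
  population.
* The predator:prey ratio uses expected predator *count*
  (density × area); using density instead would make the ratio
  area-independent — switchable by editing one line of the behaviour
  module, but count is the default and the documented behaviour.
* Problem sizes used by the shipped tests and acceptance script: the
  full default experiment (85 days × 24 steps, 126 fish, 4 rules × 5
  replicates), a 34-day natural-flow window with one replicate per
  sensitivity variant, and minute-scale fixtures elsewhere. These are the
  package's own choices of experiment size.
* Known limitations are those of the model class: no individual
  physiological variation beyond starting mass (growth-rate spread is
  therefore under-dispersed relative to real populations), fixed
  territories, no predation mortality (risk shapes movement only), and a
  single-channel linear stream.
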