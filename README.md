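# salmodrift

An individual-based model of juvenile Atlantic salmon (*Salmo salar*) and
brown trout (*Salmo trutta*) in a virtual chalk stream, for predicting how
growth and distribution respond to altered flow regimes.

Fisheries managers increasingly need to anticipate what a drawdown — from
abstraction, regulation or drought — does to a salmonid population.
Habitat-association models cannot answer that outside the conditions they
were fitted to, because fish *behave*: they move, compete for feeding
territories, and trade food against risk. `salmodrift` makes that
behaviour explicit. Virtual fish are diurnal drift feeders with full
energy budgets, living on an hourly clock in a stream whose depth and
velocity follow discharge through a Manning-type hydraulic submodel. The
central question the package is built around: **which habitat selection
rule reproduces real population patterns?** Four are implemented —
random movement (`RANDOM`), consumption-rate maximisation (`MCR`),
predation-risk minimisation (`MPR`), and consumption-first risk-second
(`CR_GT_PR`).

## The model in brief

Per hour, a fish in a patch with velocity *v*, depth *d* and drift
densities *D_c* (ten prey categories) can potentially ingest

&nbsp;&nbsp;potential = Σ_c min(RE_c·PCS, 3600/HT_c) · m_c · E_c,&nbsp;
RE_c = D_c · v · CA_c · 3600,

with a square capture window CA sized by its reaction distance and capped
by the wetted cross-section, capture success declining with velocity, and
pursuit-and-return handling time. Intake is clamped at the physiological
maximum C_max = a_C·M^0.75·φ(T); the fish feeds the fraction of the hour
that maximises net energy and rests the remainder. The energy budget is

&nbsp;&nbsp;ΔM · ε = 0.69·GEI − (R_s + SC + SDA·GEI), capped at R_max,

with 31% of gross intake lost to faeces and urea, allometric-exponential
standard respiration, and swimming costs at 100% of patch velocity while
feeding and 50% while resting. Growth rates are reported as the specific
growth rate SGR = 100·(ln M_e − ln M_s)/(t_e − t_s) in % body mass·day⁻¹.
Feeding requires daylight, flowing water, and enough available feeding
area (patch flowing area minus the territories of fish already feeding)
to hold the fish's territory; fish process in dominance order (1+ before
young-of-the-year, random within cohort) and fall out of the population
below 1 g.

## A worked example

Generate the default synthetic chalk stream — 7 stretches, 75 patches, a
68-day natural-flow summer followed by a 17-day experimental drawdown —
and compare two movement rules over five replicate simulations:

```r
library(salmodrift)

env  <- generate_environment(synth_spec(seed = 7))
init <- attr(env, "init")

out <- lapply(c("MCR", "CR_GT_PR"), function(rule) {
  cfg <- sim_config(env, init, rule = rule, n_days = 85, nf_days = 68,
                    replicates = 5, seed = 1)
  summary_sgr(run_simulation(cfg))
})
names(out) <- c("MCR", "CR_GT_PR")

sapply(out, function(s) c(
  mean_sgr  = mean(s$sgr_total, na.rm = TRUE),
  feed_prop = mean(s$mean_feed_total),
  var_nf    = var(s$sgr_nf,  na.rm = TRUE),
  var_mlf   = var(s$sgr_mlf, na.rm = TRUE)))
#>                 MCR  CR_GT_PR
#> mean_sgr  0.4150074 0.4658866
#> feed_prop 0.3198133 0.3293762
#> var_nf    0.3582241 0.4277821
#> var_mlf   0.6658316 0.7376698
```

Both consumption-led populations grow (~0.4% body mass·day⁻¹ over the
whole period). `MCR` fish spend slightly *less* of the day feeding than
`CR_GT_PR` fish — they sit in richer patches and hit their consumption
ceiling sooner — and for both rules the spread of individual growth rates
roughly doubles under the drawdown, when shallow slow patches fall below
C_max and growth starts to depend on where a fish is. Under the same
conditions `RANDOM` and `MPR` populations lose mass (mean SGR −0.98 and
−0.47 %·day⁻¹): undirected movement keeps landing fish in slack water, and
pure risk minimisation degenerates into a random walk wherever pike are
absent.

Validation utilities compare simulated and observed patterns the same
way field data would be analysed: `sgr_from_recaptures()`,
`stretch_distribution()` (with a 0.2 capture-probability filter),
`patch_occupancy()` for tagged fish across tracking surveys, and
`match_patterns()` for Pearson r / MAE / a seeded bootstrap interval on
the mean SGR difference. `generate_observations()` thins a run's tagged
snapshots into imperfect-detection "observations" for closed-loop tests.

A thin CLI lives at `inst/scripts/salmodrift`
(`salmodrift synth|run|sensitivity ...`) for shell use.

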