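# Simulation engine: initialisation, processing order, conservation,
# determinism, energy bookkeeping at the step scale, replicate structure.

test_that("initial population honours counts, truncation and tagging", {
  env <- tiny_env()
  init <- tiny_init(n_salmon = 6, n_trout1p = 3)
  set.seed(1)
  pop <- initialize_population(init, species_params_default(), env$patches)
  expect_equal(nrow(pop), 9)
  expect_equal(sum(pop$tagged), 3)
  expect_true(all(pop$mass >= 1))
  expect_true(all(pop$patch_id[pop$species == "salmon"] %in% 1:3))
  expect_true(all(pop$patch_id[pop$species == "trout"] %in% 4:5))
  # SD = 0 collapses to the mean
  init0 <- tiny_init()
  init0$mass_sd <- 0
  pop0 <- initialize_population(init0, species_params_default(), env$patches)
  expect_equal(unique(pop0$mass[pop0$species == "salmon"]), 3.5)
  # impossible truncation errors out
  bad <- tiny_init()
  bad$mass_mean <- 0.5
  bad$mass_sd <- 0
  expect_error(initialize_population(bad, species_params_default(),
                                     env$patches), "threshold")
})

test_that("drawn initial masses concentrate on the configured mean", {
  env <- tiny_env()
  init <- data.frame(stretch_id = 1, species = "salmon", cohort = "YOY",
                     count = 10000, mass_mean = 3.5, mass_sd = 1, tagged = 0)
  set.seed(42)
  pop <- initialize_population(init, species_params_default(), env$patches)
  # truncation at 1 g barely shifts a N(3.5, 1) draw; 3 SE window
  expect_lt(abs(mean(pop$mass) - 3.5), 3 * 1 / sqrt(10000) + 0.01)
})

test_that("1+ fish are processed before YOY fish on every daylight step", {
  env <- tiny_env(n_days = 2)
  cfg <- sim_config(env, tiny_init(), n_days = 2, nf_days = 2,
                    rule = "MCR", replicates = 1, seed = 5,
                    trace_order = TRUE)
  res <- run_simulation(cfg)
  ord <- res$order
  expect_gt(nrow(ord), 0)
  for (st in unique(ord$step)) {
    coh <- ord$cohort[ord$step == st]
    expect_true(all(which(coh == "1+") < min(which(coh == "YOY"))))
  }
})

test_that("the system is closed: population never grows, deaths only", {
  env <- tiny_env(n_days = 3, prey = 0) # starvation environment
  cfg <- sim_config(env, tiny_init(), n_days = 3, nf_days = 3,
                    rule = "RANDOM", replicates = 1, seed = 2,
                    survey_steps = seq(0, 72, by = 12))
  res <- run_simulation(cfg)
  counts <- tapply(res$fish$fish_id, res$fish$step, length)
  expect_true(all(diff(as.integer(counts)) <= 0))
  # snapshot at step 0 reproduces the whole initial population
  expect_equal(sum(res$fish$step == 0), 6)
})

test_that("identical configurations reproduce bit-identical outputs", {
  env <- tiny_env(n_days = 2)
  cfg <- sim_config(env, tiny_init(), n_days = 2, nf_days = 2,
                    rule = "CR_GT_PR", replicates = 2, seed = 11)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$fish, r2$fish)
  expect_identical(r1$summary, r2$summary)
  # replicates differ from one another
  s1 <- r1$summary[r1$summary$replicate == 1, ]
  s2 <- r1$summary[r1$summary$replicate == 2, ]
  expect_false(isTRUE(all.equal(s1$end_mass, s2$end_mass)))
})

test_that("per-step energy bookkeeping holds for every fish and step", {
  # survey every step; Delta mass * e_fish == 0.69 * GEI - R exactly
  env <- tiny_env(n_days = 2)
  steps <- 0:48
  cfg <- sim_config(env, tiny_init(), n_days = 2, nf_days = 2,
                    rule = "MCR", replicates = 1, seed = 3,
                    survey_steps = steps)
  res <- run_simulation(cfg)
  sp <- species_params_default()
  f <- res$fish[order(res$fish$fish_id, res$fish$step), ]
  checked <- 0L
  for (id in unique(f$fish_id)) {
    fi <- f[f$fish_id == id, ]
    ef <- sp$e_fish[sp$species == fi$species[1] & sp$cohort == fi$cohort[1]]
    lf <- sp$loss_frac[sp$species == fi$species[1] &
                         sp$cohort == fi$cohort[1]]
    dm <- diff(fi$mass)
    rhs <- ((1 - lf) * fi$gei - fi$resp)[-1] / ef
    expect_equal(dm, rhs, tolerance = 1e-12)
    checked <- checked + length(dm)
  }
  expect_gt(checked, 200)
  # GEI never exceeds Cmax for the fish's current state
  for (i in seq_len(nrow(f))) {
    if (f$step[i] == 0) next
    prow <- sp[sp$species == f$species[i] & sp$cohort == f$cohort[i], ]
    prev <- f$mass[i] - ((1 - prow$loss_frac) * f$gei[i] - f$resp[i]) /
      prow$e_fish
    Tt <- res$global$temperature[f$step[i]]
    expect_lte(f$gei[i], cmax(prev, Tt, prow) + 1e-9)
  }
})

test_that("AFA stays non-negative and occupancy is conserved in snapshots", {
  env <- generate_environment(small_synth_spec(seed = 2))
  init <- attr(env, "init")
  cfg <- sim_config(env, init, n_days = 6, nf_days = 4, rule = "CR_GT_PR",
                    replicates = 2, seed = 4,
                    survey_steps = seq(12, 144, by = 12))
  res <- run_simulation(cfg)
  expect_true(all(res$patch$afa >= 0))
  # sum of per-patch counts equals the alive population at each survey
  for (r in unique(res$patch$replicate)) {
    for (st in unique(res$patch$step)) {
      np <- sum(res$patch$n_fish[res$patch$replicate == r &
                                   res$patch$step == st])
      nf <- sum(res$fish$replicate == r & res$fish$step == st)
      expect_equal(np, nf)
    }
  }
})

test_that("fish never feed at night or in slack patches", {
  env <- tiny_env(n_days = 2)
  steps <- 1:48
  cfg <- sim_config(env, tiny_init(), n_days = 2, nf_days = 2,
                    rule = "RANDOM", replicates = 1, seed = 9,
                    survey_steps = steps)
  res <- run_simulation(cfg)
  night <- res$global$step[!res$global$is_day]
  expect_true(all(res$fish$gei[res$fish$step %in% night] == 0))
  slackers <- res$fish$patch_id == 3 # flowing fraction 0 in tiny_env
  expect_true(all(res$fish$feed_fraction[slackers] == 0))
})
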