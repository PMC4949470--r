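# Pattern-oriented validation: recapture SGRs, stretch/patch patterns,
# Pearson/MAE/bootstrap scoring, order invariance, and the closed loop
# against a perfect-detection truth run.

test_that("recapture SGRs use first and last capture, singles excluded", {
  rec <- data.frame(
    fish_id = c(1, 1, 2, 3, 3, 3),
    day = c(0, 68, 0, 0, 33, 68),
    mass = c(10, 20, 5, 4, 6, 9)
  )
  out <- sgr_from_recaptures(rec)
  expect_equal(nrow(out), 2)
  expect_equal(out$sgr[out$fish_id == 1], 100 * log(2) / 68)
  expect_equal(out$sgr[out$fish_id == 3], 100 * (log(9) - log(4)) / 68)
  expect_warning(out0 <- sgr_from_recaptures(
    data.frame(fish_id = 1, day = 0, mass = 5)), "no recaptured")
  expect_equal(nrow(out0), 0)
})

test_that("stretch distribution filters low-capture stretches, sums to 100", {
  rec <- data.frame(stretch_id = rep(c("a", "b", "c"), c(10, 10, 20)))
  d <- stretch_distribution(rec)
  expect_equal(d$percent, c(25, 25, 50))
  d2 <- stretch_distribution(rec, capture_prob = c(a = 0.1, b = 0.9, c = 0.9))
  expect_equal(d2$stretch_id, c("b", "c"))
  expect_equal(sum(d2$percent), 100, tolerance = 1e-9)
  expect_warning(stretch_distribution(rec, capture_prob =
                                        c(a = 0.1, b = 0.1, c = 0.1)),
                 "filtered")
})

test_that("patch occupancy averages tagged counts with gaps as zeros", {
  rec <- data.frame(
    patch_id = c(1, 1, 2, 1),
    step = c(10, 20, 10, 10),
    replicate = 1L,
    tagged = c(TRUE, TRUE, TRUE, FALSE)
  )
  occ <- patch_occupancy(rec, survey_steps = c(10, 20), patch_ids = 1:3)
  expect_equal(occ$mean, c(1, 0.5, 0)) # patch 3 never occupied: gap
  expect_true(all(occ$se >= 0))
  # conservation: totals across patches = total tagged detections
  expect_equal(sum(occ$mean) * 2, 3)
  # single survey: SE undefined, flagged
  occ1 <- patch_occupancy(rec, survey_steps = 10, patch_ids = 1:3)
  expect_false(occ1$se_defined[1])
  expect_equal(occ1$se, rep(0, 3))
})

test_that("pattern scores behave on exact and offset predictions", {
  obs <- c(10, 20, 30, 40)
  rep1 <- match_patterns(obs, obs)
  expect_equal(rep1$pearson_r, 1)
  expect_equal(rep1$mae, 0)
  expect_true(rep1$zero_in_interval)
  rep2 <- match_patterns(obs, obs + 5)
  expect_equal(rep2$pearson_r, 1)
  expect_equal(rep2$mae, 5)
  # fewer than 3 units: r undefined
  rep3 <- match_patterns(c(1, 2), c(2, 1))
  expect_true(is.na(rep3$pearson_r))
})

test_that("the bootstrap interval is calibrated on equal-mean samples", {
  set.seed(10)
  hits <- 0L
  n_rep <- 60
  for (i in 1:n_rep) {
    a <- rnorm(40)
    b <- rnorm(40)
    rep <- match_patterns(a, b, n_boot = 2000, seed = i)
    if (isTRUE(rep$zero_in_interval)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9) # nominal ~95%, allow sampling slack
})

test_that("pattern statistics are invariant to record ordering", {
  set.seed(5)
  rec <- data.frame(
    patch_id = sample(1:6, 200, replace = TRUE),
    stretch_id = sample(letters[1:4], 200, replace = TRUE),
    step = sample(c(10, 20, 30), 200, replace = TRUE),
    replicate = sample(1:2, 200, replace = TRUE),
    tagged = TRUE
  )
  perm <- sample.int(nrow(rec))
  o1 <- patch_occupancy(rec, c(10, 20, 30), 1:6)
  o2 <- patch_occupancy(rec[perm, ], c(10, 20, 30), 1:6)
  expect_equal(o1, o2)
  s1 <- stretch_distribution(rec)
  s2 <- stretch_distribution(rec[perm, ])
  expect_equal(s1, s2)
})

test_that("a truth run thinned at detection 1 matches its own snapshots", {
  env <- generate_environment(small_synth_spec(seed = 17))
  init <- attr(env, "init")
  steps <- c(48, 96)
  cfg <- sim_config(env, init, n_days = 4, nf_days = 4, rule = "CR_GT_PR",
                    replicates = 1, seed = 20, survey_steps = steps)
  res <- run_simulation(cfg)
  obs <- generate_observations(res$fish, detection_prob = 1, seed = 1)
  po_obs <- patch_occupancy(obs, steps, env$patches$patch_id)
  po_truth <- patch_occupancy(res$fish, steps, env$patches$patch_id)
  expect_equal(po_obs, po_truth)
  sd_obs <- stretch_distribution(obs)
  sd_truth <- stretch_distribution(res$fish[res$fish$tagged, ])
  expect_equal(sd_obs, sd_truth)
})

test_that("sensitivity driver: unused parameters do not move growth", {
  env <- tiny_env(n_days = 2, prey = 20)
  init <- tiny_init()
  # v_floor is never touched when velocity stays above it
  out <- sensitivity_analysis(env, init, c("v_floor"), delta = 0.05,
                              n_days = 2, replicates = 1, seed = 30)
  expect_equal(out$delta_sgr, c(0, 0), tolerance = 1e-12)
  # an invalid perturbation is flagged and skipped
  sp <- species_params_default()
  sp$loss_frac <- 0.99
  out2 <- sensitivity_analysis(env, init, c("loss_frac"), delta = 0.05,
                               species_params = sp, n_days = 2,
                               replicates = 1, seed = 30)
  expect_true(any(!out2$valid))
  expect_true(any(is.na(out2$delta_sgr)))
})
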