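# Drift-foraging mechanics: geometry, encounter/capture/handling rates,
# gape-limited diet, and the clamped gross energy intake.

par1 <- species_params_default()[1, ]
cats <- prey_categories_default()

test_that("reaction distance is linear in fork length", {
  rd1 <- reaction_distance(60, 4)
  rd2 <- reaction_distance(120, 4)
  expect_equal(rd2, 2 * rd1)
  expect_equal(reaction_distance(60, 4, beta = 0),
               reaction_distance(60, 10.5, beta = 0))
  expect_true(all(reaction_distance(c(20, 60, 150), 2) > 0))
})

test_that("capture window is square and capped by the wetted section", {
  expect_equal(capture_area(0.1, depth = 2, width_per_fish = 5), 0.04)
  expect_equal(capture_area(0.1, depth = 0.1, width_per_fish = 5), 0.01)
  expect_equal(capture_area(0.1, depth = 2, width_per_fish = 0.05), 0.0025)
  rds <- seq(0.01, 0.5, by = 0.01)
  ca <- capture_area(rds, depth = 0.4, width_per_fish = 1)
  expect_true(all(diff(ca) >= 0))
})

test_that("encounter rate is the linear drift flux", {
  expect_equal(encounter_rate(10, 0.5, 0.04), 720)
  expect_equal(encounter_rate(10, 0, 0.04), 0)
  expect_equal(encounter_rate(2 * 10, 0.5, 0.04), 2 * 720)
  expect_equal(encounter_rate(10, 2 * 0.5, 0.04), 2 * 720)
  expect_equal(encounter_rate(10, 0.5, 2 * 0.04), 2 * 720)
})

test_that("capture success declines with velocity and stays a probability", {
  expect_equal(capture_success(0, 0.6), 1)
  expect_equal(capture_success(0.6, 0.6, gamma = 1), 0)
  v <- seq(0, 2, by = 0.1)
  p <- capture_success(v, 0.6)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("handling time is pursuit out plus drift back", {
  expect_equal(handling_time(0.1, 0.6, 0.1), 0.1 / 0.5 + 0.1 / 0.1)
  expect_equal(handling_time(0.1, 0.6, 0.7), Inf) # cannot close on prey
  # strictly increases as the current approaches Vmax (pursuit-dominated
  # regime, v > Vmax / 2)
  v <- seq(0.31, 0.59, by = 0.01)
  ht <- handling_time(0.1, 0.6, v)
  expect_true(all(diff(ht) > 0))
})

test_that("diet is a gape window on prey midpoints, monotone in length", {
  all10 <- diet_categories(60, cats, delta_min = 0, delta_max = 1)
  expect_equal(sort(all10), 1:10)
  # small fish exclude the 9-12 mm class under the default window
  d_small <- diet_categories(60, cats, par1$delta_min, par1$delta_max)
  expect_false(any(cats$midpoint[d_small] > 10))
  d_large <- diet_categories(150, cats, par1$delta_min, par1$delta_max)
  expect_gte(max(cats$midpoint[d_large]), max(cats$midpoint[d_small]))
})

test_that("gross energy intake is clamped, monotone and saturates", {
  dens <- rep(2, 10)
  g <- gross_energy_intake(70, 3.5, 16, dens, velocity = 0.5, depth = 0.5,
                           feed_fraction = 1, params = par1)
  expect_lte(g$gei, g$cmax)
  expect_equal(gross_energy_intake(70, 3.5, 16, dens, 0.5, 0.5,
                                   feed_fraction = 0, params = par1)$gei, 0)
  expect_equal(gross_energy_intake(70, 3.5, 16, rep(0, 10), 0.5, 0.5,
                                   feed_fraction = 1, params = par1)$gei, 0)
  # monotone non-decreasing in every density and in feed fraction
  g2 <- gross_energy_intake(70, 3.5, 16, dens * 2, 0.5, 0.5,
                            feed_fraction = 1, params = par1)
  expect_gte(g2$potential, g$potential)
  g3 <- gross_energy_intake(70, 3.5, 16, dens, 0.5, 0.5,
                            feed_fraction = 0.5, params = par1)
  expect_lte(g3$gei, g$gei)
  # rich water saturates at exactly Cmax
  g4 <- gross_energy_intake(70, 3.5, 16, rep(100, 10), 0.5, 0.5,
                            feed_fraction = 1, params = par1)
  expect_equal(g4$gei, g4$cmax)
  # handling-time saturation: CR <= RE * PCS and CR <= 3600 / HT per category
  bd <- g$breakdown[g$breakdown$edible, ]
  expect_true(all(bd$CR <= bd$RE * bd$PCS + 1e-12))
  expect_true(all(bd$CR <= 3600 / bd$HT + 1e-12))
})

test_that("with perfect capture and no handling, GEI is the drift-flux sum", {
  # PCS == 1 (gamma 0) and HT -> 0 (rd small but pursuit instant via huge
  # Vmax) reduce intake to sum(density * v * CA * E), the linear limit
  p <- par1
  p$pcs_gamma <- 0
  p$vmax_bl <- 1e9 # pursuit effectively instant
  p$delta_min <- 0; p$delta_max <- Inf
  dens <- runif(10, 0, 0.02)
  v <- 0.4; d <- 5
  g <- gross_energy_intake(70, 3.5, 16, dens, v, d,
                           feed_fraction = 1, params = p)
  RD <- p$rd_alpha * 70 * (1 + p$rd_beta * cats$midpoint)
  CA <- pmin(2 * RD, d)^2
  manual <- sum(dens * v * CA * 3600 * cats$dry_mass * cats$energy_density)
  expect_equal(g$potential, manual, tolerance = 1e-9)
})
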