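# Drift-feeding mechanics: what a fish of a given size can see, catch and
# ingest from the drift in a patch over an hour. A drift feeder holds
# station, intercepts prey passing through a square capture window sized by
# its reaction distance, darts at maximum swim speed, and returns with the
# current; capture success declines with water velocity and intake saturates
# through handling time.

#' Reaction distance to a drifting prey item
#'
#' `RD = alpha * FL * (1 + beta * midpoint)`: linear in fish fork length and
#' increasing with prey size (larger items are visible further away).
#'
#' @param FL Fork length, mm (> 0).
#' @param prey_midpoint Prey size-class midpoint, mm (vectorised).
#' @param alpha Metres of reaction distance per mm of fork length.
#' @param beta Relative gain per mm of prey midpoint.
#' @return Reaction distance, m.
#' @export
reaction_distance <- function(FL, prey_midpoint, alpha = 0.002, beta = 0.05) {
  stopifnot(all(FL > 0))
  alpha * FL * (1 + beta * prey_midpoint)
}

#' Square capture window area
#'
#' The window side is `2 * RD`, capped by water depth and by the fish's
#' share of channel width so the window never exceeds the wetted
#' cross-section; the area is the squared side.
#'
#' @param RD Reaction distance, m (> 0, vectorised).
#' @param depth Patch mean depth, m.
#' @param width_per_fish Channel width available to this fish, m.
#' @return Capture area, m^2.
#' @export
capture_area <- function(RD, depth, width_per_fish = Inf) {
  stopifnot(all(RD > 0))
  s <- pmin(2 * RD, depth, width_per_fish)
  s <- pmax(s, 0)
  s * s
}

#' Drift encounter rate
#'
#' Prey flux through the capture window:
#' `RE = density * velocity * CA * 3600` prey per hour.
#'
#' @param density Drift density, prey/m^3 (>= 0).
#' @param velocity Water velocity, m/s (>= 0).
#' @param CA Capture area, m^2 (>= 0).
#' @return Encounters per hour.
#' @export
encounter_rate <- function(density, velocity, CA) {
  stopifnot(all(density >= 0), all(velocity >= 0), all(CA >= 0))
  density * velocity * CA * 3600
}

#' Probability of capture success
#'
#' Declines linearly with water velocity relative to the fish's maximum
#' swimming speed: `PCS = clip(1 - gamma * v / Vmax, 0, 1)`.
#'
#' @param velocity Water velocity, m/s (>= 0).
#' @param Vmax Maximum swimming speed, m/s (> 0).
#' @param gamma Velocity penalty coefficient.
#' @return Probability in `[0, 1]`.
#' @export
capture_success <- function(velocity, Vmax, gamma = 0.6) {
  stopifnot(all(velocity >= 0), all(Vmax > 0))
  pmin(1, pmax(0, 1 - gamma * velocity / Vmax))
}

#' Handling time of one pursuit
#'
#' Out to the prey at the closing speed `Vmax - v`, back with the current:
#' `HT = RD / (Vmax - v) + RD / max(v, v_floor)` seconds. If the current is
#' at or above the fish's maximum swimming speed the prey cannot be closed
#' on and handling time is infinite (no capture).
#'
#' @param RD Reaction distance, m.
#' @param Vmax Maximum swimming speed, m/s.
#' @param velocity Water velocity, m/s.
#' @param v_floor Velocity floor for the return leg, m/s.
#' @return Seconds per pursuit (`Inf` when `velocity >= Vmax`).
#' @export
handling_time <- function(RD, Vmax, velocity, v_floor = 0.05) {
  stopifnot(all(RD > 0), all(Vmax > 0), all(velocity >= 0))
  ifelse(velocity >= Vmax, Inf,
         RD / (Vmax - velocity) + RD / pmax(velocity, v_floor))
}

#' Edible prey categories for a fish length
#'
#' Gape window: a category is edible when its size-class midpoint lies in
#' `[delta_min * FL, delta_max * FL]`; both aquatic and terrestrial origins
#' are included.
#'
#' @param FL Fork length, mm (> 0).
#' @param categories Prey category table ([prey_categories_default()]).
#' @param delta_min,delta_max Gape window bounds relative to fork length.
#' @return Integer vector of edible category ids.
#' @export
diet_categories <- function(FL, categories = prey_categories_default(),
                            delta_min = 0.015, delta_max = 0.12) {
  stopifnot(FL > 0)
  mid <- categories$midpoint
  categories$id[mid >= delta_min * FL & mid <= delta_max * FL]
}

# Per-category capture rates for one fish in one patch. Internal hot path
# shared by gross_energy_intake() and the scheduler. `densities` is the
# length-10 drift density vector of the patch's stretch.
capture_rates <- function(FL, Vmax, densities, velocity, depth,
                          width_per_fish, params,
                          mid = c(2, 4, 6, 8, 10.5, 2, 4, 6, 8, 10.5)) {
  RD <- params$rd_alpha * FL * (1 + params$rd_beta * mid)
  s <- pmax(pmin(2 * RD, depth, width_per_fish), 0)
  CA <- s * s
  RE <- densities * velocity * CA * 3600
  PCS <- min(1, max(0, 1 - params$pcs_gamma * velocity / Vmax))
  if (velocity >= Vmax) {
    HT <- rep(Inf, 10L)
    CR <- numeric(10L)
    PCS <- 0
  } else {
    HT <- RD / (Vmax - velocity) + RD / pmax(velocity, params$v_floor)
    CR <- pmin(RE * PCS, 3600 / HT)
  }
  list(RD = RD, CA = CA, RE = RE, PCS = PCS, HT = HT, CR = CR)
}

#' Gross energy intake of a drift-feeding fish over one hour
#'
#' Per edible category `c`, the capture rate is
#' `CR_c = min(RE_c * PCS, 3600 / HT_c)` prey per hour (encounter-limited
#' or handling-limited, whichever binds); the potential hourly intake is
#' `sum_c CR_c * dry_mass_c * energy_density_c`. Gross energy intake for
#' the step is `min(potential * feed_fraction, Cmax)`: a fish feeding a
#' fraction of the hour in rich water is clamped at its physiological
#' maximum.
#'
#' @param FL Fork length, mm.
#' @param mass Body mass, g.
#' @param temperature Water temperature, degC.
#' @param densities Length-10 drift density vector for the patch's stretch
#'   (prey/m^3).
#' @param velocity,depth Patch hydraulics (m/s, m).
#' @param width_per_fish Channel width available to this fish, m.
#' @param feed_fraction Fraction of the hour spent feeding, in `[0, 1]`.
#' @param params Species parameter row.
#' @param categories Prey category table.
#' @return List with `gei` (kJ for the hour), `potential` (uncapped kJ/h)
#'   and `breakdown`, a per-category data frame of `RE`, `PCS`, `HT`, `CR`
#'   and gross energy.
#' @export
gross_energy_intake <- function(FL, mass, temperature, densities, velocity,
                                depth, width_per_fish = Inf,
                                feed_fraction = 1,
                                params = species_params_default()[1, ],
                                categories = prey_categories_default()) {
  stopifnot(length(densities) == 10L, feed_fraction >= 0, feed_fraction <= 1)
  Vmax <- params$vmax_bl * FL / 1000
  cr <- capture_rates(FL, Vmax, densities, velocity, depth, width_per_fish,
                      params, mid = categories$midpoint)
  edible <- categories$id %in% diet_categories(FL, categories,
                                               params$delta_min,
                                               params$delta_max)
  CR <- ifelse(edible, cr$CR, 0)
  energy <- CR * categories$dry_mass * categories$energy_density
  potential <- sum(energy)
  cm <- cmax(mass, temperature, params)
  gei <- min(potential * feed_fraction, cm)
  list(
    gei = gei,
    potential = potential,
    cmax = cm,
    breakdown = data.frame(
      id = categories$id, edible = edible, RE = cr$RE, PCS = cr$PCS,
      HT = cr$HT, CR = CR, energy = energy
    )
  )
}
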