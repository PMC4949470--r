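# Virtual stream environment: hierarchical state (global -> stretch -> patch),
# sparse field samples turned into hourly series, and the diel drift profile.
#
# Time convention: the simulation clock is a 0-based hourly index h; step t of
# a run (1-based, R indexing) covers hour h = t - 1. The calendar day of hour
# h is floor(h / 24) and the hour-of-day is h %% 24. Between-day series are
# sampled at (integer) days and held flat within a day, so a day's base value
# is the linear interpolation of the samples evaluated at that integer day.

#' Default drift prey categories
#'
#' The ten invertebrate drift categories: five length classes (1-3, 3-5, 5-7,
#' 7-9 and 9-12 mm) by two origins (aquatic, terrestrial). Per-item dry mass
#' follows a standard invertebrate length-mass power law on the class
#' midpoint, and energy density is a constant 22.13 kJ per g dry weight for
#' every category. Aquatic categories carry multiplicative diel anchors
#' (dawn, midday, dusk) describing the within-day drift cycle; terrestrial
#' categories are flat within a day (all anchors 1).
#'
#' @param lm_a,lm_b Coefficients of the length-mass law `dry mass (mg) =
#'   lm_a * L^lm_b` with `L` the class midpoint in mm.
#' @param energy_density Energy density, kJ per g dry weight.
#' @param anchors_aquatic Numeric length-3 vector of dawn/midday/dusk
#'   multipliers for aquatic categories.
#' @return A data frame with one row per category: `id`, `size_min`,
#'   `size_max`, `midpoint` (mm), `origin`, `dry_mass` (g per item),
#'   `energy_density` (kJ/g), `anchor_dawn`, `anchor_midday`, `anchor_dusk`.
#' @export
prey_categories_default <- function(lm_a = 0.002, lm_b = 2.7,
                                    energy_density = 22.13,
                                    anchors_aquatic = c(1.6, 0.7, 1.7)) {
  lo <- c(1, 3, 5, 7, 9)
  hi <- c(3, 5, 7, 9, 12)
  mid <- (lo + hi) / 2
  origin <- rep(c("aquatic", "terrestrial"), each = 5L)
  out <- data.frame(
    id = 1:10,
    size_min = rep(lo, 2L),
    size_max = rep(hi, 2L),
    midpoint = rep(mid, 2L),
    origin = origin,
    dry_mass = rep(lm_a * mid^lm_b, 2L) / 1000, # mg -> g
    energy_density = energy_density,
    anchor_dawn = ifelse(origin == "aquatic", anchors_aquatic[1L], 1),
    anchor_midday = ifelse(origin == "aquatic", anchors_aquatic[2L], 1),
    anchor_dusk = ifelse(origin == "aquatic", anchors_aquatic[3L], 1),
    stringsAsFactors = FALSE
  )
  out
}

#' Piecewise-linear interpolation of a sampled series
#'
#' Linear interpolation between bracketing samples; exact at sample times;
#' outside the sampled range the nearest endpoint is held constant (no linear
#' extrapolation, which could produce negative densities).
#'
#' @param times Strictly increasing sample times.
#' @param values Sample values, same length as `times`.
#' @param t Times at which to evaluate (vectorised).
#' @return Interpolated values at `t`.
#' @export
interpolate_series <- function(times, values, t) {
  if (length(times) == 0L) {
    stop("empty series: at least one sample is required", call. = FALSE)
  }
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (length(times) == 1L) {
    return(rep(values, length(t)))
  }
  stats::approx(times, values, xout = t, method = "linear", rule = 2)$y
}

#' Day/night state of an hour of day
#'
#' Half-open daylight convention: an hour-of-day is daylight iff it lies in
#' `[sunrise, sunset)`.
#'
#' @param hour_of_day Hour of day in `[0, 24)` (vectorised).
#' @param sunrise,sunset Sunrise and sunset as hours of day,
#'   `0 <= sunrise < sunset <= 24`.
#' @return Logical vector.
#' @export
is_daylight <- function(hour_of_day, sunrise, sunset) {
  stopifnot(all(sunrise >= 0), all(sunrise < sunset), all(sunset <= 24))
  hour_of_day >= sunrise & hour_of_day < sunset
}

# Within-day multiplicative drift profile: linear between anchors placed at
# dawn (sunrise), midday ((sunrise+sunset)/2) and dusk (sunset); the dusk
# value is held overnight until the next dawn.
diel_multiplier <- function(hour_of_day, sunrise, sunset,
                            a_dawn, a_mid, a_dusk) {
  n <- length(hour_of_day)
  sunrise <- rep_len(sunrise, n)
  sunset <- rep_len(sunset, n)
  midday <- (sunrise + sunset) / 2
  out <- numeric(n)
  before <- hour_of_day < sunrise
  after <- hour_of_day >= sunset
  rise <- !before & hour_of_day < midday
  fall <- !after & hour_of_day >= midday
  out[before | after] <- a_dusk
  out[rise] <- a_dawn + (a_mid - a_dawn) *
    (hour_of_day[rise] - sunrise[rise]) / (midday[rise] - sunrise[rise])
  out[fall] <- a_mid + (a_dusk - a_mid) *
    (hour_of_day[fall] - midday[fall]) / (sunset[fall] - midday[fall])
  out
}

#' Hourly drift density for one prey category
#'
#' Turns sparse between-day base samples into an hourly drift density.
#' The base density is the linear interpolation of the day-indexed samples
#' evaluated at the (integer) calendar day of `t_hour`, so it is flat within
#' each day. Aquatic categories are further multiplied by the within-day
#' diel profile (linear between dawn/midday/dusk anchors; dusk value held
#' overnight); terrestrial categories stay constant within a day.
#'
#' @param sample_days Days at which base densities were sampled (increasing).
#' @param sample_values Base densities at `sample_days` (invertebrates/m^3,
#'   all non-negative).
#' @param t_hour 0-based hour index (vectorised).
#' @param origin `"aquatic"` or `"terrestrial"`.
#' @param anchors Length-3 vector of dawn/midday/dusk multipliers (ignored
#'   for terrestrial categories).
#' @param sunrise,sunset Hours of day bounding daylight for the day of
#'   `t_hour`.
#' @return Drift density (invertebrates/m^3), non-negative.
#' @export
drift_density <- function(sample_days, sample_values, t_hour,
                          origin = c("aquatic", "terrestrial"),
                          anchors = c(1, 1, 1), sunrise = 6, sunset = 18) {
  origin <- match.arg(origin)
  if (any(sample_values < 0)) {
    stop("configured drift densities must be non-negative", call. = FALSE)
  }
  day <- floor(t_hour / 24)
  base <- interpolate_series(sample_days, sample_values, day)
  if (origin == "terrestrial") {
    return(base)
  }
  hod <- t_hour %% 24
  base * diel_multiplier(hod, sunrise, sunset,
                         anchors[1L], anchors[2L], anchors[3L])
}

#' Validate a raw stream environment
#'
#' Checks the structural invariants of an environment object: non-negative
#' densities and discharge, a consistent linear patch chain, positive areas,
#' flowing fractions in `[0, 1]`, vegetation cover in `[0, 1]`, and exactly
#' ten prey categories.
#'
#' @param env A `stream_env` object (see [load_environment()] or
#'   [generate_environment()]).
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_environment <- function(env) {
  p <- env$patches
  stopifnot(is.data.frame(p), nrow(p) >= 1L)
  if (any(p$area <= 0)) stop("patch areas must be positive", call. = FALSE)
  if (any(p$width <= 0) || any(p$slope <= 0)) {
    stop("patch width and slope must be positive", call. = FALSE)
  }
  if (any(p$flowing_fraction < 0 | p$flowing_fraction > 1)) {
    stop("flowing_fraction must lie in [0, 1]", call. = FALSE)
  }
  # linear chain consistency: A's downstream neighbour has A as upstream
  for (i in seq_len(nrow(p))) {
    dn <- p$downstream[i]
    if (!is.na(dn)) {
      j <- match(dn, p$patch_id)
      if (is.na(j) || is.na(p$upstream[j]) || p$upstream[j] != p$patch_id[i]) {
        stop("patch adjacency is not a consistent linear chain", call. = FALSE)
      }
    }
    up <- p$upstream[i]
    if (!is.na(up)) {
      j <- match(up, p$patch_id)
      if (is.na(j) || is.na(p$downstream[j]) ||
          p$downstream[j] != p$patch_id[i]) {
        stop("patch adjacency is not a consistent linear chain", call. = FALSE)
      }
    }
  }
  g <- env$global_series
  if (any(g$discharge < 0)) stop("discharge must be non-negative", call. = FALSE)
  if (any(!is.finite(g$temperature))) {
    stop("temperature must be finite", call. = FALSE)
  }
  if (any(g$sunrise < 0 | g$sunrise >= g$sunset | g$sunset > 24)) {
    stop("need 0 <= sunrise < sunset <= 24", call. = FALSE)
  }
  s <- env$stretch_series
  if (any(s$value < 0)) {
    stop("stretch densities must be non-negative", call. = FALSE)
  }
  pc <- env$prey_categories
  if (nrow(pc) != 10L) stop("exactly 10 prey categories required", call. = FALSE)
  if (any(pc$dry_mass <= 0) || any(pc$energy_density <= 0)) {
    stop("prey dry mass and energy density must be positive", call. = FALSE)
  }
  v <- env$vegetation_series
  if (any(v$cover < 0 | v$cover > 1)) {
    stop("vegetation cover must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a stream environment from delimited files
#'
#' Reads the five-file environment schema from a directory:
#' `patches.csv` (static patch table: `patch_id`, `stretch_id`, `area`,
#' `upstream`, `downstream`, `flowing_fraction`, `width`, `slope`, `n_base`,
#' `k_veg`, `k_slack`), `global_series.csv` (per-day `day`, `temperature`,
#' `discharge`, `sunrise`, `sunset`), `stretch_series.csv` (long format
#' `day`, `stretch_id`, `series`, `value` with `series` one of
#' `prey_1`..`prey_10`, `pred_small`, `pred_large`), `prey_categories.csv`
#' and `vegetation_series.csv` (`day`, `patch_id`, `cover`).
#'
#' @param dir Directory containing the files.
#' @return A validated `stream_env` object.
#' @export
load_environment <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  env <- structure(list(
    patches = rd("patches.csv"),
    global_series = rd("global_series.csv"),
    stretch_series = rd("stretch_series.csv"),
    prey_categories = rd("prey_categories.csv"),
    vegetation_series = rd("vegetation_series.csv")
  ), class = "stream_env")
  validate_environment(env)
  env
}

#' Write a stream environment to delimited files
#'
#' Inverse of [load_environment()]; writes the five CSV files into `dir`.
#'
#' @param env A `stream_env` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_environment <- function(env, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) {
    utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  }
  wr(env$patches, "patches.csv")
  wr(env$global_series, "global_series.csv")
  wr(env$stretch_series, "stretch_series.csv")
  wr(env$prey_categories, "prey_categories.csv")
  wr(env$vegetation_series, "vegetation_series.csv")
  invisible(dir)
}

#' Expand a raw environment into hourly per-step state
#'
#' Precomputes, for every hourly step of a run, the global state
#' (temperature, discharge, day/night), per-patch hydraulics (depth,
#' velocity, flowing fraction via the vegetation series) and per-stretch
#' drift densities (ten categories, diel dynamics applied) and predator
#' densities. All sparse day-indexed series are interpolated linearly and
#' held at the nearest endpoint outside their sampled range.
#'
#' @param env A validated `stream_env` object.
#' @param n_steps Number of hourly steps to cover.
#' @return A `stream_env_prepared` list with vectors/matrices indexed by
#'   step (rows) and patch or stretch (columns); `drift` is a
#'   `n_steps x n_stretches x 10` array.
#' @export
prepare_environment <- function(env, n_steps) {
  validate_environment(env)
  p <- env$patches
  np <- nrow(p)
  stretch_ids <- sort(unique(p$stretch_id))
  ns <- length(stretch_ids)
  g <- env$global_series
  h <- seq_len(n_steps) - 1   # 0-based hours
  day <- floor(h / 24)
  hod <- h %% 24
  temperature <- interpolate_series(g$day, g$temperature, h / 24)
  discharge <- interpolate_series(g$day, g$discharge, h / 24)
  sunrise <- interpolate_series(g$day, g$sunrise, day)
  sunset <- interpolate_series(g$day, g$sunset, day)
  day_flag <- hod >= sunrise & hod < sunset

  # vegetation cover per patch per step (flat within day)
  cover <- matrix(0, n_steps, np)
  for (j in seq_len(np)) {
    vj <- env$vegetation_series[env$vegetation_series$patch_id == p$patch_id[j], ]
    if (nrow(vj) > 0L) {
      vj <- vj[order(vj$day), ]
      cover[, j] <- interpolate_series(vj$day, vj$cover, day)
    }
  }

  # hydraulics (closed-form Manning balance, vectorised over patches)
  depth <- matrix(0, n_steps, np)
  velocity <- matrix(0, n_steps, np)
  flowfrac <- matrix(0, n_steps, np)
  for (t in seq_len(n_steps)) {
    hy <- patch_hydraulics(discharge[t], width = p$width, slope = p$slope,
                           n_base = p$n_base, k_veg = p$k_veg,
                           cover = cover[t, ])
    depth[t, ] <- hy$depth
    velocity[t, ] <- hy$velocity
    flowfrac[t, ] <- flowing_fraction_at(p$flowing_fraction, cover[t, ],
                                         p$k_slack)
  }

  # stretch drift densities and predators
  pc <- env$prey_categories
  drift <- array(0, dim = c(n_steps, ns, 10L))
  pred_small <- matrix(0, n_steps, ns)
  pred_large <- matrix(0, n_steps, ns)
  ss <- env$stretch_series
  for (si in seq_len(ns)) {
    s_rows <- ss[ss$stretch_id == stretch_ids[si], ]
    for (c in 1:10) {
      rows <- s_rows[s_rows$series == paste0("prey_", c), ]
      if (nrow(rows) == 0L) next
      rows <- rows[order(rows$day), ]
      drift[, si, c] <- drift_density(
        rows$day, rows$value, h,
        origin = pc$origin[c],
        anchors = c(pc$anchor_dawn[c], pc$anchor_midday[c], pc$anchor_dusk[c]),
        sunrise = sunrise, sunset = sunset
      )
    }
    for (k in c("pred_small", "pred_large")) {
      rows <- s_rows[s_rows$series == k, ]
      if (nrow(rows) == 0L) next
      rows <- rows[order(rows$day), ]
      val <- interpolate_series(rows$day, rows$value, day)
      if (k == "pred_small") pred_small[, si] <- val else pred_large[, si] <- val
    }
  }

  structure(list(
    patches = p,
    stretch_ids = stretch_ids,
    stretch_index = match(p$stretch_id, stretch_ids),
    up_index = match(p$upstream, p$patch_id),
    down_index = match(p$downstream, p$patch_id),
    n_steps = n_steps,
    temperature = temperature,
    discharge = discharge,
    sunrise = sunrise,
    sunset = sunset,
    is_day = day_flag,
    day = day,
    depth = depth,
    velocity = velocity,
    flowfrac = flowfrac,
    drift = drift,
    pred_small = pred_small,
    pred_large = pred_large,
    prey_categories = pc
  ), class = "stream_env_prepared")
}
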