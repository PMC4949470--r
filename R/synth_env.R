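# Synthetic chalk-stream generator: complete, statistically plausible
# environments and initial populations so every module is testable without
# field data. Defaults emulate a 520 m lowland chalk-stream reach (7
# stretches, 75 patches of 39.6 m^2 on average) over a 68-day natural-flow
# summer period followed by a 17-day modified-low-flow drawdown, with
# diel-cycling aquatic drift, flat-within-day terrestrial drift, monthly
# invertebrate sampling, seasonal Ranunculus growth and sparse,
# stretch-varying pike densities. Prey densities default high (chalk
# streams are extremely productive), so maximum consumption — not prey —
# limits intake.

#' Specification of a synthetic chalk-stream environment
#'
#' @param n_stretches,n_patches Spatial layout (patches form one linear
#'   chain split into contiguous stretches).
#' @param area_mean,area_sd Patch area distribution, m^2 (draws truncated
#'   at `area_min`).
#' @param area_min Lower truncation for patch areas, m^2.
#' @param width_range Patch effective width range, m.
#' @param slope_meanlog,slope_sdlog Log-normal bed slope parameters.
#' @param n_base,k_veg,k_slack Manning roughness baseline, its vegetation
#'   inflation, and the slack-water expansion coefficient.
#' @param slack_prob Probability that a patch is slack water (flowing
#'   fraction 0: pool or dead margin).
#' @param flowing_range Flowing-fraction range for non-slack patches.
#' @param nf_days,mlf_days Lengths of the natural-flow and
#'   modified-low-flow periods, days.
#' @param nf_discharge,mlf_discharge Mean discharge per period, m^3/s
#'   (`mlf_discharge < nf_discharge`).
#' @param temp_start,temp_end Water temperature at the start and end of the
#'   run, degC (linear seasonal decline plus a small fortnightly wiggle).
#' @param sunrise_range,sunset_range Sunrise/sunset hours at the start and
#'   end of the run (linear seasonal change).
#' @param prey_base_aquatic,prey_base_terrestrial Base drift densities per
#'   size class (1-3 .. 9-12 mm), prey/m^3.
#' @param prey_sample_every Days between invertebrate sampling occasions.
#' @param diel_anchors Dawn/midday/dusk multipliers for aquatic drift.
#' @param pred_stretch_frac Fraction of stretches holding pike at all
#'   (pike are lentic ambush predators and patchy at the stretch scale;
#'   the remaining stretches carry zero predator density).
#' @param pred_small_range,pred_large_range Ranges of stretch pike
#'   densities in occupied stretches, individuals/m^2 (low, as in lowland
#'   chalk streams).
#' @param veg_peak_cover Site-mean Ranunculus cover at its seasonal peak.
#' @param init_per_stretch Per-stretch initial population: a data frame
#'   with `species`, `cohort`, `count`, `mass_mean`, `mass_sd`, `tagged`.
#' @param seed Generator seed (byte-identical output per seed).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_stretches = 7, n_patches = 75,
                       area_mean = 39.6, area_sd = 14.15, area_min = 8,
                       width_range = c(4.5, 8),
                       slope_meanlog = log(0.0012), slope_sdlog = 0.35,
                       n_base = 0.035, k_veg = 1, k_slack = 0,
                       slack_prob = 0.35, flowing_range = c(0.4, 0.9),
                       nf_days = 68, mlf_days = 17,
                       nf_discharge = 1.8, mlf_discharge = 0.2,
                       temp_start = 17.5, temp_end = 13.8,
                       sunrise_range = c(5.0, 7.5),
                       sunset_range = c(21.3, 18.4),
                       prey_base_aquatic = c(5, 2.5, 1.2, 0.5, 0.25),
                       prey_base_terrestrial = c(1, 0.5, 0.25, 0.1, 0.05),
                       prey_sample_every = 30,
                       diel_anchors = c(1.6, 0.7, 1.7),
                       pred_stretch_frac = 0.43,
                       pred_small_range = c(0.004, 0.02),
                       pred_large_range = c(0.002, 0.01),
                       veg_peak_cover = 0.55,
                       init_per_stretch = NULL, seed = 7) {
  stopifnot(n_stretches >= 1, n_patches >= n_stretches,
            mlf_discharge < nf_discharge, nf_days >= 1, mlf_days >= 0)
  if (is.null(init_per_stretch)) {
    init_per_stretch <- data.frame(
      species = c("salmon", "trout", "trout"),
      cohort = c("YOY", "YOY", "1+"),
      count = c(12, 4, 2),
      mass_mean = c(3.5, 5, 30),
      mass_sd = c(1, 1.5, 8),
      tagged = c(5, 2, 1),
      stringsAsFactors = FALSE
    )
  }
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic chalk-stream environment
#'
#' Builds a complete `stream_env` from a [synth_spec()]: a linear patch
#' chain with stretch assignments and hydraulic geometry, a per-day global
#' series with the discharge step-down at the natural-flow boundary, prey
#' densities sampled at the specified cadence (interpolated between days at
#' run time; aquatic categories get the diel anchors), constant-in-time but
#' stretch-varying pike densities, and a seasonal per-patch vegetation
#' series. The same seed yields a byte-identical environment.
#'
#' @param spec A [synth_spec()].
#' @param dir Optional directory: when given, the environment file set is
#'   also written there via [write_environment()].
#' @return A validated `stream_env`, with the matching initial population
#'   table attached as attribute `"init"`.
#' @export
generate_environment <- function(spec = synth_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  np <- spec$n_patches
  ns <- spec$n_stretches
  n_days <- spec$nf_days + spec$mlf_days
  days <- 0:n_days

  # --- patches: one linear chain, contiguous stretches
  stretch_of <- sort(rep_len(seq_len(ns), np))
  area <- pmax(spec$area_min,
               stats::rnorm(np, spec$area_mean, spec$area_sd))
  slack <- stats::runif(np) < spec$slack_prob
  ff <- ifelse(slack, 0,
               stats::runif(np, spec$flowing_range[1], spec$flowing_range[2]))
  patches <- data.frame(
    patch_id = seq_len(np),
    stretch_id = stretch_of,
    area = area,
    upstream = c(NA, seq_len(np - 1)),
    downstream = c(seq_len(np)[-1], NA),
    flowing_fraction = ff,
    width = stats::runif(np, spec$width_range[1], spec$width_range[2]),
    slope = stats::rlnorm(np, spec$slope_meanlog, spec$slope_sdlog),
    n_base = spec$n_base, k_veg = spec$k_veg, k_slack = spec$k_slack
  )

  # --- global series: declining summer->autumn temperature, sharp
  # discharge drawdown at the natural-flow boundary
  frac <- days / max(n_days, 1)
  temperature <- spec$temp_start +
    (spec$temp_end - spec$temp_start) * frac +
    0.4 * sin(2 * pi * days / 14)
  discharge <- ifelse(days < spec$nf_days,
                      spec$nf_discharge * (1 + 0.05 * sin(2 * pi * days / 21)),
                      spec$mlf_discharge * (1 + 0.04 * sin(2 * pi * days / 21)))
  global_series <- data.frame(
    day = days,
    temperature = temperature,
    discharge = pmax(discharge, 0),
    sunrise = spec$sunrise_range[1] +
      (spec$sunrise_range[2] - spec$sunrise_range[1]) * frac,
    sunset = spec$sunset_range[1] +
      (spec$sunset_range[2] - spec$sunset_range[1]) * frac
  )

  # --- stretch series: prey sampled every `prey_sample_every` days with
  # stretch-level productivity factors; pike constant per stretch
  sample_days <- unique(c(seq(0, n_days, by = spec$prey_sample_every), n_days))
  n_pike <- max(1L, min(ns, round(spec$pred_stretch_frac * ns)))
  pike_stretches <- sort(sample.int(ns, n_pike))
  rows <- list()
  for (s in seq_len(ns)) {
    prod_fac <- stats::runif(1, 0.7, 1.3)
    for (c in 1:10) {
      base <- if (c <= 5) spec$prey_base_aquatic[c] else
        spec$prey_base_terrestrial[c - 5]
      vals <- pmax(0, base * prod_fac *
                     (1 + stats::runif(length(sample_days), -0.2, 0.2)))
      rows[[length(rows) + 1L]] <- data.frame(
        day = sample_days, stretch_id = s,
        series = paste0("prey_", c), value = vals
      )
    }
    occupied <- s %in% pike_stretches
    ps <- if (occupied) {
      stats::runif(1, spec$pred_small_range[1], spec$pred_small_range[2])
    } else {
      stats::runif(1) * 0 # keep the RNG stream aligned across specs
    }
    pl <- if (occupied) {
      stats::runif(1, spec$pred_large_range[1], spec$pred_large_range[2])
    } else {
      stats::runif(1) * 0
    }
    rows[[length(rows) + 1L]] <- data.frame(
      day = c(0, n_days), stretch_id = s, series = "pred_small", value = ps
    )
    rows[[length(rows) + 1L]] <- data.frame(
      day = c(0, n_days), stretch_id = s, series = "pred_large", value = pl
    )
  }
  stretch_series <- do.call(rbind, rows)

  # --- prey categories with diel anchors
  prey_categories <- prey_categories_default(
    anchors_aquatic = spec$diel_anchors
  )

  # --- vegetation: seasonal Ranunculus growth peaking mid-run, per-patch
  # multiplier; sampled at the prey cadence
  veg_days <- sample_days
  season <- spec$veg_peak_cover *
    exp(-((veg_days - 0.45 * n_days) / (0.45 * n_days))^2)
  vrows <- lapply(seq_len(np), function(j) {
    m <- stats::runif(1, 0.5, 1.2)
    data.frame(day = veg_days, patch_id = j,
               cover = pmin(0.95, pmax(0, season * m)))
  })
  vegetation_series <- do.call(rbind, vrows)

  env <- structure(list(
    patches = patches,
    global_series = global_series,
    stretch_series = stretch_series,
    prey_categories = prey_categories,
    vegetation_series = vegetation_series
  ), class = "stream_env")
  validate_environment(env)

  ips <- spec$init_per_stretch
  init <- do.call(rbind, lapply(seq_len(ns), function(s) {
    cbind(stretch_id = s, ips)
  }))
  attr(env, "init") <- init
  if (!is.null(dir)) {
    write_environment(env, dir)
    utils::write.csv(init, file.path(dir, "init_population.csv"),
                     row.names = FALSE)
  }
  env
}

#' Thin a truth run into synthetic PIT-tracking observations
#'
#' Emulates imperfect portable-detector tracking: each tagged-fish record
#' of a run's survey snapshots is kept independently with probability
#' `detection_prob`, producing "observed" tables in the schema the
#' validation readers expect. With `detection_prob = 1` the observed table
#' equals the truth snapshot.
#'
#' @param fish_snapshots The `fish` data frame of a `sim_result`.
#' @param detection_prob Detection probability in `(0, 1]`.
#' @param seed Seed for the thinning draws.
#' @param tagged_only Keep only tagged fish (the trackable ones).
#' @return A data frame of detected records with a `source = "observed"`
#'   column.
#' @export
generate_observations <- function(fish_snapshots, detection_prob = 0.45,
                                  seed = 1, tagged_only = TRUE) {
  stopifnot(detection_prob > 0, detection_prob <= 1)
  x <- fish_snapshots
  if (tagged_only) x <- x[x$tagged, ]
  set.seed(seed)
  keep <- stats::runif(nrow(x)) <= detection_prob
  out <- x[keep, , drop = FALSE]
  out$source <- "observed"
  rownames(out) <- NULL
  out
}
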