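# Simulation engine: hourly time loop, processing order (1+ before YOY,
# random order within a cohort), sequential within-step commitment of patch
# choices, death below the 1 g threshold, replicates and survey snapshots.
#
# Scheduling follows the platform order global -> stretch -> patch ->
# forager. Movement and feeding decisions are evaluated during daylight
# steps; at night the fish are obligate resters and hold position (their
# consumption would be identically zero everywhere, so any score-based rule
# would degenerate to a random walk).

# deterministic child seeds: one per (replicate, concern), kept < 2^31
child_seed <- function(master, replicate, concern) {
  ((master %% 65011) * 33029 + replicate * 1009 + concern) %% 2147483647L
}

resample <- function(x) if (length(x) <= 1L) x else x[sample.int(length(x))]

#' Build a simulation configuration
#'
#' @param env A `stream_env` object (raw environment).
#' @param init Initial population table: one row per stretch x species x
#'   cohort with columns `stretch_id`, `species`, `cohort`, `count`,
#'   `mass_mean`, `mass_sd`, `tagged` (number of tagged fish in the group).
#' @param species_params Species parameter table
#'   ([species_params_default()]).
#' @param n_days Run duration in days (hourly steps: `24 * n_days`).
#' @param nf_days Length of the natural-flow period in days; steps beyond
#'   it belong to the modified-low-flow period (used for per-period
#'   summaries).
#' @param rule Movement rule, one of [movement_rules()].
#' @param replicates Number of replicate simulations.
#' @param seed Master seed; every source of randomness in the run is
#'   derived from it deterministically.
#' @param survey_steps Steps (1-based) at which global, patch and fish
#'   snapshot records are written; surveys record state at the end of the
#'   step. Step 0 is always recorded as the initial population.
#' @param trace_order Record the cohort processing order of each daylight
#'   step (diagnostic; off by default).
#' @return A `sim_config` list.
#' @export
sim_config <- function(env, init, species_params = species_params_default(),
                       n_days = 85, nf_days = 68, rule = "CR_GT_PR",
                       replicates = 5, seed = 1,
                       survey_steps = NULL, trace_order = FALSE) {
  rule <- match.arg(rule, movement_rules())
  n_steps <- as.integer(24 * n_days)
  if (is.null(survey_steps)) {
    days <- unique(pmin(c(33, nf_days, n_days), n_days))
    survey_steps <- c(0, days * 24 - 12)  # midday of each survey day
  }
  stopifnot(replicates >= 1, n_steps > 0, nf_days <= n_days,
            all(survey_steps >= 0), all(survey_steps <= n_steps))
  structure(list(
    env = env, init = init, species_params = species_params,
    n_steps = n_steps, nf_end_step = as.integer(24 * nf_days),
    rule = rule, replicates = as.integer(replicates),
    seed = as.integer(seed), survey_steps = sort(unique(survey_steps)),
    trace_order = trace_order
  ), class = "sim_config")
}

#' Draw an initial fish population
#'
#' Each group row spawns `count` fish with starting mass drawn from
#' `Normal(mass_mean, mass_sd)` truncated below at the death threshold
#' (redrawn), fork length from the inverse length-mass relation, a
#' uniformly random starting patch within the group's stretch, and the
#' first `tagged` fish of the group flagged as tagged.
#'
#' @param init Initial population table (see [sim_config()]).
#' @param species_params Species parameter table.
#' @param patches Patch table of the environment.
#' @return A data frame with one row per fish: `fish_id`, `species`,
#'   `cohort`, `stretch_id`, `patch_id`, `mass`, `FL`, `ts`, `tagged`,
#'   `alive`.
#' @export
initialize_population <- function(init, species_params, patches) {
  rows <- list()
  fid <- 0L
  for (g in seq_len(nrow(init))) {
    n <- init$count[g]
    if (n <= 0) next
    pr <- species_params[species_params$species == init$species[g] &
                           species_params$cohort == init$cohort[g], ]
    if (nrow(pr) != 1L) {
      stop("no unique species parameter row for ",
           init$species[g], " ", init$cohort[g], call. = FALSE)
    }
    mu <- init$mass_mean[g]
    sd <- init$mass_sd[g]
    if (mu < pr$death_mass && sd == 0) {
      stop("initial mass below the death threshold with zero SD",
           call. = FALSE)
    }
    mass <- numeric(n)
    todo <- seq_len(n)
    guard <- 0L
    while (length(todo) > 0L) {
      mass[todo] <- stats::rnorm(length(todo), mu, sd)
      todo <- todo[mass[todo] < pr$death_mass]
      guard <- guard + 1L
      if (guard > 1000L) {
        stop("cannot draw initial masses above the death threshold",
             call. = FALSE)
      }
    }
    ppool <- patches$patch_id[patches$stretch_id == init$stretch_id[g]]
    patch <- ppool[sample.int(length(ppool), n, replace = TRUE)]
    ntag <- min(init$tagged[g], n)
    rows[[g]] <- data.frame(
      fish_id = fid + seq_len(n),
      species = init$species[g], cohort = init$cohort[g],
      stretch_id = init$stretch_id[g], patch_id = patch,
      mass = mass, FL = (mass / pr$a_W)^(1 / pr$b_W),
      ts = pr$ts, tagged = seq_len(n) <= ntag, alive = TRUE,
      stringsAsFactors = FALSE
    )
    fid <- fid + n
  }
  do.call(rbind, rows)
}

# One replicate of the hourly loop. `prep` is a prepared environment
# covering n_steps. Returns snapshots plus a per-fish summary.
run_replicate <- function(prep, cfg, replicate) {
  sp <- cfg$species_params
  set.seed(child_seed(cfg$seed, replicate, 1L))
  fish <- initialize_population(cfg$init, sp, prep$patches)
  n <- nrow(fish)
  prow <- match(paste(fish$species, fish$cohort),
                paste(sp$species, sp$cohort))
  # per-fish parameter vectors (flat, for the hot loop)
  aC <- sp$a_C[prow]; bC <- sp$b_C[prow]
  Tlo <- sp$T_low[prow]; Top <- sp$T_opt[prow]; Thi <- sp$T_high[prow]
  aR <- sp$a_R[prow]; bR <- sp$b_R[prow]; cR <- sp$c_R[prow]
  aS <- sp$a_S[prow]; bS <- sp$b_S[prow]; cS <- sp$c_S[prow]
  sda <- sp$sda[prow]; loss <- sp$loss_frac[prow]; rmm <- sp$rmax_mult[prow]
  ef <- sp$e_fish[prow]; aW <- sp$a_W[prow]; bW <- sp$b_W[prow]
  ts <- sp$ts[prow]; vbl <- sp$vmax_bl[prow]
  gam <- sp$pcs_gamma[prow]
  dmin <- sp$delta_min[prow]; dmax <- sp$delta_max[prow]
  dth <- sp$death_mass[prow]
  rdA <- sp$rd_alpha[prow]; rdB <- sp$rd_beta[prow]; vfl <- sp$v_floor[prow]
  is_yoy <- fish$cohort == "YOY"

  mass <- fish$mass; FL <- fish$FL; alive <- fish$alive
  patch_of <- match(fish$patch_id, prep$patches$patch_id)
  area <- prep$patches$area
  width <- prep$patches$width
  sid <- prep$stretch_index
  up <- prep$up_index; down <- prep$down_index
  mid <- prep$prey_categories$midpoint
  em <- prep$prey_categories$dry_mass * prep$prey_categories$energy_density

  n_patch <- nrow(prep$patches)
  nfish_patch <- tabulate(patch_of, n_patch)

  feed_sum_nf <- numeric(n); feed_n_nf <- 0L
  feed_sum_mlf <- numeric(n); feed_n_mlf <- 0L
  mass_nf_end <- mass
  gei_step <- numeric(n); resp_step <- numeric(n); feed_step <- numeric(n)

  snap_at <- rep(FALSE, cfg$n_steps)
  snap_at[cfg$survey_steps[cfg$survey_steps >= 1]] <- TRUE
  fish_snaps <- list(); patch_snaps <- list(); order_log <- list()

  if (0 %in% cfg$survey_steps) {
    fish_snaps[["s0"]] <- data.frame(
      replicate = replicate, step = 0L, fish_id = fish$fish_id,
      species = fish$species, cohort = fish$cohort,
      patch_id = prep$patches$patch_id[patch_of],
      stretch_id = prep$patches$stretch_id[patch_of],
      mass = mass, FL = FL, feed_fraction = 0, gei = 0, resp = 0,
      tagged = fish$tagged, alive = alive, stringsAsFactors = FALSE
    )
  }

  set.seed(child_seed(cfg$seed, replicate, 2L))
  fed_ts <- numeric(n_patch)
  for (t in seq_len(cfg$n_steps)) {
    Tt <- prep$temperature[t]
    velt <- prep$velocity[t, ]; dept <- prep$depth[t, ]
    fft <- prep$flowfrac[t, ]
    gei_step[] <- 0; resp_step[] <- 0; feed_step[] <- 0
    fed_ts[] <- 0
    if (!prep$is_day[t]) {
      # night: every fish rests in place (vectorised)
      idx <- which(alive)
      if (length(idx) > 0L) {
        v <- velt[patch_of[idx]]
        rs <- aR[idx] * mass[idx]^bR[idx] * exp(cR[idx] * Tt)
        rr <- pmin(rs + aS[idx] * mass[idx]^bS[idx] * (0.5 * v)^cS[idx],
                   rmm[idx] * rs)
        mass[idx] <- mass[idx] - rr / ef[idx]
        resp_step[idx] <- rr
      }
    } else {
      driftm <- prep$drift[t, , , drop = FALSE]
      dim(driftm) <- dim(prep$drift)[2:3]
      prS <- prep$pred_small[t, ]; prL <- prep$pred_large[t, ]
      ord <- c(resample(which(alive & !is_yoy)),
               resample(which(alive & is_yoy)))
      if (cfg$trace_order && length(ord) > 0L) {
        order_log[[length(order_log) + 1L]] <- data.frame(
          step = t, position = seq_along(ord),
          fish_id = fish$fish_id[ord], cohort = fish$cohort[ord],
          stringsAsFactors = FALSE
        )
      }
      for (i in ord) {
        cur <- patch_of[i]
        cand <- c(cur, up[cur], down[cur])
        cand <- cand[!is.na(cand)]
        nc <- length(cand)
        mi <- mass[i]
        fli <- FL[i]
        Vm <- vbl[i] * fli / 1000
        phi <- min((Tt - Tlo[i]) / (Top[i] - Tlo[i]),
                   (Thi[i] - Tt) / (Thi[i] - Top[i]), 1)
        cm <- if (phi > 0) aC[i] * mi^bC[i] * phi else 0
        RD <- rdA[i] * fli * (1 + rdB[i] * mid)
        edible <- mid >= dmin[i] * fli & mid <= dmax[i] * fli
        emv <- em * edible
        pot <- numeric(nc); rat <- numeric(nc)
        for (k in seq_len(nc)) {
          p <- cand[k]
          ninc <- nfish_patch[p] + (p != cur)
          ffp <- fft[p]
          # feeding feasibility: daylight (true here), flowing water, AFA>=TS
          afa <- area[p] * ffp - fed_ts[p]
          if (ffp > 0 && afa >= ts[i]) {
            v <- velt[p]
            if (v > 0 && v < Vm) {
              wpf <- width[p] / max(1, ninc)
              s <- pmin.int(pmin.int(2 * RD, dept[p]), wpf)
              RE <- driftm[sid[p], ] * v * (s * s) * 3600
              pcs <- max(0, 1 - gam[i] * v / Vm)
              HT <- RD / (Vm - v) + RD / max(v, vfl[i])
              pot[k] <- sum(pmin.int(RE * pcs, 3600 / HT) * emv)
            }
          }
          pdens <- if (is_yoy[i]) prS[sid[p]] + prL[sid[p]] else prL[sid[p]]
          rat[k] <- pdens * area[p] / max(1, ninc)
        }
        k_choice <- .select_patch(pot, rat, cm, cfg$rule)
        choice <- cand[k_choice]
        if (choice != cur) {
          nfish_patch[cur] <- nfish_patch[cur] - 1L
          nfish_patch[choice] <- nfish_patch[choice] + 1L
          patch_of[i] <- choice
        }
        v <- velt[choice]
        scf <- aS[i] * mi^bS[i] * v^cS[i]
        scr <- aS[i] * mi^bS[i] * (0.5 * v)^cS[i]
        f <- allocate_time(pot[k_choice], cm, scf, scr, sda[i], loss[i])
        if (f > 0) fed_ts[choice] <- fed_ts[choice] + ts[i]
        gei <- min(f * pot[k_choice], cm)
        rs <- aR[i] * mi^bR[i] * exp(cR[i] * Tt)
        rr <- min(rs + f * scf + (1 - f) * scr + sda[i] * gei, rmm[i] * rs)
        mass[i] <- mi + ((1 - loss[i]) * gei - rr) / ef[i]
        FL[i] <- max(fli, (max(mass[i], 1e-9) / aW[i])^(1 / bW[i]))
        gei_step[i] <- gei; resp_step[i] <- rr; feed_step[i] <- f
      }
      if (t <= cfg$nf_end_step) {
        feed_sum_nf <- feed_sum_nf + feed_step
        feed_n_nf <- feed_n_nf + 1L
      } else {
        feed_sum_mlf <- feed_sum_mlf + feed_step
        feed_n_mlf <- feed_n_mlf + 1L
      }
    }
    # deaths at end of step: mass below the threshold
    dead_now <- which(alive & mass < dth)
    if (length(dead_now) > 0L) {
      alive[dead_now] <- FALSE
      for (i in dead_now) {
        nfish_patch[patch_of[i]] <- nfish_patch[patch_of[i]] - 1L
      }
    }
    if (t == cfg$nf_end_step) mass_nf_end <- mass
    if (snap_at[t]) {
      keep <- which(alive)
      fish_snaps[[paste0("s", t)]] <- data.frame(
        replicate = replicate, step = t, fish_id = fish$fish_id[keep],
        species = fish$species[keep], cohort = fish$cohort[keep],
        patch_id = prep$patches$patch_id[patch_of[keep]],
        stretch_id = prep$patches$stretch_id[patch_of[keep]],
        mass = mass[keep], FL = FL[keep],
        feed_fraction = feed_step[keep], gei = gei_step[keep],
        resp = resp_step[keep], tagged = fish$tagged[keep],
        alive = alive[keep], stringsAsFactors = FALSE
      )
      fa <- pmax(0, area * prep$flowfrac[t, ] - fed_ts)
      patch_snaps[[paste0("s", t)]] <- data.frame(
        replicate = replicate, step = t, patch_id = prep$patches$patch_id,
        stretch_id = prep$patches$stretch_id,
        depth = prep$depth[t, ], velocity = prep$velocity[t, ],
        afa = fa, n_fish = nfish_patch, stringsAsFactors = FALSE
      )
    }
  }

  summary <- data.frame(
    replicate = replicate, fish_id = fish$fish_id,
    species = fish$species, cohort = fish$cohort,
    tagged = fish$tagged, start_mass = fish$mass,
    mass_nf_end = mass_nf_end, end_mass = mass, alive = alive,
    mean_feed_nf = if (feed_n_nf > 0) feed_sum_nf / feed_n_nf else 0,
    mean_feed_mlf = if (feed_n_mlf > 0) feed_sum_mlf / feed_n_mlf else 0,
    mean_feed_total = (feed_sum_nf + feed_sum_mlf) /
      max(1L, feed_n_nf + feed_n_mlf),
    stringsAsFactors = FALSE
  )
  list(
    fish = do.call(rbind, fish_snaps),
    patch = do.call(rbind, patch_snaps),
    summary = summary,
    order = if (cfg$trace_order) do.call(rbind, order_log) else NULL
  )
}

#' Run a configured simulation
#'
#' Executes all replicates of the hourly loop. Each replicate draws its own
#' deterministic child seeds from the master seed (one stream for
#' initialisation, one for the step loop), so the whole output bundle is a
#' pure function of the configuration.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_result` list: `fish` and `patch` snapshot data frames
#'   (rows per survey step), `summary` (one row per fish per replicate:
#'   start/end masses, natural-flow boundary mass, mean daylight feeding
#'   fraction per flow period, survival), `global` (per-step temperature,
#'   discharge, day flag), `order` (processing-order trace when enabled)
#'   and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prep <- prepare_environment(config$env, config$n_steps)
  reps <- lapply(seq_len(config$replicates), function(r) {
    run_replicate(prep, config, r)
  })
  structure(list(
    fish = do.call(rbind, lapply(reps, `[[`, "fish")),
    patch = do.call(rbind, lapply(reps, `[[`, "patch")),
    summary = do.call(rbind, lapply(reps, `[[`, "summary")),
    order = do.call(rbind, lapply(reps, `[[`, "order")),
    global = data.frame(
      step = seq_len(config$n_steps),
      temperature = prep$temperature, discharge = prep$discharge,
      is_day = prep$is_day
    ),
    config = config
  ), class = "sim_result")
}

#' Per-fish specific growth rates from a run summary
#'
#' Computes, for every fish of a run, the SGR over the whole run and over
#' each flow period, using the run's start, natural-flow-boundary and final
#' masses. Fish that died keep the mass they held at removal.
#'
#' @param result A `sim_result`.
#' @return The summary data frame with `sgr_total`, `sgr_nf` and `sgr_mlf`
#'   columns appended (percent body mass per day; `sgr_mlf` is `NA` when
#'   the run has no modified-low-flow period).
#' @export
summary_sgr <- function(result) {
  s <- result$summary
  cfg <- result$config
  nf_days <- cfg$nf_end_step / 24
  total_days <- cfg$n_steps / 24
  safe <- function(a, b, d) {
    ifelse(a > 0 & b > 0, 100 * (log(b) - log(a)) / d, NA_real_)
  }
  s$sgr_total <- safe(s$start_mass, s$end_mass, total_days)
  s$sgr_nf <- safe(s$start_mass, s$mass_nf_end, nf_days)
  s$sgr_mlf <- if (total_days > nf_days) {
    safe(s$mass_nf_end, s$end_mass, total_days - nf_days)
  } else {
    NA_real_
  }
  s
}
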