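# Pattern-oriented validation: the four patterns (body mass, specific
# growth rate, stretch distribution, patch occupancy) computed identically
# from observed and simulated survey records, scored by Pearson r, mean
# absolute error, and a seeded bootstrap percentile interval on the mean
# SGR difference (the decision criterion: does the 95% interval of the
# difference include zero?). Plus the one-at-a-time sensitivity driver.

#' Specific growth rates from recaptured tagged fish
#'
#' For every fish with at least two mass records at distinct days, the SGR
#' between its first and last record; single-capture fish are excluded.
#' Records need columns `fish_id`, `day`, `mass` (and optionally grouping
#' columns the caller has already filtered on).
#'
#' @param records Data frame of capture/recapture (or snapshot) records.
#' @return Data frame with one row per recaptured fish: `fish_id`,
#'   `day_start`, `day_end`, `mass_start`, `mass_end`, `sgr`. Empty (with
#'   a warning) when there are no recaptures.
#' @export
sgr_from_recaptures <- function(records) {
  stopifnot(all(c("fish_id", "day", "mass") %in% names(records)))
  records <- records[!is.na(records$mass), ]
  out <- lapply(split(records, records$fish_id), function(r) {
    r <- r[order(r$day), ]
    if (nrow(r) < 2L || r$day[1] == r$day[nrow(r)]) return(NULL)
    data.frame(
      fish_id = r$fish_id[1],
      day_start = r$day[1], day_end = r$day[nrow(r)],
      mass_start = r$mass[1], mass_end = r$mass[nrow(r)],
      sgr = sgr(r$mass[1], r$mass[nrow(r)], r$day[1], r$day[nrow(r)])
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    warning("no recaptured fish in records", call. = FALSE)
    return(data.frame(fish_id = integer(), day_start = numeric(),
                      day_end = numeric(), mass_start = numeric(),
                      mass_end = numeric(), sgr = numeric()))
  }
  rownames(out) <- NULL
  out
}

#' Population distribution across stretches
#'
#' Counts records per stretch, removes stretches whose electric-fishing
#' capture probability is below `p_min`, and normalises the retained
#' counts to percentages summing to 100.
#'
#' @param records Data frame with a `stretch_id` column.
#' @param capture_prob Named numeric vector (names = stretch ids) of
#'   capture probabilities; stretches not listed default to 1.
#' @param p_min Minimum capture probability for retention.
#' @return Data frame `stretch_id`, `count`, `percent` over retained
#'   stretches (empty, with a warning, if every stretch is filtered).
#' @export
stretch_distribution <- function(records, capture_prob = NULL, p_min = 0.2) {
  stopifnot("stretch_id" %in% names(records), nrow(records) > 0)
  cnt <- table(records$stretch_id)
  ids <- names(cnt)
  p <- rep(1, length(ids))
  if (!is.null(capture_prob)) {
    hit <- match(ids, names(capture_prob))
    p[!is.na(hit)] <- capture_prob[hit[!is.na(hit)]]
  }
  keep <- p >= p_min
  if (!any(keep)) {
    warning("all stretches filtered by capture probability", call. = FALSE)
    return(data.frame(stretch_id = character(), count = integer(),
                      percent = numeric()))
  }
  cnt <- cnt[keep]
  data.frame(
    stretch_id = names(cnt),
    count = as.integer(cnt),
    percent = 100 * as.integer(cnt) / sum(cnt),
    stringsAsFactors = FALSE
  )
}

#' Tagged-fish occupancy per patch
#'
#' Mean and standard error of the number of tagged fish recorded per patch
#' across the listed survey steps (and across replicates for simulated
#' data). Patches never occupied get mean 0 — the gaps of the observed
#' pattern. With a single survey-replicate the SE is undefined and
#' reported as 0 with `se_defined = FALSE`.
#'
#' @param records Snapshot/tracking records with `patch_id`, `step` and
#'   (for simulated data) `replicate` columns; a logical `tagged` column is
#'   honoured when present.
#' @param survey_steps Steps over which to average.
#' @param patch_ids Full patch universe (so empty patches appear).
#' @param tagged_only Restrict to tagged fish.
#' @return Data frame `patch_id`, `mean`, `se`, `se_defined`.
#' @export
patch_occupancy <- function(records, survey_steps, patch_ids,
                            tagged_only = TRUE) {
  stopifnot(all(c("patch_id", "step") %in% names(records)))
  x <- records[records$step %in% survey_steps, ]
  if (tagged_only && "tagged" %in% names(x)) x <- x[x$tagged, ]
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  reps <- if (nrow(x) > 0) unique(x$replicate) else 1L
  cells <- expand.grid(replicate = reps, step = survey_steps)
  counts <- matrix(0, nrow(cells), length(patch_ids))
  for (r in seq_len(nrow(cells))) {
    sub <- x[x$replicate == cells$replicate[r] & x$step == cells$step[r], ]
    counts[r, ] <- tabulate(match(sub$patch_id, patch_ids),
                            length(patch_ids))
  }
  m <- colMeans(counts)
  nsur <- nrow(cells)
  se_def <- nsur > 1L
  se <- if (se_def) apply(counts, 2, stats::sd) / sqrt(nsur) else
    rep(0, length(patch_ids))
  data.frame(patch_id = patch_ids, mean = m, se = se, se_defined = se_def)
}

#' Score an observed-vs-predicted pattern
#'
#' Pearson's r and mean absolute error across aligned units, plus a seeded
#' bootstrap percentile interval (default 10^4 resamples) of the
#' difference in means `mean(predicted samples) - mean(observed samples)`
#' and whether zero lies inside it — the pattern-match decision criterion.
#' When per-individual samples are not supplied the unit values double as
#' samples.
#'
#' @param observed,predicted Aligned numeric unit values (same stretches /
#'   patches / groups, same order).
#' @param observed_samples,predicted_samples Optional per-individual
#'   samples (e.g. per-fish SGRs) for the bootstrap mean difference.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @param level Interval coverage (default 95%).
#' @return A `pattern_report` list: `n_units`, `pearson_r` (NA with fewer
#'   than 3 units), `mae`, `mean_diff`, `boot_lower`, `boot_upper`,
#'   `zero_in_interval`.
#' @export
match_patterns <- function(observed, predicted,
                           observed_samples = observed,
                           predicted_samples = predicted,
                           n_boot = 10000, seed = 1, level = 0.95) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  obs <- observed[ok]; pred <- predicted[ok]
  r <- if (length(obs) >= 3L && stats::sd(obs) > 0 && stats::sd(pred) > 0) {
    stats::cor(obs, pred)
  } else {
    NA_real_
  }
  mae <- if (length(obs) > 0) mean(abs(pred - obs)) else NA_real_
  os <- observed_samples[is.finite(observed_samples)]
  ps <- predicted_samples[is.finite(predicted_samples)]
  if (length(os) > 0 && length(ps) > 0) {
    set.seed(seed)
    bo <- matrix(sample(os, n_boot * length(os), replace = TRUE), n_boot)
    bp <- matrix(sample(ps, n_boot * length(ps), replace = TRUE), n_boot)
    diffs <- rowMeans(bp) - rowMeans(bo)
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(diffs, c(alpha, 1 - alpha)))
    md <- mean(ps) - mean(os)
  } else {
    ci <- c(NA_real_, NA_real_); md <- NA_real_
  }
  structure(list(
    n_units = length(obs), pearson_r = r, mae = mae,
    mean_diff = md, boot_lower = ci[1], boot_upper = ci[2],
    zero_in_interval = if (all(is.finite(ci))) ci[1] <= 0 && ci[2] >= 0
    else NA
  ), class = "pattern_report")
}

#' One-at-a-time parameter sensitivity of predicted growth
#'
#' Perturbs each listed species-parameter column by `+delta` and `-delta`
#' (all rows at once), re-runs the simulation with the identical master
#' seed, and reports the change in population mean SGR against the
#' unadjusted run. Perturbations producing an invalid parameterisation
#' (e.g. a loss fraction of 1 or more) are flagged and skipped.
#'
#' @param env Stream environment.
#' @param init Initial population table.
#' @param parameters Character vector of [species_params_default()] column
#'   names to perturb.
#' @param delta Relative perturbation (default 0.05, i.e. +/-5%).
#' @param species_params Baseline parameter table.
#' @param rule Movement rule for all runs.
#' @param n_days,nf_days,replicates,seed Passed to [sim_config()]; the
#'   same seed is used for every variant so differences are attributable
#'   to the perturbation alone.
#' @return Data frame `parameter`, `direction`, `delta_sgr` (perturbed
#'   minus baseline mean SGR, % body mass/day; NA when skipped), `valid`;
#'   ordered by decreasing `max |delta_sgr|` per parameter.
#' @export
sensitivity_analysis <- function(env, init, parameters, delta = 0.05,
                                 species_params = species_params_default(),
                                 rule = "CR_GT_PR", n_days = 68,
                                 nf_days = n_days, replicates = 1,
                                 seed = 1) {
  stopifnot(all(parameters %in% names(species_params)))
  mean_sgr <- function(sp) {
    cfg <- sim_config(env, init, species_params = sp, n_days = n_days,
                      nf_days = nf_days, rule = rule,
                      replicates = replicates, seed = seed)
    s <- summary_sgr(run_simulation(cfg))
    mean(s$sgr_total, na.rm = TRUE)
  }
  base <- mean_sgr(species_params)
  rows <- list()
  for (p in parameters) {
    for (dir in c(+1, -1)) {
      sp2 <- species_params
      sp2[[p]] <- sp2[[p]] * (1 + dir * delta)
      valid <- all(sp2$loss_frac < 1) && all(sp2$sda < 1) &&
        all(sp2$e_fish > 0) && all(sp2$T_low < sp2$T_opt) &&
        all(sp2$T_opt < sp2$T_high)
      dsgr <- if (valid) mean_sgr(sp2) - base else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, direction = ifelse(dir > 0, "up", "down"),
        delta_sgr = dsgr, valid = valid, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rank <- tapply(abs(out$delta_sgr), out$parameter, max, na.rm = TRUE)
  out$rank_stat <- as.numeric(rank[out$parameter])
  out[order(-out$rank_stat, out$parameter, out$direction), ]
}
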