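# Habitat selection and within-step behaviour: the four movement rules,
# territory-limited feeding space (AFA), patch-scale predation risk, and
# the optimal feed/rest time split.

#' The four habitat selection rules
#'
#' `RANDOM` moves uniformly among reachable patches; `MCR` maximises the
#' (potential) consumption rate; `MPR` minimises the patch predator:prey
#' ratio; `CR_GT_PR` considers risk only where consumption reaches Cmax —
#' if at least one reachable patch supports a consumption rate at or above
#' Cmax the fish picks the lowest-ratio patch among those (ratio ties broken
#' by consumption rate, then at random), otherwise it behaves as `MCR`.
#'
#' @return Character vector of the four rule names.
#' @export
movement_rules <- function() c("RANDOM", "MCR", "MPR", "CR_GT_PR")

#' Available feeding area of a patch
#'
#' The flowing area left after subtracting the territories of the fish
#' currently feeding there, floored at zero:
#' `AFA = max(0, area * flowing_fraction - sum TS(feeding fish))`.
#'
#' @param area Patch area, m^2.
#' @param flowing_fraction Flowing share of the patch in `[0, 1]`.
#' @param ts_feeding Total territory size of currently feeding fish, m^2.
#' @return AFA, m^2 (never negative).
#' @export
available_feeding_area <- function(area, flowing_fraction, ts_feeding = 0) {
  pmax(0, area * flowing_fraction - ts_feeding)
}

#' Can a fish establish a feeding territory here now?
#'
#' Virtual fish are diurnal obligate drift feeders that can only feed in
#' flowing water and only where the available feeding area covers their
#' territory: feeding requires daylight, a positive flowing fraction and
#' `AFA >= TS`. A fish failing the test may still occupy the patch, but
#' only rest.
#'
#' @param is_day Logical: is it daylight?
#' @param flowing_fraction Flowing share of the patch.
#' @param afa Available feeding area, m^2.
#' @param ts The fish's territory size, m^2.
#' @return Logical.
#' @export
can_feed <- function(is_day, flowing_fraction, afa, ts) {
  is_day & flowing_fraction > 0 & afa >= ts
}

#' Patch predator:prey ratio
#'
#' Gape-limited risk index: YOY fish are vulnerable to both pike size
#' classes and count small and large predators; 1+ fish only count large
#' ones. The applicable predator count is density times patch area; the
#' denominator is the number of fish in the patch including the evaluating
#' fish (so it is at least 1 and the ratio is always finite).
#'
#' @param cohort `"YOY"` or `"1+"`.
#' @param pred_small,pred_large Predator densities, individuals/m^2.
#' @param area Patch area, m^2.
#' @param n_fish Number of fish in the patch including the evaluating fish
#'   (>= 1).
#' @return Non-negative finite ratio.
#' @export
predator_prey_ratio <- function(cohort, pred_small, pred_large, area, n_fish) {
  stopifnot(all(pred_small >= 0), all(pred_large >= 0), all(n_fish >= 1))
  dens <- if (identical(cohort, "YOY")) pred_small + pred_large else pred_large
  dens * area / n_fish
}

#' Reachable patches within one step
#'
#' Movement in a time step is limited to one patch distance up- or
#' downstream: the candidate set is the current patch plus its existing
#' neighbours on the linear chain.
#'
#' @param patch_id Current patch id.
#' @param upstream,downstream Neighbour ids (NA at the chain ends).
#' @return Integer vector of 1-3 candidate patch ids (current first).
#' @export
candidate_patches <- function(patch_id, upstream = NA, downstream = NA) {
  out <- c(patch_id, upstream, downstream)
  out[!is.na(out)]
}

# draw uniformly among tied indices, consuming one RNG draw only when there
# is a real tie (keeps RNG streams aligned across rules)
pick_tied <- function(idx) {
  if (length(idx) > 1L) idx[sample.int(length(idx), 1L)] else idx
}

#' Choose a patch under a movement rule
#'
#' Scores are evaluated per candidate with feeding feasibility honoured
#' upstream: a candidate where the fish could not feed carries potential 0.
#' `RANDOM` draws uniformly; `MCR` takes the argmax of the potential
#' consumption rate; `MPR` the argmin of the predator:prey ratio;
#' `CR_GT_PR` takes, if any candidate's consumption reaches Cmax, the
#' lowest-ratio candidate among those (ties broken by higher consumption,
#' then uniformly at random), and otherwise falls back to `MCR`. Exact
#' score ties are always broken uniformly at random.
#'
#' @param potential Potential consumption rate (kJ/h) per candidate,
#'   0 where the fish cannot feed.
#' @param ratio Predator:prey ratio per candidate.
#' @param cmax The fish's current Cmax, kJ/h.
#' @param rule One of [movement_rules()].
#' @return Index into the candidate vectors of the chosen patch.
#' @export
select_patch <- function(potential, ratio, cmax, rule = movement_rules()) {
  rule <- match.arg(rule)
  stopifnot(length(potential) >= 1L, length(ratio) == length(potential))
  .select_patch(potential, ratio, cmax, rule)
}

# validation-free core used by the scheduler's hot loop
.select_patch <- function(potential, ratio, cmax, rule) {
  if (rule == "RANDOM") {
    return(sample.int(length(potential), 1L))
  }
  if (rule == "MPR") {
    return(pick_tied(which(ratio == min(ratio))))
  }
  if (rule == "CR_GT_PR" && cmax > 0) {
    reach <- which(potential >= cmax)
    if (length(reach) > 0L) {
      r <- ratio[reach]
      t1 <- reach[r == min(r)]
      p1 <- potential[t1]
      return(pick_tied(t1[p1 == max(p1)]))
    }
  }
  # MCR, and the CR_GT_PR fallback when no candidate reaches Cmax
  pick_tied(which(potential == max(potential)))
}

#' Optimal feed/rest split for one step
#'
#' A fish spends a fraction `f` of the hour feeding and the rest resting;
#' it picks the fraction maximising that step's net energy. Intake is
#' clamped at Cmax, so feeding beyond `f* = min(1, Cmax / potential)` only
#' adds swimming cost: the maximiser is `f*` when the marginal net gain of
#' feeding, `(1 - loss_frac - sda) * potential - (SC_feed - SC_rest)`, is
#' positive, and 0 otherwise (resting dominates when the feeding premium
#' exceeds the assimilable intake).
#'
#' @param potential Potential consumption rate in the patch, kJ/h (0 when
#'   the fish cannot feed).
#' @param cmax Maximum hourly consumption, kJ/h.
#' @param sc_feed,sc_rest Hourly swimming cost while feeding / resting, kJ/h.
#' @param sda Digestion cost fraction of intake.
#' @param loss_frac Faecal/urinary loss fraction.
#' @return Feed fraction in `[0, 1]`.
#' @export
allocate_time <- function(potential, cmax, sc_feed, sc_rest,
                          sda = 0.14, loss_frac = 0.31) {
  if (potential <= 0 || cmax <= 0) {
    return(0)
  }
  slope <- (1 - loss_frac - sda) * potential - (sc_feed - sc_rest)
  if (slope > 0) min(1, cmax / potential) else 0
}
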