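# Quasi-1D hydraulic submodel: discharge + seasonal macrophyte (Ranunculus)
# cover -> per-patch mean depth and velocity, via Manning uniform flow in a
# rectangular channel with vegetation-scaled roughness.

#' Per-patch depth and velocity from discharge and vegetation cover
#'
#' Solves the rectangular-channel uniform-flow balance
#' `Q = w * d * v` with `v = (1 / n_eff) * d^(2/3) * sqrt(S)` where the
#' effective Manning roughness is `n_eff = n_base * (1 + k_veg * cover)`.
#' For a rectangular channel (hydraulic radius approximated by depth) the
#' balance has the closed-form root
#' `d = (Q * n_eff / (w * sqrt(S)))^(3/5)`, which is the unique
#' non-negative solution; velocity follows from continuity `v = Q / (w d)`.
#' Zero discharge gives zero depth and velocity.
#'
#' All arguments are vectorised over patches.
#'
#' @param discharge River discharge, m^3/s (>= 0).
#' @param width Effective channel width, m (> 0).
#' @param slope Bed slope (> 0, dimensionless).
#' @param n_base Baseline Manning roughness.
#' @param k_veg Roughness inflation per unit vegetation cover.
#' @param cover Macrophyte cover fraction in `[0, 1]`.
#' @return A list with `depth` (m) and `velocity` (m/s); continuity
#'   `|w d v - Q| / max(Q, eps) <= 1e-6` holds for every `Q > 0`.
#' @export
patch_hydraulics <- function(discharge, width, slope, n_base = 0.035,
                             k_veg = 1, cover = 0) {
  if (any(width <= 0) || any(slope <= 0)) {
    stop("width and slope must be positive", call. = FALSE)
  }
  if (any(discharge < 0)) stop("discharge must be >= 0", call. = FALSE)
  if (any(cover < 0 | cover > 1)) stop("cover must lie in [0, 1]", call. = FALSE)
  n_eff <- n_base * (1 + k_veg * cover)
  d <- (discharge * n_eff / (width * sqrt(slope)))^(3 / 5)
  v <- ifelse(d > 0, discharge / (width * d), 0)
  list(depth = d, velocity = v)
}

#' Flowing fraction of a patch under vegetation encroachment
#'
#' Links macrophyte growth to the share of a patch that is flowing (vs.
#' slack water): `flowing = base * (1 - k_slack * cover)`, clipped to
#' `[0, 1]`. With the default `k_slack = 0` the base flowing fraction is
#' returned unchanged.
#'
#' @param base Base flowing fraction in `[0, 1]`.
#' @param cover Vegetation cover fraction in `[0, 1]`.
#' @param k_slack Slack-water expansion coefficient per unit cover.
#' @return Flowing fraction in `[0, 1]`.
#' @export
flowing_fraction_at <- function(base, cover, k_slack = 0) {
  pmin(1, pmax(0, base * (1 - k_slack * cover)))
}
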