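# Turtle internal states. Transitions follow the nesting-migration-foraging
# cycle: feeding -> {foraging_migration, prenesting}; foraging_migration ->
# feeding; prenesting -> nesting; nesting -> postnesting; postnesting ->
# feeding.
TURTLE_STATES <- c("feeding", "prenesting", "postnesting", "nesting",
                   "foraging_migration")
ST_FEEDING <- 1L
ST_PRENESTING <- 2L
ST_POSTNESTING <- 3L
ST_NESTING <- 4L
ST_FORAGING <- 5L

# Legal state-machine edges, as from-to integer pairs.
LEGAL_TRANSITIONS <- rbind(
  c(ST_FEEDING, ST_FORAGING),
  c(ST_FEEDING, ST_PRENESTING),
  c(ST_FORAGING, ST_FEEDING),
  c(ST_PRENESTING, ST_NESTING),
  c(ST_NESTING, ST_POSTNESTING),
  c(ST_POSTNESTING, ST_FEEDING))

#' Per-step probability of leaving a feeding patch
#'
#' A feeding turtle leaves its patch with probability
#' `P_leave = (1 - S_F) / 1000 * (1 - logistic((phi - b) / a))`,
#' a decreasing logistic response to the patch resource level `phi`: patches
#' above the leaving threshold `b` are almost never abandoned, depleted
#' patches are left at up to 1/1000 per step, and the foraging
#' patch-fidelity strategy `S_F` scales the whole curve (S_F = 1, a
#' "stayer", never leaves; S_F = 0, a "mover", is most prone to leave).
#'
#' @param phi Patch resource level (vectorized, >= 0).
#' @param s_f Foraging patch-fidelity strategy in `[0, 1]`.
#' @param a Steepness of the response (> 0, resource units).
#' @param b Leaving threshold (resource units).
#' @return Probability per half-day step, in `[0, 1e-3]`.
#' @export
leave_probability <- function(phi, s_f, a, b) {
  if (any(a <= 0)) stop("steepness a must be positive")
  stopifnot(all(s_f >= 0 & s_f <= 1), all(phi >= 0))
  (1 - s_f) / 1000 * (1 - stats::plogis((phi - b) / a))
}

# Distance-decay selection weights over candidate patches: w = (1 - d_rel)^l
# with d_rel = (d - d_min) / (d_max - d_min) clamped to [0, 1].
patch_choice_weights <- function(d, d_min, d_max, lambda_decay) {
  if (d_max <= d_min) return(0 * d + 1)  # all candidates equidistant
  d_rel <- (d - d_min) / (d_max - d_min)
  d_rel <- pmin(pmax(d_rel, 0), 1)
  (1 - d_rel)^lambda_decay
}

#' Choose a new feeding patch by distance decay
#'
#' Samples a destination patch (different from the current one) with
#' probability proportional to `(1 - d_relative)^lambda`, where
#' `d_relative` rescales the distance from the current patch into `[0, 1]`
#' using the minimum and maximum pairwise patch distances of the landscape.
#' Nearby patches are strongly preferred: turtles know the locations of
#' patches, not their resource levels, and knowledge decays with distance.
#' If every candidate has zero weight (all at the maximum distance) the
#' draw falls back to uniform.
#'
#' @param current_patch Identifier of the patch being left.
#' @param patch_registry Data frame with `patch_id`, `x_km`, `y_km` (>= 2
#'   rows).
#' @param lambda_decay Decay exponent (default 5).
#' @param d_min,d_max Minimum/maximum pairwise patch distance (km),
#'   `d_max > d_min`.
#' @return The chosen `patch_id`.
#' @export
choose_new_patch <- function(current_patch, patch_registry, lambda_decay,
                             d_min, d_max) {
  cand <- patch_registry[patch_registry$patch_id != current_patch, ]
  if (nrow(cand) == 0L) stop("no candidate patch to choose from")
  cur <- patch_registry[patch_registry$patch_id == current_patch, ]
  d <- sqrt((cand$x_km - cur$x_km)^2 + (cand$y_km - cur$y_km)^2)
  w <- patch_choice_weights(d, d_min, d_max, lambda_decay)
  if (sum(w) <= 0) w <- rep(1, length(w))
  cand$patch_id[sample.int(length(w), 1L, prob = w)]
}

#' Energy required for a full nesting cycle
#'
#' The capital-breeding threshold: a turtle starts its pre-nesting migration
#' only once its stored energy covers the round-trip migration plus the
#' nesting effort,
#' `eps_cycle = 2 * delta_eps_m * (d / c) + S_N * T_n_max * delta_eps_n`,
#' with `d` the distance from the feeding patch to the natal nesting site
#' and `c` the swimming speed (so `d / c` is the one-way travel time in
#' days).
#'
#' @param distance_to_nest Distance from the current feeding patch to the
#'   nesting site (km; vectorized).
#' @param c_speed Swimming speed (km/day, > 0).
#' @param s_n Nesting allocation strategy in `[0, 1]`.
#' @param t_n_max Maximum nesting duration (days).
#' @param delta_eps_m Migration cost (energy/day).
#' @param delta_eps_n Nesting cost (energy/day).
#' @return Required energy (same units as the energy budget).
#' @export
cycle_energy_requirement <- function(distance_to_nest, c_speed, s_n, t_n_max,
                                     delta_eps_m, delta_eps_n) {
  if (c_speed <= 0) stop("swimming speed must be positive")
  stopifnot(delta_eps_m >= 0, delta_eps_n >= 0)
  2 * delta_eps_m * distance_to_nest / c_speed + s_n * t_n_max * delta_eps_n
}

#' Number of half-day steps spent nesting
#'
#' The nesting duration is `T_n = S_N * T_n_max` days, i.e.
#' `round(2 * S_N * T_n_max)` half-day steps: an "investment" strategy
#' (S_N near 1) nests long and expensively, a "conservative" one (S_N near
#' 0) briefly and cheaply.
#'
#' @param s_n Nesting allocation strategy in `[0, 1]`.
#' @param t_n_max Maximum nesting duration (days).
#' @return Number of half-day steps.
#' @export
nesting_duration_steps <- function(s_n, t_n_max) {
  stopifnot(all(s_n >= 0 & s_n <= 1))
  as.integer(round(2 * s_n * t_n_max))
}

#' Should a feeding turtle start its pre-nesting migration?
#'
#' True exactly when stored energy has reached the cycle requirement from
#' the current feeding patch to the natal nesting site (threshold inclusive).
#'
#' @param energy Current energy level (vectorized).
#' @param eps_cycle Cycle requirement from [cycle_energy_requirement()].
#' @return Logical.
#' @export
should_start_prenesting <- function(energy, eps_cycle) {
  energy >= eps_cycle
}
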