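#' Regrowth coefficient balancing depletion at even occupancy
#'
#' The logistic regrowth coefficient beta is calibrated so that, with the
#' turtle population spread evenly over the patches (occupancy `N_T / N_F`),
#' patch resource levels are stationary at half the carrying capacity:
#' `beta = 2 * alpha * N_T / N_F`.
#'
#' @param alpha Depletion coefficient (per day).
#' @param n_turtles Total number of turtles `N_T`.
#' @param n_patches Number of feeding patches `N_F`.
#' @return `beta`, the daily logistic regrowth coefficient.
#' @export
regrowth_coefficient <- function(alpha, n_turtles, n_patches) {
  if (alpha <= 0 || n_turtles <= 0 || n_patches <= 0) {
    stop("alpha, n_turtles and n_patches must all be positive")
  }
  2 * alpha * n_turtles / n_patches
}

#' One resource-dynamics update of feeding patches
#'
#' Applies the per-step net growth
#' `dPhi = beta * Phi * (1 - Phi / phi_max) - alpha * N * Phi`
#' (logistic regrowth minus density-dependent grazing by `N` feeding
#' turtles) and clamps the result to `[0, phi_max]`. Vectorized over
#' patches. `beta` and `alpha` must already be per-step rates (i.e. daily
#' values divided by the number of steps per day).
#'
#' @param phi Current resource levels (vector).
#' @param occupancy Number of turtles feeding on each patch (vector).
#' @param beta Per-step regrowth coefficient.
#' @param alpha Per-step depletion coefficient.
#' @param phi_max Carrying capacity, common to all patches.
#' @return Updated resource levels.
#' @export
update_patch_resource <- function(phi, occupancy, beta, alpha, phi_max) {
  dphi <- beta * phi * (1 - phi / phi_max) - alpha * occupancy * phi
  pmin(pmax(phi + dphi, 0), phi_max)
}

#' Perturbation forcing
#'
#' A perturbation is a latitude band of reduced seagrass productivity,
#' defined by a latitude `sigma_y` (degrees), an intensity `sigma_i`, and a
#' maximum range of action `d_sigma_max` (degrees latitude).
#'
#' @param sigma_y Perturbation latitude (degrees).
#' @param sigma_i Intensity (dimensionless, >= 0).
#' @param d_sigma_max Maximum range of action (degrees latitude, > 0).
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(sigma_y, sigma_i, d_sigma_max) {
  stopifnot(sigma_i >= 0, d_sigma_max > 0)
  structure(list(sigma_y = sigma_y, sigma_i = sigma_i,
                 d_sigma_max = d_sigma_max), class = "perturbation")
}

#' Apply a perturbation to patch resource levels
#'
#' Patches whose latitude lies within `d_sigma_max` degrees of the
#' perturbation latitude lose
#' `sigma_i * beta * (d_sigma_max / d) * Phi` per step, where `d` is the
#' latitudinal distance to the perturbation; patches outside the range are
#' unaffected. The `1/d` factor diverges as a patch approaches the
#' perturbation latitude, so `d` is floored at one cell's latitude extent
#' and the result clamped at zero, making the operator total.
#'
#' @param phi Patch resource levels (vector).
#' @param patch_lat Patch latitudes in degrees (vector, from
#'   [latitude_of()]).
#' @param pert A [perturbation()] object.
#' @param beta Per-step regrowth coefficient.
#' @param d_floor_deg Floor on the latitudinal distance (degrees); default
#'   one 7 km cell (~0.0693 deg).
#' @return Reduced resource levels.
#' @export
apply_perturbation <- function(phi, patch_lat, pert, beta,
                               d_floor_deg = 7 / 101) {
  d <- abs(patch_lat - pert$sigma_y)
  hit <- d < pert$d_sigma_max
  if (any(hit)) {
    dphi <- pert$sigma_i * beta * (pert$d_sigma_max / pmax(d[hit], d_floor_deg)) *
      phi[hit]
    phi[hit] <- pmax(phi[hit] - dphi, 0)
  }
  phi
}

#' Per-step energy gain from feeding
#'
#' A feeding turtle gains `alpha * Phi` per step (the same depletion
#' coefficient links individual intake and patch loss, so energy bookkeeping
#' is consistent with [update_patch_resource()]).
#'
#' @param phi Patch resource level (vector).
#' @param alpha Per-step depletion coefficient.
#' @return Energy gain per step.
#' @export
net_energy_gain <- function(phi, alpha) {
  stopifnot(all(phi >= 0))
  alpha * phi
}

#' Analytic resource equilibrium under constant occupancy
#'
#' For constant occupancy `N`, the resource dynamics have the fixed point
#' `Phi* = phi_max * (1 - alpha * N / beta)` when positive, else 0. With
#' `beta` from [regrowth_coefficient()] and `N = N_T / N_F`, this is
#' `phi_max / 2`.
#'
#' @param occupancy Constant occupancy `N`.
#' @param beta,alpha Rates on a common time base.
#' @param phi_max Carrying capacity.
#' @return The equilibrium resource level.
#' @export
resource_equilibrium <- function(occupancy, beta, alpha, phi_max) {
  pmax(phi_max * (1 - alpha * occupancy / beta), 0)
}
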