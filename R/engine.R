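#' Simulation configuration
#'
#' Collects every model parameter. All rates are stored in daily units; the
#' engine converts them once to half-day steps (`daily / 2`). The default
#' calibration targets a mean individual remigration interval inside the
#' 2-7 year band observed worldwide (see the methods vignette for the
#' calibration procedure); none of the energy-scale defaults is claimed to
#' be a field measurement.
#'
#' @param n_turtles Number of adult females `N_T` (default 7,000).
#' @param steps_total Total half-day steps (default 36,500, about 50 years).
#' @param steps_burn_in Burn-in steps discarded from observation (default
#'   1,500, about two years).
#' @param scenario 1 = no currents, 2 = currents, 3 = no currents but a
#'   perturbation of southern feeding patches.
#' @param s_f Foraging patch-fidelity strategy in `[0, 1]` (shared by all
#'   turtles in a run).
#' @param s_n Nesting allocation strategy in `[0, 1]`.
#' @param alpha Depletion coefficient (per day).
#' @param a,b Steepness and threshold of the patch-leaving response
#'   (resource units).
#' @param lambda_decay Distance-decay exponent for new-patch choice.
#' @param phi_max Patch carrying capacity (resource units), common to all
#'   patches.
#' @param delta_eps_m Migration cost (energy/day).
#' @param delta_eps_n Nesting cost (energy/day).
#' @param t_n_max Maximum nesting duration (days).
#' @param movement A [movement_params()] object.
#' @param perturbation A [perturbation()] object, or `NULL` to build the
#'   default scenario-3 band at initialization (latitude one degree south
#'   of the southernmost patch, range 10 degrees, intensity 0.2).
#' @param min_allocation Minimum turtles per rookery at the reference scale
#'   of 7,000 (default 45); rescaled as `round(45 * n_turtles / 7000)` for
#'   other population sizes.
#' @param sampling_period Mean steps between track samples of a migrating
#'   turtle (default 500; sampling is Bernoulli per migrating turtle-step).
#' @param record_patch_timeseries Record per-step patch resource levels?
#' @param seed Root seed for the run; every stochastic draw flows from it.
#' @param scale_factor Optional uniform down-scaling of `n_turtles`,
#'   `steps_total` and `steps_burn_in` for desk runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_turtles = 7000, steps_total = 36500,
                       steps_burn_in = 1500, scenario = 1,
                       s_f = 0.5, s_n = 0.5,
                       alpha = 0.001, a = 50, b = 300, lambda_decay = 5,
                       phi_max = 1000, delta_eps_m = 10, delta_eps_n = 5,
                       t_n_max = 100, movement = movement_params(),
                       perturbation = NULL, min_allocation = 45,
                       sampling_period = 500,
                       record_patch_timeseries = FALSE,
                       seed = 1, scale_factor = NULL) {
  if (!is.null(scale_factor)) {
    stopifnot(scale_factor > 0)
    n_turtles <- max(1L, round(n_turtles * scale_factor))
    steps_total <- max(1L, round(steps_total * scale_factor))
    steps_burn_in <- round(steps_burn_in * scale_factor)
  }
  stopifnot(steps_burn_in < steps_total, scenario %in% 1:3,
            s_f >= 0, s_f <= 1, s_n >= 0, s_n <= 1,
            alpha > 0, a > 0, phi_max > 0, t_n_max >= 0,
            delta_eps_m >= 0, delta_eps_n >= 0, sampling_period > 0)
  structure(list(
    n_turtles = as.integer(n_turtles), steps_total = as.integer(steps_total),
    steps_burn_in = as.integer(steps_burn_in),
    step_duration_days = 0.5, scenario = as.integer(scenario),
    s_f = s_f, s_n = s_n, alpha = alpha, a = a, b = b,
    lambda_decay = lambda_decay, phi_max = phi_max,
    delta_eps_m = delta_eps_m, delta_eps_n = delta_eps_n, t_n_max = t_n_max,
    movement = movement, perturbation = perturbation,
    min_allocation = min_allocation, sampling_period = sampling_period,
    record_patch_timeseries = record_patch_timeseries,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> scenario ", x$scenario, ", ", x$n_turtles, " turtles, ",
      x$steps_total, " half-day steps (burn-in ", x$steps_burn_in, ")\n",
      "  S_F = ", x$s_f, ", S_N = ", x$s_n,
      ", alpha = ", x$alpha, "/day, phi_max = ", x$phi_max, "\n", sep = "")
  invisible(x)
}

# Largest-remainder (Hamilton) apportionment of n among weights.
hamilton <- function(weights, n) {
  q <- weights / sum(weights) * n
  base <- floor(q)
  rem <- as.integer(round(n - sum(base)))
  counts <- as.integer(base)
  if (rem > 0) {
    ord <- order(q - base, weights, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  counts
}

#' Allocate turtles to rookeries by relative weight
#'
#' Rookeries whose proportional share floors at or below the minimum
#' allocation receive exactly the minimum (the smallest rookeries always
#' field a viable contingent); the remaining turtles are apportioned among
#' the larger rookeries by largest remainder, so the counts total exactly
#' `n_turtles`.
#'
#' @param weights Positive rookery weights.
#' @param n_turtles Total population size.
#' @param min_allocation Minimum per-rookery count (already rescaled to
#'   `n_turtles` if needed).
#' @return Integer counts, one per rookery, summing to `n_turtles`.
#' @export
allocate_rookeries <- function(weights, n_turtles, min_allocation = 45) {
  if (sum(weights) <= 0) stop("rookery weights sum to zero")
  n_sites <- length(weights)
  if (n_turtles < n_sites * min_allocation) {
    stop("n_turtles too small for ", n_sites, " rookeries at minimum ",
         min_allocation)
  }
  base <- floor(weights / sum(weights) * n_turtles)
  small <- base <= min_allocation
  counts <- integer(n_sites)
  if (all(small)) return(hamilton(weights, n_turtles))
  counts[small] <- as.integer(min_allocation)
  counts[!small] <- hamilton(weights[!small],
                             n_turtles - sum(counts[small]))
  counts
}

# Build the simulation state environment: turtle vectors, patch state,
# precomputed distance geometry and choice weights. Assumes the RNG has
# been seeded by the caller.
initialize_simulation <- function(config, landscape) {
  st <- new.env(parent = emptyenv())
  st$cfg <- config
  st$lsc <- landscape
  mp <- config$movement
  n_patch <- nrow(landscape$feeding_patches)
  n_site <- nrow(landscape$nesting_sites)
  st$n_patch <- n_patch
  st$n_site <- n_site
  st$px <- landscape$feeding_patches$x_km
  st$py <- landscape$feeding_patches$y_km
  st$sx <- landscape$nesting_sites$x_km
  st$sy <- landscape$nesting_sites$y_km
  st$plat <- latitude_of(landscape, st$py)

  # per-step rates (daily / 2)
  st$alpha_step <- config$alpha / 2
  st$beta_day <- regrowth_coefficient(config$alpha, config$n_turtles, n_patch)
  st$beta_step <- st$beta_day / 2
  st$dEm_step <- config$delta_eps_m / 2
  st$dEn_step <- config$delta_eps_n / 2
  st$step_len <- mp$speed_km_per_day / 2
  st$nest_steps <- nesting_duration_steps(config$s_n, config$t_n_max)

  pert <- config$perturbation
  if (config$scenario == 3L && is.null(pert)) {
    pert <- perturbation(sigma_y = min(st$plat) - 1, sigma_i = 0.2,
                         d_sigma_max = 10)
  }
  st$pert <- pert
  st$d_floor_deg <- (landscape$bbox[["lat_max"]] - landscape$bbox[["lat_min"]]) /
    landscape$n_rows

  # distance geometry: patch-site cycle requirements and patch-patch
  # distance-decay choice weights (row-normalized cumulative sums)
  dps <- outer(st$px, st$sx, function(x, s) x - s)^2 +
    outer(st$py, st$sy, function(y, s) y - s)^2
  st$dist_patch_site <- sqrt(dps)
  st$eps_cycle <- cycle_energy_requirement(st$dist_patch_site,
                                           mp$speed_km_per_day, config$s_n,
                                           config$t_n_max, config$delta_eps_m,
                                           config$delta_eps_n)
  if (n_patch >= 2L) {
    dpp <- as.matrix(stats::dist(cbind(st$px, st$py)))
    W <- patch_choice_weights(dpp, landscape$d_min, landscape$d_max,
                              config$lambda_decay)
    diag(W) <- 0
    rs <- rowSums(W)
    zero <- rs <= 0
    if (any(zero)) {          # degenerate rows: uniform over candidates
      W[zero, ] <- 1
      diag(W) <- 0
      rs <- rowSums(W)
    }
    st$choice_cum <- t(apply(W / rs, 1L, cumsum))
  } else {
    st$choice_cum <- NULL
  }

  # rookery allocation and initial patch choice (distance decay from the
  # natal site, all patches candidates)
  min_alloc <- round(config$min_allocation * config$n_turtles / 7000)
  counts <- allocate_rookeries(landscape$nesting_sites$weight,
                               config$n_turtles, min_alloc)
  site <- rep(seq_len(n_site), counts)
  n <- config$n_turtles
  patch <- integer(n)
  for (s in seq_len(n_site)) {
    idx <- which(site == s)
    if (length(idx) == 0L) next
    w <- patch_choice_weights(st$dist_patch_site[, s], landscape$d_min,
                              landscape$d_max, config$lambda_decay)
    if (sum(w) <= 0) w <- rep(1, n_patch)
    patch[idx] <- sample.int(n_patch, length(idx), replace = TRUE, prob = w)
  }
  st$site <- site
  st$patch <- patch
  st$x <- st$px[patch]
  st$y <- st$py[patch]
  st$state <- rep(ST_FEEDING, n)
  st$energy <- stats::runif(n, 0, st$eps_cycle[cbind(patch, site)])
  st$initial_energy <- sum(st$energy)
  st$rot <- integer(n)                 # 0 unset, +1 left, -1 right
  st$wfh <- rep(NA_real_, n)           # persistent wall-follow heading
  st$nest_rem <- integer(n)

  st$phi <- stats::runif(n_patch, 0, config$phi_max)

  # observation store
  st$time_usage <- numeric(n_patch)
  st$postnesting_visits <- integer(n_patch)
  st$foraging_visits <- integer(n_patch)
  st$visits_by_origin <- matrix(0L, n_patch, n_site)
  st$events <- matrix(NA_real_, 256L, 4L)
  st$n_events <- 0L
  st$tracks <- matrix(NA_real_, 256L, 6L)
  st$n_tracks <- 0L
  st$phi_series <- if (isTRUE(config$record_patch_timeseries)) list() else NULL

  # energy ledger
  st$gains <- 0
  st$migration_costs <- 0
  st$nesting_costs <- 0
  st$enclosed_warnings <- 0L
  st$negative_energy_events <- 0L
  st$step <- 0L
  st
}

buf_push <- function(buf, n_used, rows) {
  need <- n_used + nrow(rows)
  if (need > nrow(buf)) {
    buf <- rbind(buf, matrix(NA_real_, max(nrow(buf), need), ncol(buf)))
  }
  buf[(n_used + 1L):need, ] <- rows
  buf
}

#' Advance the simulation by one half-day step
#'
#' Processes first all turtles (state-dependent tasks: feed and possibly
#' start a foraging or pre-nesting migration; move toward the target or
#' arrive; nest), then all feeding patches (logistic regrowth with
#' density-dependent depletion, then the perturbation under scenario 3),
#' with immediate state updating. The per-step shuffle drives the order of
#' the random draws. Observation hooks (tallies, nesting events, track
#' samples) fire after the burn-in. Every state change is checked against
#' the legal transition edges.
#'
#' @param st A state environment from `initialize_simulation()` (exposed via
#'   [run_simulation()]'s `step_hook`).
#' @return The state environment, invisibly.
#' @export
run_step <- function(st) {
  cfg <- st$cfg
  lsc <- st$lsc
  mp <- cfg$movement
  step_now <- st$step + 1L
  observing <- step_now > cfg$steps_burn_in
  n <- length(st$x)
  perm <- sample.int(n)                # randomized processing order
  st0 <- st$state

  ## --- feeding turtles: win energy, maybe start a migration -------------
  feed <- which(st0 == ST_FEEDING)
  if (length(feed)) {
    feed <- feed[order(perm[feed])]
    gain <- st$alpha_step * st$phi[st$patch[feed]]
    st$energy[feed] <- st$energy[feed] + gain
    st$gains <- st$gains + sum(gain)
    if (observing) {
      st$time_usage <- st$time_usage + tabulate(st$patch[feed], st$n_patch)
    }
    p_leave <- leave_probability(st$phi[st$patch[feed]], cfg$s_f, cfg$a, cfg$b)
    leav <- feed[stats::runif(length(feed)) < p_leave]
    if (length(leav)) {
      u <- stats::runif(length(leav))
      for (k in seq_along(leav)) {
        i <- leav[k]
        cw <- st$choice_cum[st$patch[i], ]
        st$patch[i] <- findInterval(u[k], cw) + 1L
      }
      st$state[leav] <- ST_FORAGING
      st$rot[leav] <- 0L               # reset at foraging-migration start
      st$wfh[leav] <- NA_real_
    }
    stay <- setdiff(feed, leav)
    if (length(stay)) {
      trig <- stay[should_start_prenesting(
        st$energy[stay], st$eps_cycle[cbind(st$patch[stay], st$site[stay])])]
      if (length(trig)) {
        st$state[trig] <- ST_PRENESTING
        st$rot[trig] <- 0L             # side re-derived at first obstruction
        st$wfh[trig] <- NA_real_
      }
    }
  }

  ## --- migrating turtles: arrive or move one step -----------------------
  mig <- which(st0 == ST_PRENESTING | st0 == ST_POSTNESTING |
                 st0 == ST_FORAGING)
  if (length(mig)) {
    mig <- mig[order(perm[mig])]
    pre <- st0[mig] == ST_PRENESTING
    tx <- st$px[st$patch[mig]]
    ty <- st$py[st$patch[mig]]
    tx[pre] <- st$sx[st$site[mig[pre]]]
    ty[pre] <- st$sy[st$site[mig[pre]]]
    d <- sqrt((tx - st$x[mig])^2 + (ty - st$y[mig])^2)
    arr <- d <= mp$detection_range_km

    # arrivals: switch state at the target
    for (i in mig[arr & pre]) {        # reached the nesting site
      st$x[i] <- st$sx[st$site[i]]; st$y[i] <- st$sy[st$site[i]]
      st$state[i] <- ST_NESTING
      st$nest_rem[i] <- st$nest_steps
      if (st$nest_steps == 0L) {       # degenerate S_N = 0: instant nesting
        if (observing) {
          st$events <- buf_push(st$events, st$n_events,
                                matrix(c(i, st$site[i], step_now,
                                         st$energy[i]), 1L))
          st$n_events <- st$n_events + 1L
        }
        st$state[i] <- ST_POSTNESTING
        st$rot[i] <- -st$rot[i]        # revert the avoidance side
        st$wfh[i] <- NA_real_
      }
    }
    post_arr <- mig[arr & !pre & st0[mig] == ST_POSTNESTING]
    if (length(post_arr)) {
      st$x[post_arr] <- st$px[st$patch[post_arr]]
      st$y[post_arr] <- st$py[st$patch[post_arr]]
      st$state[post_arr] <- ST_FEEDING
      if (observing) {
        st$postnesting_visits <- st$postnesting_visits +
          tabulate(st$patch[post_arr], st$n_patch)
        for (i in post_arr) {
          st$visits_by_origin[st$patch[i], st$site[i]] <-
            st$visits_by_origin[st$patch[i], st$site[i]] + 1L
        }
      }
    }
    for_arr <- mig[arr & !pre & st0[mig] == ST_FORAGING]
    if (length(for_arr)) {
      st$x[for_arr] <- st$px[st$patch[for_arr]]
      st$y[for_arr] <- st$py[st$patch[for_arr]]
      st$state[for_arr] <- ST_FEEDING
      st$rot[for_arr] <- 0L            # reset at foraging-migration end
      st$wfh[for_arr] <- NA_real_
      if (observing) {
        st$foraging_visits <- st$foraging_visits +
          tabulate(st$patch[for_arr], st$n_patch)
      }
    }

    # movers: coast-aware step toward the target, plus drift in scenario 2
    mv <- which(!arr)
    if (length(mv)) {
      im <- mig[mv]
      x0 <- st$x[im]; y0 <- st$y[im]
      desired <- atan2(ty[mv] - y0, tx[mv] - x0) * 180 / pi
      mlen <- pmin(st$step_len, d[mv])
      blocked <- ray_blocked(lsc, x0, y0, desired,
                             pmin(mlen, mp$sensing_radius_km))$blocked
      heading <- desired
      st$wfh[im[!blocked]] <- NA_real_   # clear target course ends a follow
      for (k in which(blocked)) {
        av <- avoid_coast_int(lsc, x0[k], y0[k], desired[k], st$rot[im[k]],
                              st$wfh[im[k]], mp$angle_step_deg, mlen[k],
                              mp$sensing_radius_km, desired_blocked = TRUE)
        st$rot[im[k]] <- av$rot
        st$wfh[im[k]] <- av$wall_heading
        if (av$ok) {
          heading[k] <- av$heading
        } else {
          mlen[k] <- 0                 # fully enclosed: stay put
          st$enclosed_warnings <- st$enclosed_warnings + 1L
        }
      }
      hr <- heading * pi / 180
      # motor leg: the ray was checked clear; truncation only guards the
      # sampling resolution
      tm <- truncate_to_ocean(lsc, x0, y0,
                              x0 + mlen * cos(hr), y0 + mlen * sin(hr))
      if (cfg$scenario == 2L) {
        # drift leg: half the cell's current vector, truncated at the coast
        # so drift can pin a turtle against a shore but never strand it or
        # cancel its motor progress. Terminal docking steps (clear path,
        # target within reach) take no drift, so arrival is always
        # possible in strong currents.
        drift <- d[mv] > st$step_len | heading != desired
        if (any(drift)) {
          ij <- cell_of(lsc, x0[drift], y0[drift])
          td <- truncate_to_ocean(
            lsc, tm$x[drift], tm$y[drift],
            tm$x[drift] + 0.5 * lsc$current_u[cbind(ij$row, ij$col)],
            tm$y[drift] + 0.5 * lsc$current_v[cbind(ij$row, ij$col)])
          tm$x[drift] <- td$x
          tm$y[drift] <- td$y
        }
      }
      st$x[im] <- tm$x
      st$y[im] <- tm$y
      st$energy[im] <- st$energy[im] - st$dEm_step
      st$migration_costs <- st$migration_costs + length(im) * st$dEm_step

      if (observing) {
        nest_mig <- mv[st0[im] != ST_FORAGING]   # foraging legs not recorded
        if (length(nest_mig)) {
          samp <- nest_mig[stats::runif(length(nest_mig)) <
                             1 / cfg$sampling_period]
          if (length(samp)) {
            ii <- mig[samp]
            st$tracks <- buf_push(st$tracks, st$n_tracks,
                                  cbind(ii, step_now, st$x[ii], st$y[ii],
                                        st0[ii], st$site[ii]))
            st$n_tracks <- st$n_tracks + length(ii)
          }
        }
      }
    }
  }

  ## --- nesting turtles ---------------------------------------------------
  nst <- which(st0 == ST_NESTING)
  if (length(nst)) {
    st$energy[nst] <- st$energy[nst] - st$dEn_step
    st$nesting_costs <- st$nesting_costs + length(nst) * st$dEn_step
    st$nest_rem[nst] <- st$nest_rem[nst] - 1L
    done <- nst[st$nest_rem[nst] <= 0L]
    if (length(done)) {
      if (observing) {
        st$events <- buf_push(st$events, st$n_events,
                              cbind(done, st$site[done], step_now,
                                    st$energy[done]))
        st$n_events <- st$n_events + length(done)
      }
      st$state[done] <- ST_POSTNESTING
      st$rot[done] <- -st$rot[done]    # opposite side on the way back
      st$wfh[done] <- NA_real_
    }
  }

  # state-machine legality: every change this step must be a legal edge
  ch <- which(st$state != st0)
  if (length(ch)) {
    pair <- paste(st0[ch], st$state[ch])
    legal <- paste(LEGAL_TRANSITIONS[, 1], LEGAL_TRANSITIONS[, 2])
    if (!all(pair %in% legal)) stop("illegal state transition at step ",
                                    step_now)
  }

  ## --- feeding patches: regrowth, depletion, perturbation ---------------
  occ <- tabulate(st$patch[st$state == ST_FEEDING], st$n_patch)
  st$phi <- update_patch_resource(st$phi, occ, st$beta_step, st$alpha_step,
                                  cfg$phi_max)
  if (cfg$scenario == 3L) {
    st$phi <- apply_perturbation(st$phi, st$plat, st$pert, st$beta_step,
                                 st$d_floor_deg)
  }
  if (!is.null(st$phi_series) && observing) {
    st$phi_series[[length(st$phi_series) + 1L]] <-
      c(step_now, st$phi, occ)
  }

  st$negative_energy_events <- st$negative_energy_events +
    sum(st$energy[mig] < 0 & st$energy[mig] + st$dEm_step >= 0)
  st$step <- step_now
  invisible(st)
}

#' Run a complete simulation
#'
#' Seeds the RNG from `config$seed`, initializes the population and patch
#' states, executes `steps_total` half-day steps, and returns the recorded
#' observations (which start after the burn-in).
#'
#' @param config A [sim_config()].
#' @param landscape A `turtle_landscape`.
#' @param step_hook Optional `function(state)` called after every step
#'   (used for instrumentation and tests).
#' @return A list of class `turtle_run` with elements `nesting_events`,
#'   `track_samples`, `patch_usage`, `origin_visits` (patch x rookery
#'   matrix of postnesting visits), optional `patch_timeseries`, and
#'   `meta` (seed, ledger totals, counts).
#' @export
run_simulation <- function(config, landscape, step_hook = NULL) {
  set.seed(config$seed)
  st <- initialize_simulation(config, landscape)
  for (k in seq_len(config$steps_total)) {
    run_step(st)
    if (!is.null(step_hook)) step_hook(st)
  }
  finalize_run(st)
}

finalize_run <- function(st) {
  cfg <- st$cfg
  ev <- st$events[seq_len(st$n_events), , drop = FALSE]
  events <- data.frame(turtle_id = as.integer(ev[, 1]),
                       site_id = as.integer(ev[, 2]),
                       step = as.integer(ev[, 3]),
                       energy_after = ev[, 4])
  tr <- st$tracks[seq_len(st$n_tracks), , drop = FALSE]
  tracks <- data.frame(turtle_id = as.integer(tr[, 1]),
                       step = as.integer(tr[, 2]),
                       x_km = tr[, 3], y_km = tr[, 4],
                       migration_phase = TURTLE_STATES[as.integer(tr[, 5])],
                       site_id = as.integer(tr[, 6]))
  usage <- data.frame(patch_id = st$lsc$feeding_patches$patch_id,
                      time_usage = st$time_usage,
                      postnesting_visits = st$postnesting_visits,
                      foraging_visits = st$foraging_visits)
  meta <- list(seed = cfg$seed, scenario = cfg$scenario,
               s_f = cfg$s_f, s_n = cfg$s_n,
               n_turtles = cfg$n_turtles, steps_total = cfg$steps_total,
               steps_burn_in = cfg$steps_burn_in,
               beta_day = st$beta_day,
               initial_energy = st$initial_energy,
               final_energy = sum(st$energy),
               gains = st$gains, migration_costs = st$migration_costs,
               nesting_costs = st$nesting_costs,
               enclosed_warnings = st$enclosed_warnings,
               negative_energy_events = st$negative_energy_events)
  out <- list(nesting_events = events, track_samples = tracks,
              patch_usage = usage, origin_visits = st$visits_by_origin,
              final_state = list(x = st$x, y = st$y, state = st$state,
                                 patch = st$patch, site = st$site,
                                 energy = st$energy, phi = st$phi),
              meta = meta, config = cfg)
  if (!is.null(st$phi_series) && length(st$phi_series)) {
    m <- do.call(rbind, st$phi_series)
    colnames(m) <- c("step", paste0("phi_", seq_len(st$n_patch)),
                     paste0("occ_", seq_len(st$n_patch)))
    out$patch_timeseries <- as.data.frame(m)
  }
  class(out) <- "turtle_run"
  out
}

#' @export
print.turtle_run <- function(x, ...) {
  m <- x$meta
  cat("<turtle_run> scenario ", m$scenario, ", seed ", m$seed, ", ",
      m$n_turtles, " turtles, ", m$steps_total, " steps\n",
      "  nesting events recorded: ", nrow(x$nesting_events),
      "; track samples: ", nrow(x$track_samples), "\n",
      "  S_F = ", m$s_f, ", S_N = ", m$s_n, "\n", sep = "")
  invisible(x)
}

#' Factorial experiment design
#'
#' @param scenarios Scenario labels (default 1:3).
#' @param s_f_grid,s_n_grid Strategy grids (default 0.2, 0.4, 0.6, 0.8).
#' @param replicates Repetitions per cell (default 5).
#' @param base_seed Base seed; run `k` (1-based) receives `base_seed + k - 1`.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(scenarios = 1:3,
                              s_f_grid = c(0.2, 0.4, 0.6, 0.8),
                              s_n_grid = c(0.2, 0.4, 0.6, 0.8),
                              replicates = 5, base_seed = 1) {
  stopifnot(length(scenarios) > 0, length(s_f_grid) > 0, length(s_n_grid) > 0,
            replicates >= 1)
  structure(list(scenarios = scenarios, s_f_grid = s_f_grid,
                 s_n_grid = s_n_grid, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "experiment_design")
}

#' Enumerate the full factorial of simulation configurations
#'
#' @param design An [experiment_design()].
#' @param base_config Template [sim_config()] supplying all non-varied
#'   parameters.
#' @return List of `sim_config` objects of length
#'   `scenarios x S_F grid x S_N grid x replicates`, each with a distinct
#'   derived seed.
#' @export
build_experiment <- function(design, base_config = sim_config()) {
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      s_n = design$s_n_grid, s_f = design$s_f_grid,
                      scenario = design$scenarios)
  configs <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$scenario <- as.integer(grid$scenario[k])
    cfg$s_f <- grid$s_f[k]
    cfg$s_n <- grid$s_n[k]
    cfg$seed <- design$base_seed + k - 1L
    configs[[k]] <- cfg
  }
  seeds <- vapply(configs, `[[`, integer(1), "seed")
  if (anyDuplicated(seeds)) stop("duplicate derived seeds")
  configs
}

#' Run a list of configurations
#'
#' @param configs List of [sim_config()] objects (e.g. from
#'   [build_experiment()]).
#' @param landscape A `turtle_landscape` shared by all runs.
#' @param out_dir Optional directory; when given, each run's outputs are
#'   written to `out_dir/run_<k>` via [write_run_outputs()].
#' @param progress Print one line per completed run?
#' @return List of `turtle_run` objects.
#' @export
run_experiment <- function(configs, landscape, out_dir = NULL,
                           progress = FALSE) {
  runs <- vector("list", length(configs))
  for (k in seq_along(configs)) {
    runs[[k]] <- run_simulation(configs[[k]], landscape)
    if (!is.null(out_dir)) {
      write_run_outputs(runs[[k]], file.path(out_dir, sprintf("run_%03d", k)))
    }
    if (progress) {
      message(sprintf("run %d/%d done (scenario %d, S_F %.1f, S_N %.1f)",
                      k, length(configs), configs[[k]]$scenario,
                      configs[[k]]$s_f, configs[[k]]$s_n))
    }
  }
  runs
}

#' Write a run's output tables
#'
#' Writes `nesting_events.csv`, `track_samples.csv`, `patch_usage.csv`,
#' `origin_visits.csv`, optional `patch_timeseries.csv`, a resolved
#' configuration copy (`config.yaml`) and `meta.json`.
#'
#' @param run A `turtle_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$nesting_events, file.path(dir, "nesting_events.csv"),
                   row.names = FALSE)
  utils::write.csv(run$track_samples, file.path(dir, "track_samples.csv"),
                   row.names = FALSE)
  usage <- cbind(run$patch_usage, run$origin_visits)
  colnames(usage) <- c(colnames(run$patch_usage),
                       paste0("origin_site_", seq_len(ncol(run$origin_visits))))
  utils::write.csv(usage, file.path(dir, "patch_usage.csv"), row.names = FALSE)
  if (!is.null(run$patch_timeseries)) {
    utils::write.csv(run$patch_timeseries,
                     file.path(dir, "patch_timeseries.csv"), row.names = FALSE)
  }
  cfg <- run$config
  cfg$movement <- unclass(cfg$movement)
  cfg$perturbation <- if (is.null(cfg$perturbation)) NULL else
    unclass(cfg$perturbation)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  jsonlite::write_json(run$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build a configuration from a YAML file
#'
#' The YAML mirrors [sim_config()] field names; `movement` and
#' `perturbation` are nested maps with their constructor's field names.
#'
#' @param path Path to a YAML config file.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$movement)) y$movement <- do.call(movement_params, y$movement)
  if (!is.null(y$perturbation)) {
    y$perturbation <- do.call(perturbation, y$perturbation)
  }
  y$step_duration_days <- NULL
  args <- utils::modifyList(y, list(...))
  do.call(sim_config, args)
}
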