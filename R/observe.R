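#' Normalized origin-diversity index of a feeding patch
#'
#' Shannon diversity of the rookeries of origin of post-nesting visitors,
#' normalized by its maximum: `H_p = -sum(r_n log r_n) / log(N_N)`, with
#' `r_n` the relative proportion of postnesting visits from nesting site
#' `n` and `0 log 0 = 0`. `H_p` is 0 when all visitors share one origin and
#' 1 when all `N_N` rookeries contribute equally.
#'
#' @param visit_counts_by_site Non-negative visit counts per rookery (not
#'   all zero).
#' @param n_sites Number of nesting sites in the model `N_N` (>= 2);
#'   defaults to `length(visit_counts_by_site)`.
#' @return `H_p` in `[0, 1]`.
#' @export
origin_diversity <- function(visit_counts_by_site,
                             n_sites = length(visit_counts_by_site)) {
  stopifnot(n_sites >= 2, all(visit_counts_by_site >= 0))
  tot <- sum(visit_counts_by_site)
  if (tot == 0) stop("all-zero visit counts: diversity undefined")
  r <- visit_counts_by_site / tot
  r <- r[r > 0]
  -sum(r * log(r)) / log(n_sites)
}

#' Per-individual mean remigration intervals
#'
#' The remigration interval is the time between an individual's successive
#' nesting events. For each turtle with at least two recorded events the
#' mean of the successive step differences is converted to years
#' (`steps * 0.5 / 365.25`); turtles with fewer than two events are
#' excluded.
#'
#' @param events Data frame with `turtle_id` and `step` (as produced in
#'   `nesting_events` by [run_simulation()]).
#' @param step_duration_days Days per step (default 0.5).
#' @return Data frame with `turtle_id` and `mean_interval_years`.
#' @export
remigration_intervals <- function(events, step_duration_days = 0.5) {
  if (nrow(events) == 0L) {
    return(data.frame(turtle_id = integer(0),
                      mean_interval_years = numeric(0)))
  }
  events <- events[order(events$turtle_id, events$step), ]
  sp <- split(events$step, events$turtle_id)
  keep <- vapply(sp, length, integer(1)) >= 2L
  sp <- sp[keep]
  data.frame(
    turtle_id = as.integer(names(sp)),
    mean_interval_years = vapply(sp, function(s) {
      mean(diff(s)) * step_duration_days / 365.25
    }, numeric(1)),
    row.names = NULL)
}

#' Rookery reproductive output
#'
#' `RO_n = S_N * sum_i sum_k eps_{i,k} / (T_{i,k} - T_{i,k-1})`: for each
#' rookery, the post-nesting energy of every repeat nesting event divided
#' by the remigration interval that preceded it (in days), summed over
#' individuals and events, scaled by the nesting investment `S_N`. First
#' events per individual carry no interval and do not contribute.
#'
#' @param events Data frame with `turtle_id`, `site_id`, `step`,
#'   `energy_after`.
#' @param s_n Nesting allocation strategy of the run.
#' @param n_sites Number of rookeries (sites with no repeat nester report
#'   0); defaults to the largest site id seen.
#' @param step_duration_days Days per step (default 0.5).
#' @return Data frame with `site_id` and `reproductive_output`.
#' @export
reproductive_output <- function(events, s_n,
                                n_sites = if (nrow(events)) max(events$site_id)
                                          else 0L,
                                step_duration_days = 0.5) {
  stopifnot(s_n >= 0, s_n <= 1)
  ro <- numeric(n_sites)
  if (nrow(events)) {
    events <- events[order(events$turtle_id, events$step), ]
    by_t <- split(seq_len(nrow(events)), events$turtle_id)
    for (idx in by_t) {
      if (length(idx) < 2L) next
      dt_days <- diff(events$step[idx]) * step_duration_days
      contrib <- events$energy_after[idx][-1] / dt_days
      s <- events$site_id[idx][1]
      ro[s] <- ro[s] + sum(contrib)
    }
  }
  data.frame(site_id = seq_len(n_sites), reproductive_output = s_n * ro)
}

#' Sample migrating turtle positions from a simulation state
#'
#' One observation sweep: every turtle currently in a pre- or post-nesting
#' migration is recorded with probability `1 / sampling_period`, so a
#' migrating turtle is sampled on average every `sampling_period` steps.
#' Feeding, nesting and foraging-migration turtles are never sampled.
#'
#' @param state A simulation state environment (see [run_simulation()]'s
#'   `step_hook`).
#' @param sampling_period Mean steps between samples (default 500).
#' @return Data frame of `TrackSample` rows (possibly empty).
#' @export
sample_tracks <- function(state, sampling_period = 500) {
  mig <- which(state$state == ST_PRENESTING | state$state == ST_POSTNESTING)
  sel <- mig[stats::runif(length(mig)) < 1 / sampling_period]
  data.frame(turtle_id = sel, step = rep(state$step, length(sel)),
             x_km = state$x[sel], y_km = state$y[sel],
             migration_phase = TURTLE_STATES[state$state[sel]],
             site_id = state$site[sel])
}

#' Pool track positions across runs
#'
#' Draws `subsample_per_run` positions per run without replacement (all
#' positions when a run has fewer) and pools them, mirroring the corridor
#' mapping protocol (125 positions per simulation, 10,000 per 80-run
#' scenario).
#'
#' @param runs List of `turtle_run` objects (or data frames of track
#'   samples).
#' @param subsample_per_run Positions drawn per run (default 125).
#' @return Data frame of pooled positions with a `run` column.
#' @export
pool_track_positions <- function(runs, subsample_per_run = 125) {
  out <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    tr <- if (inherits(runs[[k]], "turtle_run")) runs[[k]]$track_samples
          else runs[[k]]
    if (nrow(tr) > subsample_per_run) {
      tr <- tr[sample.int(nrow(tr), subsample_per_run), ]
    }
    if (nrow(tr)) tr$run <- k
    out[[k]] <- tr
  }
  do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
}

#' Migration-corridor kernel density
#'
#' Gaussian product-kernel density estimate of pooled migration positions
#' on the landscape grid (the utilization-distribution view of the
#' corridors). The default bandwidth is the normal reference rule per axis;
#' the raster integrates to ~1 over the world (mass falling outside the
#' bounds is truncated).
#'
#' @param positions Data frame with `x_km`, `y_km` (e.g. from
#'   [pool_track_positions()]); at least one row.
#' @param landscape A `turtle_landscape` supplying the grid extent.
#' @param bandwidth_km Bandwidth `c(hx, hy)` passed to [MASS::kde2d()]
#'   (its `h` is ~4x the kernel sd); default normal reference rule.
#' @param grid_n Number of evaluation points per axis (default 200, capped
#'   at the grid dims).
#' @return List of class `corridor_density` with `x`, `y`, `z` (density per
#'   km^2), `h`.
#' @export
kernel_density <- function(positions, landscape, bandwidth_km = NULL,
                           grid_n = 200) {
  if (nrow(positions) == 0L) stop("no positions to smooth")
  x <- positions$x_km
  y <- positions$y_km
  if (is.null(bandwidth_km)) {
    nrd <- function(v) {
      h <- MASS::bandwidth.nrd(v)
      if (h <= 0) h <- 4 * 1.06 * max(stats::sd(v), 1) * length(v)^(-1 / 5)
      h
    }
    bandwidth_km <- c(nrd(x), nrd(y))
  }
  lims <- c(0, landscape$n_cols * landscape$cell_size_km,
            0, landscape$n_rows * landscape$cell_size_km)
  n <- c(min(grid_n, landscape$n_cols), min(grid_n, landscape$n_rows))
  kd <- MASS::kde2d(x, y, h = bandwidth_km, n = n, lims = lims)
  structure(list(x = kd$x, y = kd$y, z = kd$z, h = bandwidth_km),
            class = "corridor_density")
}

#' Write a corridor density as an ESRI ASCII raster
#'
#' @param density A `corridor_density`.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_corridor_density <- function(density, path) {
  # kde2d returns z[x, y]; the raster wants rows = y (south first)
  write_esri_ascii(t(density$z), path,
                   xllcorner = min(density$x), yllcorner = min(density$y),
                   cellsize = diff(density$x[1:2]))
}

#' Pooled per-patch usage report
#'
#' Pools the usage tables of several runs (counts add elementwise) and
#' reports, per patch: time usage, post-nesting and foraging visit counts,
#' the number of rookeries of origin, and the normalized origin-diversity
#' index (`NA` for patches without post-nesting visits).
#'
#' @param runs List of `turtle_run` objects from the same landscape.
#' @return Data frame with one row per patch.
#' @export
usage_report <- function(runs) {
  stopifnot(length(runs) >= 1)
  usage <- runs[[1]]$patch_usage
  origin <- runs[[1]]$origin_visits
  for (r in runs[-1]) {
    usage$time_usage <- usage$time_usage + r$patch_usage$time_usage
    usage$postnesting_visits <- usage$postnesting_visits +
      r$patch_usage$postnesting_visits
    usage$foraging_visits <- usage$foraging_visits +
      r$patch_usage$foraging_visits
    origin <- origin + r$origin_visits
  }
  n_sites <- ncol(origin)
  usage$n_origin_sites <- as.integer(rowSums(origin > 0))
  # normalized diversity needs >= 2 rookeries in the model and >= 1 visit
  usage$origin_diversity <- apply(origin, 1L, function(v) {
    if (sum(v) == 0 || n_sites < 2) NA_real_
    else origin_diversity(v, n_sites)
  })
  usage
}
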