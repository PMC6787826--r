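#' Movement parameter set
#'
#' @param speed_km_per_day Motor swimming speed `c` (default 65 km/day, i.e.
#'   2.7 km/hr, from satellite tracking of migrating females).
#' @param angle_step_deg Incremental rotation used by the wall-following
#'   coast avoidance (must divide 360; default 15).
#' @param detection_range_km Arrival radius around targets (default 7, one
#'   cell).
#' @param sensing_radius_km Coast sensing horizon (default 100 km).
#' @param migration_cost_per_day Energy lost per day while migrating
#'   (`delta_eps_m`).
#' @return A list of class `movement_params`.
#' @export
movement_params <- function(speed_km_per_day = 65, angle_step_deg = 15,
                            detection_range_km = 7, sensing_radius_km = 100,
                            migration_cost_per_day = 10) {
  stopifnot(speed_km_per_day > 0, angle_step_deg > 0, detection_range_km > 0,
            sensing_radius_km > 0, migration_cost_per_day >= 0,
            360 %% angle_step_deg == 0)
  structure(list(speed_km_per_day = speed_km_per_day,
                 angle_step_deg = angle_step_deg,
                 detection_range_km = detection_range_km,
                 sensing_radius_km = sensing_radius_km,
                 migration_cost_per_day = migration_cost_per_day),
            class = "movement_params")
}

#' Has a migrating turtle arrived at its target?
#'
#' True iff the distance to the target is at most the detection range
#' (closed boundary: exactly on the range counts as arrived).
#'
#' @param position `c(x, y)` km (or two-column matrix).
#' @param target_point `c(x, y)` km.
#' @param detection_range_km Arrival radius.
#' @return Logical.
#' @export
arrived <- function(position, target_point, detection_range_km) {
  point_distance(position, target_point) <= detection_range_km
}

#' Update the coast-avoidance rotation memory at a state transition
#'
#' The turn side memorized while wall-following is reverted when a turtle
#' starts a postnesting migration (so the return leg hugs the coast on the
#' opposite side, giving near-symmetric out-and-back routes), left to be
#' re-derived at the first obstruction when a prenesting migration starts,
#' and cleared when a foraging migration starts or ends.
#'
#' @param rotation_direction `"left"`, `"right"` or `"unset"`.
#' @param transition One of `"start_prenesting"`, `"start_postnesting"`,
#'   `"start_foraging_migration"`, `"end_foraging_migration"`.
#' @return The updated rotation direction.
#' @export
reset_rotation_direction <- function(rotation_direction, transition) {
  transition <- match.arg(transition,
                          c("start_prenesting", "start_postnesting",
                            "start_foraging_migration",
                            "end_foraging_migration"))
  switch(transition,
    start_postnesting = switch(rotation_direction,
                               left = "right", right = "left", "unset"),
    "unset")
}

# Integer encoding used by the engine: 0 unset, +1 left (counterclockwise),
# -1 right (clockwise).
rotation_to_int <- function(dir) {
  switch(dir, left = 1L, right = -1L, unset = 0L,
         stop("invalid rotation direction: ", dir))
}
rotation_from_int <- function(i) c("right", "unset", "left")[i + 2L]

# Scalar wall-following heading search. Returns list(heading, rotation, ok).
# With the side memorized, the heading is rotated from the *desired* heading
# in that direction by the minimal multiple of angle_step that clears the
# lookahead, which both follows the wall and relaxes back toward the target
# as soon as the way is clear.
# All-rays-from-one-origin clearance check, fully vectorized (hot path of
# the wall follower). Returns TRUE for headings whose lookahead is clear.
rays_clear <- function(landscape, x, y, hs_deg, len) {
  cs <- landscape$cell_size_km
  ts <- seq(cs / 2, len, by = cs / 2)
  if (length(ts) == 0L || ts[length(ts)] < len) ts <- c(ts, len)
  h <- hs_deg * (pi / 180)
  px <- x + outer(cos(h), ts)
  py <- y + outer(sin(h), ts)
  col <- floor(px / cs) + 1
  row <- floor(py / cs) + 1
  bad <- col < 1 | col > landscape$n_cols | row < 1 | row > landscape$n_rows
  ok <- which(!bad)
  bad[ok] <- landscape$land[row[ok] + (col[ok] - 1) * landscape$n_rows]
  rowSums(bad) == 0
}

# One decision of the wall follower. `wall_heading` is the persistent
# swimming direction while coast-following (NA when moving directly).
# Logic: a clear target direction is always taken (following ends); at the
# first obstruction the side with the smaller clearing angle is chosen and
# memorized; while following, the heading is first relaxed one angle-step
# back toward the target if that is clear, else kept, else rotated further
# in the memorized direction by the minimal clearing angle. The persistent
# heading is what lets a turtle trace around an obstacle even when drift
# opposes its progress.
avoid_coast_int <- function(landscape, x, y, desired, rot, wall_heading,
                            step_deg, lookahead, sensing,
                            desired_blocked = NA) {
  len <- min(lookahead, sensing)
  if (is.na(desired_blocked)) {
    desired_blocked <- !rays_clear(landscape, x, y, desired, len)
  }
  if (!desired_blocked) {
    return(list(heading = desired, rot = rot, wall_heading = NA_real_,
                ok = TRUE))
  }
  ks <- seq_len(as.integer(360 / step_deg) - 1L)
  if (is.na(wall_heading)) {
    # entering wall-following: minimal clearing angle from the target
    # heading; with no memorized side, interleave left/right so which()[1]
    # picks the smaller angle, left on ties
    if (rot == 0L) {
      hs <- as.vector(rbind(desired + ks * step_deg, desired - ks * step_deg))
      rots <- rep(c(1L, -1L), length(ks))
    } else {
      hs <- desired + rot * ks * step_deg
      rots <- rep(rot, length(ks))
    }
    clear <- rays_clear(landscape, x, y, hs, len)
    i <- which(clear)[1]
    if (is.na(i)) {
      return(list(heading = desired, rot = rot, wall_heading = wall_heading,
                  ok = FALSE))                       # fully enclosed
    }
    return(list(heading = hs[i], rot = rots[i], wall_heading = hs[i],
                ok = TRUE))
  }
  # already following: relax one increment toward the target if possible
  relax <- wall_heading - rot * step_deg
  cand <- c(relax, wall_heading, wall_heading + rot * ks * step_deg)
  clear <- rays_clear(landscape, x, y, cand, len)
  i <- which(clear)[1]
  if (is.na(i)) {
    list(heading = desired, rot = rot, wall_heading = wall_heading,
         ok = FALSE)
  } else {
    list(heading = cand[i], rot = rot, wall_heading = cand[i], ok = TRUE)
  }
}

#' Adjust a heading to avoid the coast (wall-following)
#'
#' If the desired heading is clear over the lookahead, it is returned
#' unchanged. Otherwise the heading is rotated in increments of
#' `angle_step_deg` up to the minimum angle that clears: on the first-ever
#' obstruction (rotation direction unset) both sides are scanned and the
#' side with the smaller clearing angle is memorized (ties go left); on
#' later steps rotation starts from the desired (target) heading in the
#' memorized direction only, so the turtle tracks the coast and resumes the
#' direct course as soon as it clears. If no heading within 360 degrees is
#' clear the turtle is enclosed and `ok = FALSE` is returned.
#'
#' @param landscape A `turtle_landscape`.
#' @param position `c(x, y)` km on a non-terrestrial cell.
#' @param desired_heading Heading toward the target (degrees, 0 = east,
#'   counterclockwise).
#' @param rotation_direction `"left"`, `"right"` or `"unset"`.
#' @param params A [movement_params()] object.
#' @param lookahead_km Lookahead distance (default one half-day step length).
#' @param wall_heading The persistent swimming direction from the previous
#'   step of an ongoing wall-follow (`NA` when moving directly); pass the
#'   returned value back in on the next step.
#' @return List with `heading`, `rotation_direction`, `wall_heading`
#'   (`NA` once the target direction is clear), `ok`.
#' @export
avoid_coast <- function(landscape, position, desired_heading,
                        rotation_direction = "unset",
                        params = movement_params(),
                        lookahead_km = params$speed_km_per_day / 2,
                        wall_heading = NA) {
  r <- avoid_coast_int(landscape, position[1], position[2], desired_heading,
                       rotation_to_int(rotation_direction), wall_heading,
                       params$angle_step_deg, lookahead_km,
                       params$sensing_radius_km)
  list(heading = r$heading %% 360,
       rotation_direction = rotation_from_int(r$rot),
       wall_heading = r$wall_heading, ok = r$ok)
}

# Pull a displacement endpoint back to the last ocean point along the
# segment from (x0, y0) to (x1, y1). Used when currents (or a raycast
# resolution miss) would strand a turtle on land; preserves the no-land
# invariant exactly.
truncate_to_ocean <- function(landscape, x0, y0, x1, y1) {
  bad <- which(is_land(landscape, x1, y1))
  if (!length(bad)) return(list(x = x1, y = y1))
  done <- rep(FALSE, length(bad))
  for (t in seq(0.95, 0.05, by = -0.05)) {
    pos <- which(!done)
    if (!length(pos)) break
    idx <- bad[pos]
    xt <- x0[idx] + t * (x1[idx] - x0[idx])
    yt <- y0[idx] + t * (y1[idx] - y0[idx])
    ok <- !is_land(landscape, xt, yt)
    if (any(ok)) {
      x1[idx[ok]] <- xt[ok]
      y1[idx[ok]] <- yt[ok]
      done[pos[ok]] <- TRUE
    }
  }
  idx <- bad[!done]
  x1[idx] <- x0[idx]
  y1[idx] <- y0[idx]
  list(x = x1, y = y1)
}

#' One migration step toward a target
#'
#' Moves a turtle one half-day step: the motor displacement has length
#' `min(c/2, distance to target)` km (landing exactly on the target when it
#' is within reach) along the desired heading adjusted by wall-following
#' coast avoidance; with `use_currents`, half the current vector at the
#' turtle's cell is added to the motor displacement (true vector addition of
#' motor and drift velocities). The final position is never on a terrestrial
#' cell: if drift would push the turtle ashore, the displacement is
#' truncated at the coast. Each migrating step costs
#' `migration_cost_per_day / 2` energy.
#'
#' @param position `c(x, y)` km on a non-terrestrial cell.
#' @param target_point `c(x, y)` km.
#' @param landscape A `turtle_landscape`.
#' @param params A [movement_params()] object.
#' @param rotation_direction `"left"`, `"right"` or `"unset"`.
#' @param use_currents Add the local current drift?
#' @param wall_heading Persistent wall-follow heading from the previous
#'   step (`NA` when not following); pass the returned value back in.
#' @return List with `position`, `rotation_direction`, `wall_heading`,
#'   `energy_cost`, `ok` (`FALSE` when fully enclosed, in which case the
#'   turtle stays put but still pays the step cost).
#' @export
step_toward <- function(position, target_point, landscape,
                        params = movement_params(),
                        rotation_direction = "unset", use_currents = FALSE,
                        wall_heading = NA) {
  if (is_land(landscape, position[1], position[2])) {
    stop("turtle position on terrestrial cell (corrupt state)")
  }
  step_len <- params$speed_km_per_day / 2
  d <- point_distance(position, target_point)
  desired <- atan2(target_point[2] - position[2],
                   target_point[1] - position[1]) * 180 / pi
  motor_len <- min(step_len, d)
  av <- avoid_coast(landscape, position, desired, rotation_direction, params,
                    lookahead_km = motor_len, wall_heading = wall_heading)
  new <- position
  if (av$ok && motor_len > 0) {
    h <- av$heading * pi / 180
    new <- position + motor_len * c(cos(h), sin(h))
  }
  tr <- truncate_to_ocean(landscape, position[1], position[2], new[1], new[2])
  new <- c(tr$x, tr$y)
  # terminal docking: a target within one clear step is hit exactly, with
  # no drift added (otherwise strong currents could keep a turtle hovering
  # outside the detection range forever). Drift is truncated at the coast
  # separately from the motor leg, so currents can pin a turtle against a
  # shore but never cancel its motor progress.
  docking <- av$ok && d <= step_len && av$heading == desired
  if (use_currents && !docking) {
    ij <- cell_of(landscape, position[1], position[2])
    drifted <- new + 0.5 * c(landscape$current_u[ij$row, ij$col],
                             landscape$current_v[ij$row, ij$col])
    tr <- truncate_to_ocean(landscape, new[1], new[2],
                            drifted[1], drifted[2])
  }
  list(position = c(tr$x, tr$y),
       rotation_direction = av$rotation_direction,
       wall_heading = av$wall_heading,
       energy_cost = params$migration_cost_per_day / 2, ok = av$ok)
}
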