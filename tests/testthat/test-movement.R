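test_that("open-water steps cover the motor speed exactly", {
  ow <- open_world()
  mp <- movement_params()
  pos <- c(14, 70)
  target <- c(126, 70)
  p1 <- step_toward(pos, target, ow, mp)
  p2 <- step_toward(p1$position, target, ow, mp,
                    rotation_direction = p1$rotation_direction)
  # two half-day steps = 65 km, dead straight toward the target
  expect_equal(point_distance(pos, p2$position), 65)
  expect_equal(p2$position[2], 70)
  expect_equal(p1$energy_cost, 5)   # delta_eps_m / 2

  # overshoot: a target within one step is hit exactly
  near <- c(20, 70)
  expect_equal(step_toward(pos, near, ow, mp)$position, near)

  expect_error(step_toward(c(70, 35), c(126, 70), wall_world() , mp,
                           use_currents = FALSE), NA)
  expect_error(step_toward(c(66.5, 35), c(126, 70), wall_world(), mp),
               "terrestrial")
})

test_that("currents add vectorially to the motor displacement", {
  ow <- open_world()
  mp <- movement_params()
  # uniform current fields built by hand
  east_to_west <- landscape(matrix(FALSE, 20, 20),
                            current_u = matrix(-65, 20, 20),
                            current_v = matrix(0, 20, 20),
                            nesting_sites = ow$nesting_sites,
                            feeding_patches = ow$feeding_patches)
  northward <- landscape(matrix(FALSE, 20, 20),
                         current_u = matrix(0, 20, 20),
                         current_v = matrix(65, 20, 20),
                         nesting_sites = ow$nesting_sites,
                         feeding_patches = ow$feeding_patches)
  pos <- c(14, 70)
  target <- c(126, 70)
  # opposing current of equal magnitude: no net displacement
  p <- step_toward(pos, target, east_to_west, mp, use_currents = TRUE)
  expect_equal(p$position, pos, tolerance = 1e-12)
  # motor east + current north: 45 degree drift
  p <- step_toward(pos, target, northward, mp, use_currents = TRUE)
  expect_equal(p$position - pos, c(32.5, 32.5))
  # currents ignored when disabled
  p <- step_toward(pos, target, northward, mp, use_currents = FALSE)
  expect_equal(p$position - pos, c(32.5, 0))
})

test_that("arrival uses a closed detection boundary", {
  expect_true(arrived(c(0, 0), c(0, 0), 7))
  expect_true(arrived(c(7, 0), c(0, 0), 7))
  expect_false(arrived(c(7.0001, 0), c(0, 0), 7))
})

test_that("rotation memory flips on postnesting and clears on foraging", {
  expect_equal(reset_rotation_direction("left", "start_postnesting"), "right")
  expect_equal(reset_rotation_direction("right", "start_postnesting"), "left")
  expect_equal(reset_rotation_direction("unset", "start_postnesting"), "unset")
  expect_equal(reset_rotation_direction("left", "start_prenesting"), "unset")
  expect_equal(reset_rotation_direction("right", "start_foraging_migration"),
               "unset")
  expect_equal(reset_rotation_direction("left", "end_foraging_migration"),
               "unset")
  expect_error(reset_rotation_direction("left", "warp"))
})

test_that("avoidance keeps the heading when clear and memorizes a side", {
  ww <- wall_world()
  mp <- movement_params()
  clear <- avoid_coast(ww, c(14, 35), 90, "unset", mp)
  expect_equal(clear$heading, 90)
  expect_equal(clear$rotation_direction, "unset")
  expect_true(clear$ok)

  # heading due east into the wall from just west of it: a side is chosen
  av <- avoid_coast(ww, c(49, 35), 0, "unset", mp)
  expect_true(av$ok)
  expect_true(av$rotation_direction %in% c("left", "right"))
  expect_false(av$heading == 0)
  # wall spans rows 1..16: turning left (north, toward the gap) clears with
  # a smaller angle than going all the way around the south end
  expect_equal(av$rotation_direction, "left")

  # memorized side is respected even if the other way would be shorter
  av_r <- avoid_coast(ww, c(49, 35), 0, "right", mp)
  expect_true(av_r$ok)
  expect_equal(av_r$rotation_direction, "right")
  # left rotation is counterclockwise (positive), right is clockwise
  expect_gt(sin(av$heading * pi / 180), 0)
  expect_lt(sin(av_r$heading * pi / 180), 0)
})

test_that("wall-following rounds a barrier and reaches the target", {
  ww <- wall_world()
  mp <- movement_params(speed_km_per_day = 30)  # fine steps near the wall
  pos <- c(21, 35)
  target <- c(119, 35)
  rot <- "unset"
  path <- list(pos)
  for (s in 1:60) {
    if (arrived(pos, target, mp$detection_range_km)) break
    st <- step_toward(pos, target, ww, mp, rotation_direction = rot)
    pos <- st$position
    rot <- st$rotation_direction
    expect_false(is_land(ww, pos[1], pos[2]))
    path[[length(path) + 1L]] <- pos
  }
  expect_true(arrived(pos, target, mp$detection_range_km))
  travelled <- sum(vapply(seq_along(path)[-1], function(i)
    point_distance(path[[i - 1]], path[[i]]), numeric(1)))
  expect_gt(travelled, point_distance(c(21, 35), target))

  # the convex single-cell island world is also always traversable
  iw <- island_world()
  pos <- c(14, 66.5); rot <- "unset"
  for (s in 1:40) {
    if (arrived(pos, c(126, 66.5), mp$detection_range_km)) break
    st <- step_toward(pos, c(126, 66.5), iw, mp, rotation_direction = rot)
    pos <- st$position; rot <- st$rotation_direction
    expect_false(is_land(iw, pos[1], pos[2]))
  }
  expect_true(arrived(pos, c(126, 66.5), mp$detection_range_km))
})

test_that("an enclosed turtle stays put and reports failure", {
  land <- matrix(FALSE, 20, 20)
  land[8:12, 8] <- TRUE; land[8:12, 12] <- TRUE
  land[8, 8:12] <- TRUE; land[12, 8:12] <- TRUE
  sites <- data.frame(site_id = 1L, trigram = "BOX", x_km = 14, y_km = 14,
                      weight = 1)
  patches <- data.frame(patch_id = 1:2, x_km = c(21, 119), y_km = c(119, 119))
  box <- landscape(land, nesting_sites = sites, feeding_patches = patches)
  inside <- c(66.5, 66.5)   # center cell of the closed box
  st <- step_toward(inside, c(126, 126), box, movement_params())
  expect_false(st$ok)
  expect_equal(st$position, inside)
})
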