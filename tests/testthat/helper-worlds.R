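# Hand-built micro-worlds used across the tests. All are built in code so
# the expected geometry is auditable by eye.

# 20 x 20 all-ocean world (7 km cells), 1 nesting site, 2 patches 35 km
# apart, no currents.
open_world <- function() generate_synthetic_landscape(1, "minimal")

# 20 x 20 world with a vertical land wall on cell column 10 (x in
# [63, 70) km) spanning cell rows 1..16, open at the north. A turtle west
# of the wall heading east must round the wall's northern end.
wall_world <- function() {
  land <- matrix(FALSE, 20, 20)
  land[1:16, 10] <- TRUE
  sites <- data.frame(site_id = 1L, trigram = "WST", x_km = 14, y_km = 14,
                      weight = 1)
  patches <- data.frame(patch_id = 1:2, x_km = c(21, 119), y_km = c(35, 35))
  landscape(land, nesting_sites = sites, feeding_patches = patches,
            cell_size_km = 7, bbox = c(44, 45.41, -11, -9.61))
}

# Single-cell island in open ocean, for enclosure-free avoidance checks.
island_world <- function() {
  land <- matrix(FALSE, 20, 20)
  land[10, 10] <- TRUE
  sites <- data.frame(site_id = 1L, trigram = "ISL", x_km = 14, y_km = 66.5,
                      weight = 1)
  patches <- data.frame(patch_id = 1:2, x_km = c(126, 126),
                        y_km = c(66.5, 31.5))
  landscape(land, nesting_sites = sites, feeding_patches = patches,
            cell_size_km = 7, bbox = c(44, 45.41, -11, -9.61))
}

# Small fast config for engine tests on the minimal/channel worlds.
mini_config <- function(n_turtles = 20, steps_total = 1200,
                        steps_burn_in = 100, seed = 42, min_allocation = 1,
                        ...) {
  sim_config(n_turtles = n_turtles, steps_total = steps_total,
             steps_burn_in = steps_burn_in, seed = seed,
             min_allocation = min_allocation, ...)
}
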