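test_that("origin diversity is the normalized Shannon index", {
  expect_equal(origin_diversity(c(10, 0, 0, 0), 14), 0)
  expect_equal(origin_diversity(rep(3, 14)), 1)
  # two of 14 sites with a 50/50 split
  v <- numeric(14); v[c(2, 9)] <- 50
  expect_equal(origin_diversity(v), log(2) / log(14), tolerance = 1e-12)
  # bounds hold on random tallies
  set.seed(8)
  for (k in 1:100) {
    v <- rpois(14, 3)
    if (sum(v) == 0) v[1] <- 1
    h <- origin_diversity(v)
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
  expect_error(origin_diversity(rep(0, 14)), "all-zero")
  expect_error(origin_diversity(c(1, 2), n_sites = 1))
})

test_that("remigration intervals convert step gaps to years", {
  ev <- data.frame(turtle_id = c(1, 1), step = c(2000, 4922))
  ri <- remigration_intervals(ev)
  expect_equal(ri$mean_interval_years, 4.0)   # 2,922 steps = 1,461 days
  # single event turtles are excluded
  ev2 <- rbind(ev, data.frame(turtle_id = 2, step = 3000))
  ri2 <- remigration_intervals(ev2)
  expect_equal(ri2$turtle_id, 1L)
  # equally spaced events: mean equals the common spacing
  ev3 <- data.frame(turtle_id = 3, step = c(1000, 2461, 3922))
  expect_equal(remigration_intervals(ev3)$mean_interval_years,
               1461 * 0.5 / 365.25)
  expect_equal(nrow(remigration_intervals(ev[0, ])), 0L)
})

test_that("reproductive output matches its definition and an oracle", {
  # one individual, one interval: eps = 10, dT = 500 days, S_N = 0.5
  ev <- data.frame(turtle_id = 1L, site_id = 1L, step = c(0, 1000),
                   energy_after = c(99, 10))
  expect_equal(reproductive_output(ev, 0.5)$reproductive_output, 0.01)
  # no repeat nester: zero
  ev1 <- data.frame(turtle_id = 1:3, site_id = 1L, step = c(1, 2, 3),
                    energy_after = 5)
  expect_equal(reproductive_output(ev1, 0.7)$reproductive_output, 0)
  # linear in S_N
  set.seed(21)
  ev <- data.frame(turtle_id = rep(1:20, each = 4),
                   site_id = rep(sample(1:5, 20, replace = TRUE), each = 4),
                   step = as.vector(replicate(20, cumsum(c(
                     sample(500:900, 1), sample(800:4000, 3))))),
                   energy_after = runif(80, 0, 300))
  ro1 <- reproductive_output(ev, 0.3, 5)
  ro2 <- reproductive_output(ev, 0.6, 5)
  expect_equal(ro2$reproductive_output, 2 * ro1$reproductive_output)

  # brute-force oracle: an independent event-by-event re-summation
  oracle <- function(events, s_n, n_sites) {
    ro <- numeric(n_sites)
    for (tid in unique(events$turtle_id)) {
      e <- events[events$turtle_id == tid, ]
      e <- e[order(e$step), ]
      if (nrow(e) < 2) next
      for (k in 2:nrow(e)) {
        dt <- (e$step[k] - e$step[k - 1]) * 0.5
        ro[e$site_id[k]] <- ro[e$site_id[k]] + s_n * e$energy_after[k] / dt
      }
    }
    ro
  }
  expect_equal(ro1$reproductive_output, oracle(ev, 0.3, 5))
})

test_that("track sampling is a Bernoulli filter on nesting migrations", {
  # hand-built state: 200 migrating among 500 turtles
  st <- new.env()
  st$state <- rep(c(1L, 2L, 3L, 4L, 5L), c(250, 100, 100, 25, 25))
  st$x <- runif(500, 0, 100); st$y <- runif(500, 0, 100)
  st$site <- rep(1L, 500); st$step <- 77L
  # feeding/nesting/foraging-migration turtles are never sampled
  set.seed(1)
  s <- sample_tracks(st, sampling_period = 1e9)
  expect_equal(nrow(s), 0L)
  set.seed(2)
  s <- do.call(rbind, replicate(30, sample_tracks(st, 1), simplify = FALSE))
  expect_true(all(s$migration_phase %in% c("prenesting", "postnesting")))
  expect_equal(nrow(s), 30 * 200)   # p = 1 samples every migrant
  # binomial expectation at period 500: 10^5 migrating turtle-steps
  set.seed(3)
  n_calls <- 500   # x 200 migrants = 1e5 turtle-steps
  tot <- sum(vapply(seq_len(n_calls), function(i)
    nrow(sample_tracks(st, 500)), numeric(1)))
  expect_lt(abs(tot - 200), 3 * sqrt(1e5 * (1 / 500)))
})

test_that("pooled subsampling reproduces the corridor-input bookkeeping", {
  set.seed(4)
  fake_run <- function(n) data.frame(
    turtle_id = seq_len(n), step = seq_len(n),
    x_km = runif(n, 0, 980), y_km = runif(n, 0, 1120),
    migration_phase = "prenesting", site_id = 1L)
  runs <- replicate(80, fake_run(300), simplify = FALSE)
  pooled <- pool_track_positions(runs, subsample_per_run = 125)
  expect_equal(nrow(pooled), 10000)   # 80 runs x 125 positions
  expect_equal(length(unique(pooled$run)), 80)
  # runs with fewer samples contribute everything they have
  small <- pool_track_positions(list(fake_run(40)), 125)
  expect_equal(nrow(small), 40)
})

test_that("kernel density peaks at the data and integrates to one", {
  ch <- generate_synthetic_landscape(1, "channel")
  one <- data.frame(x_km = 500, y_km = 600)
  kd <- kernel_density(one, ch, bandwidth_km = c(100, 100))
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)
  expect_lt(abs(kd$x[peak[1]] - 500), 10)
  expect_lt(abs(kd$y[peak[2]] - 600), 10)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  expect_equal(sum(kd$z) * cell, 1, tolerance = 0.05)

  # mirror-symmetric samples give a mirror-symmetric surface
  xm <- 980 / 2
  sym <- data.frame(x_km = c(xm - 200, xm + 200, xm - 100, xm + 100),
                    y_km = c(400, 400, 700, 700))
  kd2 <- kernel_density(sym, ch, bandwidth_km = c(80, 80), grid_n = 101)
  expect_equal(kd2$z, kd2$z[rev(seq_along(kd2$x)), ], tolerance = 1e-8)

  expect_error(kernel_density(one[0, ], ch), "no positions")
})

test_that("usage report pools runs additively with origin metrics", {
  ow <- open_world()
  r1 <- run_simulation(mini_config(steps_total = 1500, s_n = 0.3,
                                   t_n_max = 20), ow)
  r2 <- run_simulation(mini_config(steps_total = 1500, s_n = 0.3,
                                   t_n_max = 20, seed = 99), ow)
  u1 <- usage_report(list(r1))
  u12 <- usage_report(list(r1, r2))
  expect_equal(u12$time_usage,
               r1$patch_usage$time_usage + r2$patch_usage$time_usage)
  expect_equal(u12$postnesting_visits,
               r1$patch_usage$postnesting_visits +
                 r2$patch_usage$postnesting_visits)
  # single-rookery world: every visited patch has one origin site
  visited <- u12$postnesting_visits > 0
  expect_true(all(u12$n_origin_sites[visited] == 1))
  expect_true(all(is.na(u12$origin_diversity[!visited])))
  # time usage cannot exceed recorded turtle-steps
  expect_lte(sum(u1$time_usage), 20 * (1500 - 100))
})
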