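# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards, so generators are deterministic without side effects.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Nearest ocean cell center to (x, y), skipping cells in `used` (encoded as
# row + n_rows * col). Expanding square ring search; the worlds built here
# always have ocean within a few cells of any placed feature.
snap_to_ocean <- function(land, cs, x, y, used = integer(0)) {
  n_rows <- nrow(land); n_cols <- ncol(land)
  r0 <- min(floor(y / cs) + 1, n_rows)
  c0 <- min(floor(x / cs) + 1, n_cols)
  key <- function(r, c) r + n_rows * c
  for (ring in 0:max(n_rows, n_cols)) {
    cand <- NULL
    for (dr in -ring:ring) {
      dcs <- if (abs(dr) == ring) -ring:ring else c(-ring, ring)
      for (dc in dcs) {
        r <- r0 + dr; c <- c0 + dc
        if (r >= 1 && r <= n_rows && c >= 1 && c <= n_cols &&
            !land[r, c] && !(key(r, c) %in% used)) {
          cand <- rbind(cand, c(r, c))
        }
      }
    }
    if (!is.null(cand)) {
      cx <- (cand[, 2] - 0.5) * cs
      cy <- (cand[, 1] - 0.5) * cs
      i <- which.min((cx - x)^2 + (cy - y)^2)
      return(c(cx[i], cy[i]))
    }
  }
  stop("no ocean cell found near (", x, ", ", y, ")")
}

# Smooth seeded wiggle added to coastline curves (sum of low-order sines).
coast_wiggle <- function(height, n_terms = 3, amp = c(8, 18)) {
  a <- stats::runif(n_terms, amp[1], amp[2])
  ph <- stats::runif(n_terms, 0, 2 * pi)
  k <- seq_len(n_terms) + 1
  function(y) {
    w <- 0
    for (i in seq_len(n_terms)) w <- w + a[i] * sin(2 * pi * k[i] * y / height + ph[i])
    w
  }
}

# Rotated-ellipse island land mask contribution; returns logical matrix.
ellipse_land <- function(n_rows, n_cols, cs, center, a, b, axis_deg,
                         boundary_amp = 0.06) {
  xs <- (seq_len(n_cols) - 0.5) * cs
  ys <- (seq_len(n_rows) - 0.5) * cs
  ph <- stats::runif(1, 0, 2 * pi)
  th <- axis_deg * pi / 180
  X <- matrix(xs, n_rows, n_cols, byrow = TRUE) - center[1]
  Y <- matrix(ys, n_rows, n_cols) - center[2]
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  s <- sqrt((U / a)^2 + (V / b)^2)
  ang <- atan2(V / b, U / a)
  s < 1 + boundary_amp * sin(5 * ang + ph)
}

#' Generate a synthetic seascape
#'
#' Builds a deterministic (per seed) synthetic world with the structural
#' features of the south-west Indian Ocean study region: a continental
#' coastline to the west, an elongated Madagascar-like barrier island with a
#' channel between the two coasts, clustered feeding patches along the
#' coasts, island rookeries, and a parametric gyre current field.
#'
#' Presets:
#' \describe{
#'   \item{`minimal`}{20 x 20 all-ocean grid, 1 nesting site, 2 feeding
#'     patches, zero currents. The smallest testable world.}
#'   \item{`channel`}{140 x 160 grid with a continental coast, an elongated
#'     barrier island, 24 coastal feeding patches, 4 island rookeries and a
#'     30 km/day gyre. Sized for desk-scale experiments.}
#'   \item{`reference`}{567 x 577 grid of 7 km cells (3,969 x 4,039 km,
#'     25-65 deg E, 30 deg S-10 deg N) with 14 rookeries carrying the
#'     reference relative weights (summing to 30,600) and 47 feeding
#'     patches clustered along the coasts.}
#' }
#'
#' @param seed Integer seed; the same (seed, preset) pair always returns an
#'   identical landscape. The caller's RNG state is untouched.
#' @param preset One of `"minimal"`, `"channel"`, `"reference"`.
#' @return A `turtle_landscape`.
#' @export
generate_synthetic_landscape <- function(seed = 1,
                                         preset = c("minimal", "channel",
                                                    "reference")) {
  preset <- match.arg(preset)
  with_seed(seed, switch(preset,
    minimal = synth_minimal(),
    channel = synth_channel(),
    reference = synth_reference()
  ))
}

synth_minimal <- function() {
  n <- 20L
  cs <- 7
  land <- matrix(FALSE, n, n)
  sites <- data.frame(site_id = 1L, trigram = "SIT",
                      x_km = 35, y_km = 70, weight = 1)
  patches <- data.frame(patch_id = 1:2, x_km = c(105, 105), y_km = c(70, 35))
  landscape(land, nesting_sites = sites, feeding_patches = patches,
            cell_size_km = cs,
            bbox = c(44, 44 + n * cs / 99.225, -11, -11 + n * cs / 100.975))
}

# Shared scaffolding for the coast + island worlds.
build_world <- function(n_rows, n_cols, cs, coast_anchor_y, coast_anchor_x,
                        islands, gyre_center, gyre_radius, gyre_amp,
                        site_spec, cluster_spec, bbox) {
  H <- n_rows * cs
  wig <- coast_wiggle(H)
  x_coast <- function(y) {
    stats::approx(coast_anchor_y, coast_anchor_x, xout = y, rule = 2)$y + wig(y)
  }
  xs <- (seq_len(n_cols) - 0.5) * cs
  ys <- (seq_len(n_rows) - 0.5) * cs
  land <- matrix(xs, n_rows, n_cols, byrow = TRUE) <
    matrix(x_coast(ys), n_rows, n_cols)
  for (isl in islands) {
    land <- land | ellipse_land(n_rows, n_cols, cs, isl$center, isl$a, isl$b,
                                isl$axis)
  }

  # Rookeries: mainland sites sit just offshore of the coast curve; island
  # rookeries get a small land blob next to the (ocean) nesting cell.
  sites <- site_spec
  for (i in seq_len(nrow(sites))) {
    if (sites$mainland[i]) sites$x_km[i] <- x_coast(sites$y_km[i]) + 1.5 * cs
  }
  for (i in which(!sites$mainland)) {
    cx <- sites$x_km[i] + 2 * cs
    cy <- sites$y_km[i]
    rr <- floor(cy / cs) + 1 + (-1:1)
    cc <- floor(cx / cs) + 1 + (-1:1)
    rr <- rr[rr >= 1 & rr <= n_rows]
    cc <- cc[cc >= 1 & cc <= n_cols]
    land[rr, cc] <- TRUE
  }
  # Nesting cells themselves are ocean-side target cells adjacent to land.
  for (i in seq_len(nrow(sites))) {
    r <- min(floor(sites$y_km[i] / cs) + 1, n_rows)
    c <- min(floor(sites$x_km[i] / cs) + 1, n_cols)
    land[r, c] <- FALSE
  }
  used <- integer(0)
  for (i in seq_len(nrow(sites))) {
    p <- snap_to_ocean(land, cs, sites$x_km[i], sites$y_km[i], used)
    sites$x_km[i] <- p[1]; sites$y_km[i] <- p[2]
    used <- c(used, floor(p[2] / cs) + 1 + n_rows * (floor(p[1] / cs) + 1))
  }

  # Feeding patches: jitter around cluster centers, coastal clusters pulled
  # to just offshore of their coast, then snapped to unique ocean cells.
  px <- numeric(0); py <- numeric(0)
  for (cl in cluster_spec) {
    for (k in seq_len(cl$n)) {
      x <- cl$x + stats::rnorm(1, 0, cl$spread)
      y <- cl$y + stats::rnorm(1, 0, cl$spread)
      y <- min(max(y, cs), H - cs)
      if (identical(cl$coastal, "west")) {
        x <- x_coast(y) + cs * stats::runif(1, 0.8, 3.5)
      } else if (identical(cl$coastal, "island")) {
        isl <- islands[[cl$island]]
        th <- isl$axis * pi / 180
        dx <- x - isl$center[1]; dy <- y - isl$center[2]
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        s <- sqrt((u / isl$a)^2 + (v / isl$b)^2)
        s_t <- 1 + stats::runif(1, 0.12, 0.35)
        if (s < 1e-6) { u <- isl$a; v <- 0; s <- 1 }
        u <- u * s_t / s; v <- v * s_t / s
        x <- isl$center[1] + u * cos(th) - v * sin(th)
        y <- isl$center[2] + u * sin(th) + v * cos(th)
      }
      x <- min(max(x, cs), n_cols * cs - cs)
      y <- min(max(y, cs), H - cs)
      p <- snap_to_ocean(land, cs, x, y, used)
      used <- c(used, floor(p[2] / cs) + 1 + n_rows * (floor(p[1] / cs) + 1))
      px <- c(px, p[1]); py <- c(py, p[2])
    }
  }
  patches <- data.frame(patch_id = seq_along(px), x_km = px, y_km = py)

  # Parametric counterclockwise gyre (western-boundary flow southward in the
  # channel, return flow along the outer limbs), zeroed on land.
  X <- matrix(xs, n_rows, n_cols, byrow = TRUE) - gyre_center[1]
  Y <- matrix(ys, n_rows, n_cols) - gyre_center[2]
  r <- pmax(sqrt(X^2 + Y^2), 1e-9)
  sp <- gyre_amp * (r / gyre_radius) * exp(0.5 * (1 - (r / gyre_radius)^2))
  u <- -sp * Y / r
  v <- sp * X / r
  u[land] <- 0; v[land] <- 0

  landscape(land, current_u = u, current_v = v, nesting_sites = sites[
    , c("site_id", "trigram", "x_km", "y_km", "weight")],
    feeding_patches = patches, cell_size_km = cs, bbox = bbox)
}

synth_channel <- function() {
  n_cols <- 140L; n_rows <- 160L; cs <- 7
  islands <- list(list(center = c(640, 560), a = 380, b = 85, axis = 80))
  sites <- data.frame(
    site_id = 1:4, trigram = c("SCH", "NCH", "NIS", "MID"),
    x_km = c(340, 400, 380, 330), y_km = c(180, 700, 950, 420),
    weight = c(10000, 5000, 2000, 200),
    mainland = c(FALSE, FALSE, FALSE, FALSE))
  clusters <- list(
    list(x = 150, y = 200, n = 4, spread = 90, coastal = "west"),
    list(x = 170, y = 550, n = 3, spread = 90, coastal = "west"),
    list(x = 160, y = 900, n = 3, spread = 90, coastal = "west"),
    list(x = 540, y = 650, n = 5, spread = 140, coastal = "island", island = 1),
    list(x = 560, y = 350, n = 3, spread = 100, coastal = "island", island = 1),
    list(x = 740, y = 600, n = 4, spread = 140, coastal = "island", island = 1),
    list(x = 620, y = 140, n = 2, spread = 60, coastal = "none"))
  build_world(n_rows, n_cols, cs,
              coast_anchor_y = c(0, 300, 600, 900, 1120),
              coast_anchor_x = c(120, 150, 135, 160, 140),
              islands = islands,
              gyre_center = c(560, 560), gyre_radius = 450, gyre_amp = 30,
              site_spec = sites, cluster_spec = clusters,
              bbox = c(40, 40 + n_cols * cs / 99.225,
                       -25, -25 + n_rows * cs / 100.975))
}

# Reference rookery registry: trigrams and relative weights of the 14
# south-west Indian Ocean rookeries (weights sum to 30,600).
reference_sites <- function() {
  lonlat <- rbind(
    EUR = c(40.35, -22.35), ALD = c(46.40, -9.40), MAY = c(45.17, -12.83),
    MOH = c(43.73, -12.30), TRO = c(54.52, -15.89), GLO = c(47.30, -11.55),
    TAN = c(39.70, -7.00), IRA = c(47.82, -13.60), JUA = c(42.75, -17.05),
    SEY = c(55.50, -4.58), VAM = c(40.67, -11.03), RUN = c(55.45, -21.10),
    KEN = c(40.90, -2.27), CHA = c(63.50, -7.30))
  w <- c(EUR = 10000, ALD = 5000, MAY = 5000, MOH = 5000, TRO = 2000,
         GLO = 2000, TAN = 200, IRA = 200, JUA = 200, SEY = 200, VAM = 200,
         RUN = 200, KEN = 200, CHA = 200)
  mainland <- c(EUR = FALSE, ALD = FALSE, MAY = FALSE, MOH = FALSE,
                TRO = FALSE, GLO = FALSE, TAN = TRUE, IRA = FALSE,
                JUA = FALSE, SEY = FALSE, VAM = FALSE, RUN = FALSE,
                KEN = TRUE, CHA = FALSE)
  data.frame(site_id = seq_len(nrow(lonlat)), trigram = rownames(lonlat),
             x_km = (lonlat[, 1] - 25) / 40 * 3969,
             y_km = (lonlat[, 2] + 30) / 40 * 4039,
             weight = as.numeric(w[rownames(lonlat)]),
             mainland = as.logical(mainland[rownames(lonlat)]))
}

synth_reference <- function() {
  n_cols <- 567L; n_rows <- 577L; cs <- 7
  lon2x <- function(lon) (lon - 25) / 40 * 3969
  lat2y <- function(lat) (lat + 30) / 40 * 4039
  islands <- list(list(center = c(lon2x(46.7), lat2y(-19)), a = 790, b = 230,
                       axis = 70))
  cl <- function(lon, lat, n, spread, coastal = "none", island = 1) {
    list(x = lon2x(lon), y = lat2y(lat), n = n, spread = spread,
         coastal = coastal, island = island)
  }
  clusters <- list(
    cl(33.0, -24.5, 5, 120, "west"),   # southern Mozambique coast
    cl(40.1, -17.5, 5, 100, "west"),   # central Mozambique coast
    cl(39.6, -6.5, 6, 150, "west"),    # Tanzania / Kenya coast
    cl(47.5, 4.0, 5, 200, "west"),     # Somali coast
    cl(44.3, -18.5, 6, 180, "island"), # west Madagascar
    cl(49.5, -17.5, 4, 150, "island"), # east Madagascar
    cl(44.8, -25.3, 2, 60, "island"),  # south Madagascar
    cl(44.4, -12.4, 4, 80),            # Comoros / Mayotte
    cl(46.8, -10.3, 3, 80),            # Aldabra / Glorieuses
    cl(55.4, -4.7, 3, 70),             # Seychelles
    cl(55.0, -18.5, 2, 120),           # Mascarene
    cl(42.8, -17.0, 1, 0),             # Juan de Nova
    cl(40.3, -22.3, 1, 0))             # Europa
  build_world(n_rows, n_cols, cs,
              coast_anchor_y = lat2y(c(-30, -26, -22, -18, -15, -11, -7, -3,
                                       1, 4, 7, 10)),
              coast_anchor_x = lon2x(c(30.5, 33.5, 35.5, 37.0, 40.3, 40.5,
                                       39.5, 40.2, 42.5, 46.5, 50.0, 52.5)),
              islands = islands,
              gyre_center = c(2600, 1400), gyre_radius = 1200, gyre_amp = 25,
              site_spec = reference_sites(), cluster_spec = clusters,
              bbox = c(25, 65, -30, 10))
}
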