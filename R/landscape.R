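# Cell-type codes used throughout the package.
CELL_OCEAN <- 0L
CELL_LAND <- 1L
CELL_NESTING <- 2L
CELL_PATCH <- 3L

#' Construct a gridded seascape
#'
#' Builds and validates the landscape object used by the simulator: a square
#' grid of cells (terrestrial / ocean / nesting site / feeding patch), a
#' current vector field, and the registries of nesting sites (rookeries) and
#' feeding patches. Positions are continuous `(x, y)` in km with the origin
#' at the south-west corner, x increasing eastward and y northward; the cell
#' containing a point is found by floor division by `cell_size_km`.
#'
#' @param land Logical matrix (`n_rows x n_cols`, row 1 = southernmost row):
#'   `TRUE` for terrestrial cells.
#' @param current_u,current_v Numeric matrices of the same shape: eastward and
#'   northward current components in km/day. Forced to zero on land.
#' @param nesting_sites Data frame with columns `site_id`, `trigram`, `x_km`,
#'   `y_km`, `weight` (relative rookery size used to allocate turtles).
#' @param feeding_patches Data frame with columns `patch_id`, `x_km`, `y_km`.
#' @param cell_size_km Cell edge length in km (default 7, the model's grain).
#' @param bbox Numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in
#'   degrees; used only to convert y to latitude (equirectangular).
#' @return An object of class `turtle_landscape`.
#' @export
landscape <- function(land, current_u = NULL, current_v = NULL,
                      nesting_sites, feeding_patches,
                      cell_size_km = 7, bbox = c(25, 65, -30, 10)) {
  stopifnot(is.matrix(land))
  n_rows <- nrow(land)
  n_cols <- ncol(land)
  if (is.null(current_u)) current_u <- matrix(0, n_rows, n_cols)
  if (is.null(current_v)) current_v <- matrix(0, n_rows, n_cols)
  if (!identical(dim(current_u), dim(land)) ||
      !identical(dim(current_v), dim(land))) {
    stop("raster dimension mismatch between land mask and current components")
  }
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  if (is.null(feeding_patches) || nrow(feeding_patches) == 0L) {
    stop("empty feeding patch registry")
  }
  if (anyDuplicated(nesting_sites$site_id)) stop("duplicate site_id")
  if (anyDuplicated(feeding_patches$patch_id)) stop("duplicate patch_id")
  if (any(nesting_sites$weight <= 0)) stop("nesting site weights must be > 0")

  land <- land == TRUE
  current_u[land] <- 0
  current_v[land] <- 0

  cell_type <- matrix(CELL_OCEAN, n_rows, n_cols)
  cell_type[land] <- CELL_LAND

  obj <- structure(list(
    n_cols = n_cols, n_rows = n_rows, cell_size_km = cell_size_km,
    bbox = stats::setNames(as.numeric(bbox),
                           c("lon_min", "lon_max", "lat_min", "lat_max")),
    cell_type = cell_type, land = land,
    current_u = current_u, current_v = current_v,
    nesting_sites = as.data.frame(nesting_sites),
    feeding_patches = as.data.frame(feeding_patches),
    d_min = NA_real_, d_max = NA_real_
  ), class = "turtle_landscape")

  for (what in c("site", "patch")) {
    reg <- if (what == "site") obj$nesting_sites else obj$feeding_patches
    if (any(!is.finite(reg$x_km)) || any(!is.finite(reg$y_km)) ||
        any(reg$x_km < 0) || any(reg$x_km > n_cols * cell_size_km) ||
        any(reg$y_km < 0) || any(reg$y_km > n_rows * cell_size_km)) {
      stop(what, " coordinates fall outside the grid")
    }
    ij <- cell_of(obj, reg$x_km, reg$y_km)
    idx <- cbind(ij$row, ij$col)
    if (any(land[idx])) {
      bad <- which(land[idx])[1]
      stop(what, " ", reg[[1]][bad], " lies on a terrestrial cell")
    }
    obj$cell_type[idx] <- if (what == "site") CELL_NESTING else CELL_PATCH
  }

  # Pairwise feeding-patch distance extremes; they scale the distance-decay
  # patch choice and therefore belong to the landscape, not the config.
  if (nrow(obj$feeding_patches) >= 2L) {
    d <- as.matrix(stats::dist(obj$feeding_patches[, c("x_km", "y_km")]))
    obj$d_min <- min(d[upper.tri(d)])
    obj$d_max <- max(d[upper.tri(d)])
  } else {
    obj$d_min <- obj$d_max <- 0
  }
  obj
}

#' @export
print.turtle_landscape <- function(x, ...) {
  cat("<turtle_landscape> ", x$n_cols, "x", x$n_rows, " cells of ",
      x$cell_size_km, " km (", round(x$n_cols * x$cell_size_km), " x ",
      round(x$n_rows * x$cell_size_km), " km)\n", sep = "")
  cat("  bbox: ", paste(sprintf("%g", x$bbox), collapse = ", "),
      " (lon_min, lon_max, lat_min, lat_max)\n", sep = "")
  cat("  terrestrial cells: ", sum(x$land), " (",
      sprintf("%.1f%%", 100 * mean(x$land)), ")\n", sep = "")
  cat("  nesting sites: ", nrow(x$nesting_sites),
      "; feeding patches: ", nrow(x$feeding_patches), "\n", sep = "")
  cat("  patch distance range: [", sprintf("%.1f", x$d_min), ", ",
      sprintf("%.1f", x$d_max), "] km\n", sep = "")
  cat("  max current speed: ",
      sprintf("%.1f", max(sqrt(x$current_u^2 + x$current_v^2))),
      " km/day\n", sep = "")
  invisible(x)
}

# Cell indices (1-based, row 1 = southernmost) of continuous km coordinates.
# Points exactly on the north/east grid edge belong to the last cell.
cell_of <- function(landscape, x, y) {
  cs <- landscape$cell_size_km
  col <- pmin(floor(x / cs) + 1L, landscape$n_cols)
  row <- pmin(floor(y / cs) + 1L, landscape$n_rows)
  list(row = as.integer(row), col = as.integer(col))
}

#' Is a point on a terrestrial cell?
#'
#' Points outside the grid count as blocked: grid edges are hard boundaries.
#'
#' @param landscape A `turtle_landscape`.
#' @param x,y Coordinates in km (vectorized).
#' @return Logical vector.
#' @export
is_land <- function(landscape, x, y) {
  cs <- landscape$cell_size_km
  out <- x < 0 | y < 0 | x > landscape$n_cols * cs | y > landscape$n_rows * cs
  res <- rep(TRUE, length(x))
  ok <- !out & is.finite(x) & is.finite(y)
  if (any(ok)) {
    ij <- cell_of(landscape, x[ok], y[ok])
    res[ok] <- landscape$land[cbind(ij$row, ij$col)]
  }
  res
}

#' Planar distance between points
#'
#' Euclidean distance in the grid km frame (the model world is planar; no
#' great-circle correction).
#'
#' @param a,b Numeric vectors `c(x, y)` in km, or two-column matrices for a
#'   vectorized call.
#' @return Distance(s) in km.
#' @export
point_distance <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 2L)
    b <- matrix(b, ncol = 2L)
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  } else {
    sqrt(sum((a - b)^2))
  }
}

# Vectorized ray check: is any cell along the segment from (x0, y0) with
# heading hdg (degrees, 0 = east, counterclockwise) and length len blocked?
# Cells are sampled every half cell plus the segment end, a resolution at
# which a 7 km coastal cell cannot be stepped over; final positions are
# additionally truncated to ocean by the movement code. Off-grid samples
# count as blocked (hard world edges). Hot path: indexes the land matrix
# directly.
ray_blocked <- function(landscape, x0, y0, hdg_deg, len) {
  n <- length(x0)
  len <- rep_len(len, n)
  hdg <- rep_len(hdg_deg, n) * (pi / 180)
  cs <- landscape$cell_size_km
  land <- landscape$land
  nr <- landscape$n_rows
  ncl <- landscape$n_cols
  maxlen <- max(len)
  ts <- seq(cs / 2, maxlen, by = cs / 2)
  if (length(ts) == 0L || ts[length(ts)] < maxlen) ts <- c(ts, maxlen)
  blocked <- rep(FALSE, n)
  first_d <- rep(NA_real_, n)
  cx <- cos(hdg); sy <- sin(hdg)
  act <- seq_len(n)
  for (t in ts) {
    act <- act[len[act] >= t - 1e-9 & !blocked[act]]
    if (!length(act)) break
    tt <- pmin(t, len[act])
    px <- x0[act] + tt * cx[act]
    py <- y0[act] + tt * sy[act]
    col <- floor(px / cs) + 1
    row <- floor(py / cs) + 1
    hit <- col < 1 | col > ncl | row < 1 | row > nr
    ok <- which(!hit)
    if (length(ok)) hit[ok] <- land[row[ok] + (col[ok] - 1) * nr]
    if (any(hit)) {
      idx <- act[hit]
      blocked[idx] <- TRUE
      first_d[idx] <- pmin(t, len[idx])
    }
  }
  list(blocked = blocked, distance = first_d)
}

#' Look ahead for coast along a heading
#'
#' Casts a ray from `position` along `heading_deg` up to
#' `min(lookahead_km, sensing_radius_km)` and reports whether any traversed
#' cell is terrestrial (or off-grid). This is the sensing primitive behind
#' coast avoidance: turtles can sense coastal cells only within a 100 km
#' radius of their location.
#'
#' @param landscape A `turtle_landscape`.
#' @param position `c(x, y)` in km, on a non-terrestrial cell.
#' @param heading_deg Heading in degrees, 0 = east, counterclockwise.
#' @param lookahead_km Distance to check (normally one step length).
#' @param sensing_radius_km Sensing horizon in km (default 100).
#' @return List with `blocked` (flag) and `distance` (km to the first blocked
#'   cell sample, `NA` when clear).
#' @export
coast_ahead <- function(landscape, position, heading_deg, lookahead_km,
                        sensing_radius_km = 100) {
  stopifnot(lookahead_km > 0)
  len <- min(lookahead_km, sensing_radius_km)
  r <- ray_blocked(landscape, position[1], position[2], heading_deg, len)
  list(blocked = r$blocked, distance = r$distance)
}

#' Latitude of a northing coordinate
#'
#' Linear (equirectangular) map from the y coordinate in km to latitude in
#' degrees within the landscape's bounding box.
#'
#' @param landscape A `turtle_landscape`.
#' @param y_km Northing in km (vectorized).
#' @return Latitude in degrees.
#' @export
latitude_of <- function(landscape, y_km) {
  h <- landscape$n_rows * landscape$cell_size_km
  landscape$bbox[["lat_min"]] +
    (y_km / h) * (landscape$bbox[["lat_max"]] - landscape$bbox[["lat_min"]])
}

#' Load a landscape from standard files
#'
#' Reads the land mask and the two current components from ESRI ASCII grids
#' and the site/patch registries from CSV, validates consistency, and returns
#' a `turtle_landscape`. Terrestrial cells are forced to zero current.
#'
#' @param land_mask_file ESRI ASCII grid, 0 = ocean, 1 = land.
#' @param current_u_file,current_v_file ESRI ASCII grids of the eastward and
#'   northward current components (km/day); `NULL` for a still ocean.
#' @param nesting_sites_file CSV with columns `site_id`, `trigram`, `x_km`,
#'   `y_km`, `weight`.
#' @param patches_file CSV with columns `patch_id`, `x_km`, `y_km`.
#' @param cell_size_km Cell size in km; defaults to the mask header value.
#' @param bbox Geographic bounds `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return A `turtle_landscape`.
#' @export
load_landscape <- function(land_mask_file, current_u_file = NULL,
                           current_v_file = NULL, nesting_sites_file,
                           patches_file, cell_size_km = NULL,
                           bbox = c(25, 65, -30, 10)) {
  mask <- read_esri_ascii(land_mask_file)
  if (is.null(cell_size_km)) cell_size_km <- mask$cellsize
  read_comp <- function(f) {
    if (is.null(f)) return(NULL)
    g <- read_esri_ascii(f)
    if (!identical(dim(g$values), dim(mask$values))) {
      stop("raster dimension mismatch: ", f)
    }
    g$values
  }
  sites <- utils::read.csv(nesting_sites_file, stringsAsFactors = FALSE)
  patches <- utils::read.csv(patches_file, stringsAsFactors = FALSE)
  landscape(land = mask$values == 1,
            current_u = read_comp(current_u_file),
            current_v = read_comp(current_v_file),
            nesting_sites = sites, feeding_patches = patches,
            cell_size_km = cell_size_km, bbox = bbox)
}

#' Write a landscape to standard files
#'
#' Writes `land_mask.asc`, `current_u.asc`, `current_v.asc`, `sites.csv`,
#' `patches.csv` and a small `landscape.json` (cell size and bbox) into a
#' directory, in the formats `load_landscape()` reads back.
#'
#' @param landscape A `turtle_landscape`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- landscape$cell_size_km
  write_esri_ascii(landscape$land + 0, file.path(dir, "land_mask.asc"),
                   cellsize = cs)
  write_esri_ascii(landscape$current_u, file.path(dir, "current_u.asc"),
                   cellsize = cs)
  write_esri_ascii(landscape$current_v, file.path(dir, "current_v.asc"),
                   cellsize = cs)
  utils::write.csv(landscape$nesting_sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(landscape$feeding_patches, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(cell_size_km = cs,
                            bbox = as.list(landscape$bbox)),
                       file.path(dir, "landscape.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a landscape previously written by [write_landscape()]
#'
#' @param dir Directory containing the files written by [write_landscape()].
#' @return A `turtle_landscape`.
#' @export
load_landscape_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "landscape.json"),
                              simplifyVector = TRUE)
  load_landscape(file.path(dir, "land_mask.asc"),
                 file.path(dir, "current_u.asc"),
                 file.path(dir, "current_v.asc"),
                 file.path(dir, "sites.csv"),
                 file.path(dir, "patches.csv"),
                 cell_size_km = meta$cell_size_km,
                 bbox = unlist(meta$bbox))
}
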