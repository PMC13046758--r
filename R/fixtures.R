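# Synthetic scenario generator: truth fields on the fine grid plus degraded
# source products (daily constraints, coarse hourly reanalysis with
# accumulated longwave, half-hourly solar, tract polygons, a fine population
# surface, and noisy stations), so the full pipeline and validation harness
# run with no external data.

#' Define a synthetic truth scenario
#'
#' The default is the desk-scale study configuration: a 20 x 20 fine grid at
#' 800 m spacing, a 3 x 3 coarse (~9 km) grid, a 5 x 5 (~4 km) solar grid,
#' five labelled days, twelve tracts and fifteen stations, with a warm-season
#' diurnal cycle (mean 24 deg C, 8 deg C peak-to-trough amplitude, dew point
#' ~6 deg C below the daily mean, moderate wind, 30 % cloudiness).
#'
#' @param seed Integer seed; identical seeds yield identical fixtures.
#' @param nx,ny Fine grid dimensions.
#' @param fine_spacing Fine grid spacing, metres.
#' @param coarse_nx,coarse_ny,coarse_spacing Coarse reanalysis-like grid.
#' @param solar_nx,solar_ny,solar_spacing Solar-product-like grid.
#' @param days Number of consecutive labelled days.
#' @param start_date First label date.
#' @param lat0,lon0 Domain centre, degrees.
#' @param mean_temp Domain mean air temperature, deg C.
#' @param diurnal_amplitude Peak-to-trough diurnal range, deg C.
#' @param dewpoint_offset Mean dew-point depression, deg C.
#' @param wind_scale Wind speed scale, m/s.
#' @param cloudiness Cloud fraction in `[0, 1]`.
#' @param n_tracts,n_stations Tract and station counts.
#' @param total_population Domain population total.
#' @return A scenario list (class `truth_scenario`).
#' @export
truth_scenario <- function(seed = 1L, nx = 20L, ny = 20L, fine_spacing = 800,
                           coarse_nx = 3L, coarse_ny = 3L, coarse_spacing = 9000,
                           solar_nx = 5L, solar_ny = 5L, solar_spacing = 4000,
                           days = 5L, start_date = "2010-07-15",
                           lat0 = 40, lon0 = -95,
                           mean_temp = 24, diurnal_amplitude = 8,
                           dewpoint_offset = 6, wind_scale = 3,
                           cloudiness = 0.3, n_tracts = 12L, n_stations = 15L,
                           total_population = 120000) {
  stopifnot(days >= 1L, nx >= 2L, ny >= 2L, cloudiness >= 0, cloudiness <= 1)
  structure(as.list(environment()), class = "truth_scenario")
}

# centred regular grid in degrees around (lat0, lon0)
.make_grid <- function(nx, ny, spacing, lat0, lon0, elev = TRUE) {
  m_per_deg_lat <- 111319.9
  dlat <- spacing / m_per_deg_lat
  dlon <- spacing / (m_per_deg_lat * cos(lat0 * pi / 180))
  ix <- seq_len(nx) - (nx + 1) / 2
  iy <- seq_len(ny) - (ny + 1) / 2
  g <- expand.grid(lon = lon0 + ix * dlon, lat = lat0 + iy * dlat)
  xn <- rep((ix - min(ix)) / max(diff(range(ix)), 1), times = ny)
  yn <- rep((iy - min(iy)) / max(diff(range(iy)), 1), each = nx)
  elevation <- if (elev) 250 + 120 * sin(pi * xn) * cos(pi * yn) else 0
  gr <- reference_grid(g$lat, g$lon, elevation = elevation)
  gr$xn <- xn; gr$yn <- yn
  gr
}

# clear-sky-shaped irradiance components from cos(zenith) and cloudiness
.solar_components <- function(cosz, cloudiness) {
  cz <- pmax(cosz, 0)
  ghi <- 1050 * cz^1.15 * (1 - 0.75 * cloudiness)
  dhi <- ghi * pmin(0.25 + 0.6 * cloudiness, 1)
  dni <- ifelse(cz > 0.05, (ghi - dhi) / cz, 0)
  list(ghi = ghi, dhi = dhi, dni = dni)
}

# cells x times matrix of cos(zenith)
.cosz_matrix <- function(lat, lon, times) {
  doy <- as.integer(format(times, "%j", tz = "UTC"))
  frac_h <- as.numeric(difftime(times, trunc(times, "days"), units = "hours"))
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  phi <- lat * pi / 180
  nt <- length(times); ncell <- length(lat)
  out <- matrix(0, ncell, nt)
  for (t in seq_len(nt)) {
    ha <- ((frac_h[t] + lon / 15) - 12) * 15 * pi / 180
    out[, t] <- sin(phi) * sin(decl[t]) + cos(phi) * cos(decl[t]) * cos(ha)
  }
  out
}

#' Generate hourly truth fields on the fine grid
#'
#' Air temperature combines a smooth spatial gradient, a shared sinusoidal
#' diurnal shape scaled by a spatially varying amplitude, and a seeded
#' per-window anomaly; because every cell shares the time shape within a
#' window, the normalized diurnal profile is identical across cells and the
#' coarse product derived from the truth carries the truth's own shape (the
#' exact-recovery regime). Dew point sits below air temperature by the
#' scenario offset; pressure follows elevation; longwave fluxes follow a
#' grey-sky Stefan-Boltzmann closure; solar geometry is the analytic
#' zenith model. `diurnal_amplitude = 0` produces flat days and exercises
#' the flat-day normalization rule.
#'
#' @param scenario A [truth_scenario()].
#' @return List with the fine `grid`, `hours` (POSIXct UTC), matrices
#'   (cells x hours) `ta`, `td`, `ps`, `u`, `v`, `ldown`, `lnet`, `cosz`,
#'   `ghi`, `dni`, `dhi`, scalar `albedo`, and the `scenario`.
#' @export
make_truth_fields <- function(scenario) {
  s <- scenario
  set.seed(s$seed)
  grid <- .make_grid(s$nx, s$ny, s$fine_spacing, s$lat0, s$lon0)
  hours <- prism_day_hours(s$start_date, s$days)
  nc <- nrow(grid); nh <- length(hours)
  hutc <- as.numeric(difftime(hours, trunc(hours, "days"), units = "hours"))
  window <- rep(seq_len(s$days), each = 24L)

  shape <- -cos(2 * pi * (hutc - 9) / 24)          # -1 coolest, +1 warmest
  grad <- 2 * sin(2 * pi * grid$xn) * cos(pi * grid$yn)
  amp <- s$diurnal_amplitude / 2 * (0.85 + 0.3 * grid$yn)
  anom <- cumsum(stats::rnorm(s$days, 0, 0.8))     # seeded day-to-day drift

  ta <- matrix(0, nc, nh)
  for (h in seq_len(nh))
    ta[, h] <- s$mean_temp + grad + amp * shape[h] + anom[window[h]]

  td_base <- s$mean_temp + grad - s$dewpoint_offset
  td <- matrix(0, nc, nh)
  for (h in seq_len(nh))
    td[, h] <- td_base + 0.8 * sin(2 * pi * hutc[h] / 24) +
      0.4 * anom[window[h]]

  ps <- matrix(0, nc, nh)
  ps_base <- 101325 * exp(-grid$elevation / 8434)
  for (h in seq_len(nh))
    ps[, h] <- ps_base * (1 + 0.0015 * sin(2 * pi * (hutc[h] - 4) / 24))

  u <- matrix(0, nc, nh); v <- matrix(0, nc, nh)
  for (h in seq_len(nh)) {
    u[, h] <- s$wind_scale * (0.8 + 0.35 * sin(2 * pi * grid$xn + 2 * pi * hutc[h] / 24))
    v[, h] <- s$wind_scale * (0.45 + 0.3 * cos(pi * grid$yn + 2 * pi * hutc[h] / 36))
  }

  cosz <- .cosz_matrix(grid$lat, grid$lon, hours)
  sol <- .solar_components(cosz, s$cloudiness)

  sigma <- .const$sigma
  tak4 <- (ta + .const$t0_k)^4
  emis_sky <- 0.72 + 0.18 * s$cloudiness
  ldown <- emis_sky * sigma * tak4
  lnet <- ldown - 0.98 * sigma * tak4

  list(grid = grid, hours = hours, ta = ta, td = td, ps = ps, u = u, v = v,
       ldown = ldown, lnet = lnet, cosz = cosz,
       ghi = sol$ghi, dni = sol$dni, dhi = sol$dhi, albedo = 0.2,
       scenario = s)
}

#' Degrade truth to the daily constraint product
#'
#' Per cell and 24-hour window: minimum and maximum air temperature and mean
#' dew point, emulating the daily high-resolution product's content.
#'
#' @param truth Output of [make_truth_fields()].
#' @return `data.table` with `cell_id`, `label_date`, `ta_min`, `ta_max`,
#'   `td_mean`.
#' @export
degrade_to_daily <- function(truth) {
  nh <- ncol(truth$ta)
  if (nh %% 24L != 0L) stop("truth must cover whole day windows")
  days <- nh %/% 24L
  start <- as.Date(truth$scenario$start_date)
  out <- vector("list", days)
  for (d in seq_len(days)) {
    cols <- ((d - 1L) * 24L + 1L):(d * 24L)
    out[[d]] <- data.table::data.table(
      cell_id = truth$grid$cell_id,
      label_date = start + (d - 1L),
      ta_min = apply(truth$ta[, cols, drop = FALSE], 1L, min),
      ta_max = apply(truth$ta[, cols, drop = FALSE], 1L, max),
      td_mean = rowMeans(truth$td[, cols, drop = FALSE]))
  }
  data.table::rbindlist(out)
}

#' Degrade truth to a coarse hourly reanalysis-like product
#'
#' Fine cells are block-averaged into their nearest coarse cell for air
#' temperature, dew point, pressure and wind. Longwave fluxes are emitted as
#' within-day running accumulations (J/m2) that reset at 00 UTC, exercising
#' the flux-recovery step.
#'
#' @param truth Output of [make_truth_fields()].
#' @param coarse_grid Optional coarse [reference_grid()]; defaults to the
#'   scenario's coarse grid.
#' @return List with `grid`, `hours`, matrices (coarse cells x hours) `ta`,
#'   `td`, `ps`, `u`, `v`, `ldown_acc`, `lnet_acc`, and the logical
#'   `reset` vector marking accumulation-day starts.
#' @export
degrade_to_coarse_hourly <- function(truth, coarse_grid = NULL) {
  s <- truth$scenario
  if (is.null(coarse_grid))
    coarse_grid <- .make_grid(s$coarse_nx, s$coarse_ny, s$coarse_spacing,
                              s$lat0, s$lon0)
  map <- nearest_source_map(truth$grid, coarse_grid)
  idx <- match(map$source_cell_id, coarse_grid$cell_id)
  ncoarse <- nrow(coarse_grid)
  # coarse cells with no fine members (domain edge) sample the truth at
  # their nearest fine cell instead of a block mean
  fill <- nearest_source_map(coarse_grid, truth$grid)
  fill_idx <- match(fill$source_cell_id, truth$grid$cell_id)
  block_mean <- function(m) {
    out <- matrix(NA_real_, ncoarse, ncol(m))
    bm <- rowsum(m, idx)
    counts <- as.vector(table(idx))
    rows <- as.integer(rownames(bm))
    out[rows, ] <- sweep(bm, 1, counts, "/")
    empty <- setdiff(seq_len(ncoarse), rows)
    if (length(empty)) out[empty, ] <- m[fill_idx[empty], , drop = FALSE]
    out
  }
  hours <- truth$hours
  hutc <- as.integer(format(hours, "%H", tz = "UTC"))
  reset <- hutc == 0L
  reset[1] <- TRUE
  accumulate <- function(flux) {
    acc <- flux * 3600
    out <- acc
    for (h in seq_along(hours)[-1])
      if (!reset[h]) out[, h] <- out[, h - 1] + acc[, h]
    out
  }
  ld <- block_mean(truth$ldown); ln <- block_mean(truth$lnet)
  list(grid = coarse_grid, hours = hours, reset = reset,
       ta = block_mean(truth$ta), td = block_mean(truth$td),
       ps = block_mean(truth$ps), u = block_mean(truth$u),
       v = block_mean(truth$v),
       ldown_acc = accumulate(ld), lnet_acc = accumulate(ln))
}

#' Generate the half-hourly solar product
#'
#' Evaluates the analytic zenith model and the clear-sky-shaped irradiance
#' components at the solar grid points on the half-hour cadence (the two
#' half-hours composing each output hour). Albedo is an 8-day product and is
#' constant over the default scenario length.
#'
#' @param truth Output of [make_truth_fields()].
#' @param solar_grid Optional [reference_grid()]; defaults to the scenario's.
#' @return List with `grid`, `times` (2 per hour), matrices `ghi`, `dni`,
#'   `dhi`, `zenith` (degrees), `albedo`.
#' @export
make_halfhourly_solar <- function(truth, solar_grid = NULL) {
  s <- truth$scenario
  if (is.null(solar_grid))
    solar_grid <- .make_grid(s$solar_nx, s$solar_ny, s$solar_spacing,
                             s$lat0, s$lon0)
  times <- sort(c(truth$hours, truth$hours + 1800))
  cosz <- .cosz_matrix(solar_grid$lat, solar_grid$lon, times)
  sol <- .solar_components(cosz, s$cloudiness)
  zen <- acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
  list(grid = solar_grid, times = times, ghi = sol$ghi, dni = sol$dni,
       dhi = sol$dhi, zenith = zen,
       albedo = matrix(truth$albedo, nrow(solar_grid), length(times)))
}

#' Generate tessellating tract polygons and a fine population surface
#'
#' Tracts are jittered rectangles tiling the grid's bounding box (every
#' centroid falls in exactly one tract). Population is laid on a 4x finer
#' lattice as a mixture of log-normal clumps scaled to the scenario total.
#'
#' @param grid Fine [reference_grid()].
#' @param n_tracts Number of tracts (rounded to a rows x cols tiling).
#' @param seed Integer seed.
#' @param total_population Domain population total.
#' @return List with `tracts` (as from [read_tracts_geojson()]) and
#'   `pop_fine` (`data.table` with `lon`, `lat`, `count`).
#' @export
make_tracts_and_population <- function(grid, n_tracts = 12L, seed = 1L,
                                       total_population = 120000) {
  set.seed(seed + 1000L)
  ncol_t <- max(1L, round(sqrt(n_tracts * 4 / 3)))
  nrow_t <- max(1L, ceiling(n_tracts / ncol_t))
  dlon <- if (length(unique(grid$lon)) > 1) min(diff(sort(unique(grid$lon)))) else 0.01
  dlat <- if (length(unique(grid$lat)) > 1) min(diff(sort(unique(grid$lat)))) else 0.01
  x0 <- min(grid$lon) - dlon / 2; x1 <- max(grid$lon) + dlon / 2
  y0 <- min(grid$lat) - dlat / 2; y1 <- max(grid$lat) + dlat / 2
  jitter_breaks <- function(a, b, n) {
    if (n == 1L) return(c(a, b))
    inner <- seq(a, b, length.out = n + 1L)[2:n]
    span <- (b - a) / n
    c(a, sort(inner + stats::runif(n - 1L, -0.25, 0.25) * span), b)
  }
  bx <- jitter_breaks(x0, x1, ncol_t)
  by <- jitter_breaks(y0, y1, nrow_t)
  tracts <- list(); k <- 0L
  for (r in seq_len(nrow_t)) for (cc in seq_len(ncol_t)) {
    k <- k + 1L
    if (k > n_tracts) break
    ring <- cbind(lon = c(bx[cc], bx[cc + 1], bx[cc + 1], bx[cc], bx[cc]),
                  lat = c(by[r], by[r], by[r + 1], by[r + 1], by[r]))
    tracts[[k]] <- list(geoid = sprintf("T%03d", k), rings = list(ring))
  }
  # last tiles absorb any remainder of the tiling
  if (k < nrow_t * ncol_t && length(tracts) == n_tracts) {
    last <- tracts[[n_tracts]]
    last$rings[[1]][, "lon"] <- pmin(pmax(last$rings[[1]][, "lon"], x0), x1)
    tracts[[n_tracts]] <- last
  }
  nfx <- 4L * length(unique(grid$lon)); nfy <- 4L * length(unique(grid$lat))
  fx <- seq(x0 + (x1 - x0) / nfx / 2, x1 - (x1 - x0) / nfx / 2, length.out = nfx)
  fy <- seq(y0 + (y1 - y0) / nfy / 2, y1 - (y1 - y0) / nfy / 2, length.out = nfy)
  pts <- expand.grid(lon = fx, lat = fy)
  clump <- function(cx, cy, sx, sy)
    exp(-((pts$lon - cx)^2 / (2 * sx^2) + (pts$lat - cy)^2 / (2 * sy^2)))
  cx <- stats::runif(3, x0, x1); cy <- stats::runif(3, y0, y1)
  dens <- 0.05 + clump(cx[1], cy[1], (x1 - x0) / 8, (y1 - y0) / 8) +
    0.6 * clump(cx[2], cy[2], (x1 - x0) / 12, (y1 - y0) / 12) +
    0.3 * clump(cx[3], cy[3], (x1 - x0) / 6, (y1 - y0) / 10)
  dens <- dens * exp(stats::rnorm(length(dens), 0, 0.3))  # log-normal texture
  count <- dens / sum(dens) * total_population
  list(tracts = tracts,
       pop_fine = data.table::data.table(lon = pts$lon, lat = pts$lat,
                                         count = count))
}

#' Generate noisy station series sampling the truth field
#'
#' Stations sit at random cell-interior locations (within 30 % of the cell
#' spacing from a sampled cell's centroid, so each station's nearest grid
#' cell is its host cell) and observe the truth air temperature plus
#' homoscedastic Gaussian noise.
#'
#' @param truth Output of [make_truth_fields()].
#' @param n Number of stations; host cells are sampled with replacement if
#'   `n` exceeds the cell count.
#' @param noise_sd Observation noise standard deviation, deg C.
#' @param seed Integer seed.
#' @return `data.table` with `station_id`, `lat`, `lon`, `timestamp`,
#'   `value`, plus attribute `host_cell` (named integer vector).
#' @export
make_stations <- function(truth, n = 15L, noise_sd = 1, seed = 1L) {
  set.seed(seed + 2000L)
  g <- truth$grid
  nc <- nrow(g)
  cells <- sample(nc, n, replace = n > nc)
  dlon <- if (length(unique(g$lon)) > 1) min(diff(sort(unique(g$lon)))) else 0.01
  dlat <- if (length(unique(g$lat)) > 1) min(diff(sort(unique(g$lat)))) else 0.01
  lat <- g$lat[cells] + stats::runif(n, -0.3, 0.3) * dlat
  lon <- g$lon[cells] + stats::runif(n, -0.3, 0.3) * dlon
  nh <- length(truth$hours)
  obs <- truth$ta[cells, , drop = FALSE] +
    matrix(stats::rnorm(n * nh, 0, noise_sd), n, nh)
  out <- data.table::data.table(
    station_id = rep(sprintf("S%03d", seq_len(n)), times = nh),
    lat = rep(lat, times = nh), lon = rep(lon, times = nh),
    timestamp = rep(truth$hours, each = n),
    value = as.vector(obs))
  data.table::setattr(out, "host_cell",
                      setNames(g$cell_id[cells], sprintf("S%03d", seq_len(n))))
  out
}

#' Build the complete fixture set for a scenario
#'
#' Convenience wrapper producing every pipeline input (truth, daily
#' constraints, coarse hourly product, half-hourly solar, tracts,
#' population, stations) in memory.
#'
#' @param scenario A [truth_scenario()].
#' @return List with elements `truth`, `daily`, `coarse`, `solar`, `tracts`,
#'   `pop_fine`, `stations`, `scenario`.
#' @export
make_fixtures <- function(scenario = truth_scenario()) {
  truth <- make_truth_fields(scenario)
  tp <- make_tracts_and_population(truth$grid, scenario$n_tracts,
                                   scenario$seed, scenario$total_population)
  list(truth = truth,
       daily = degrade_to_daily(truth),
       coarse = degrade_to_coarse_hourly(truth),
       solar = make_halfhourly_solar(truth),
       tracts = tp$tracts, pop_fine = tp$pop_fine,
       stations = make_stations(truth, scenario$n_stations, 1,
                                scenario$seed),
       scenario = scenario)
}
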