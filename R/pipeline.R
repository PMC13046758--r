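# End-to-end orchestration: configuration, fixture file I/O, the staged
# pipeline (align -> reconstruct -> regrid -> ancillary -> indices ->
# aggregate), and the run manifest.

#' Pipeline run configuration
#'
#' @param start_date First labelled output day.
#' @param days Number of consecutive output days.
#' @param seed Seed for the synthetic scenario (fixtures only; the pipeline
#'   itself contains no randomness).
#' @param out_dir Output directory for stage tables, tract files and the
#'   manifest.
#' @param input_dir Optional fixture directory (as written by
#'   [write_fixtures()]); when `NULL`, fixtures are generated in memory from
#'   `scenario`.
#' @param scenario A [truth_scenario()]; defaults to the desk-scale scenario
#'   with `seed`, `start_date` and `days` applied.
#' @param idw_power Inverse-distance weight exponent (default 2).
#' @param k Number of IDW neighbours (default 4).
#' @param cutoff_coarse,cutoff_solar IDW distance cutoffs, metres (defaults
#'   9000 and 4000, the native resolutions of the two source products).
#' @param pressure_adjust Apply the hypsometric elevation adjustment to
#'   interpolated surface pressure (default `FALSE`; see
#'   [adjust_pressure()]).
#' @param night_cos_zenith Nighttime sentinel for the zenith cosine.
#' @param wbgt_tol,wbgt_max_iter Iteration controls for [wbgt_liljegren()].
#' @return A named config list.
#' @export
heattract_config <- function(start_date = "2010-07-15", days = 5L, seed = 1L,
                             out_dir = tempfile("heattract_out_"),
                             input_dir = NULL, scenario = NULL,
                             idw_power = 2, k = 4L,
                             cutoff_coarse = 9000, cutoff_solar = 4000,
                             pressure_adjust = FALSE,
                             night_cos_zenith = .const$night_cos_zenith,
                             wbgt_tol = .const$liljegren$convergence,
                             wbgt_max_iter = .const$liljegren$max_iter) {
  stopifnot(days >= 1L, cutoff_coarse > 0, cutoff_solar > 0, wbgt_tol > 0)
  if (is.null(scenario))
    scenario <- truth_scenario(seed = seed, start_date = start_date,
                               days = days)
  as.list(environment())
}

#' Write a fixture set to a directory in the pipeline's input formats
#'
#' Grids, daily constraints, population and stations as CSV; hourly and
#' half-hourly products as long-format Parquet keyed by (cell_id,
#' timestamp); tracts as GeoJSON; the scenario as YAML.
#'
#' @param fixtures As from [make_fixtures()].
#' @param dir Target directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixtures <- function(fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite_grid <- function(g, fn)
    data.table::fwrite(g[, .(cell_id, lat, lon, elevation)], file.path(dir, fn))
  fwrite_grid(fixtures$truth$grid, "grid.csv")
  fwrite_grid(fixtures$coarse$grid, "coarse_grid.csv")
  fwrite_grid(fixtures$solar$grid, "solar_grid.csv")
  data.table::fwrite(fixtures$daily, file.path(dir, "daily_constraints.csv"))
  long <- function(grid, times, mats) {
    nc <- nrow(grid); nt <- length(times)
    dt <- data.table::data.table(
      cell_id = rep(grid$cell_id, times = nt),
      timestamp = rep(times, each = nc))
    for (nm in names(mats)) dt[[nm]] <- as.vector(mats[[nm]])
    dt
  }
  co <- fixtures$coarse
  arrow::write_parquet(
    long(co$grid, co$hours,
         list(ta = co$ta, td = co$td, ps = co$ps, u = co$u, v = co$v,
              ldown_acc = co$ldown_acc, lnet_acc = co$lnet_acc)),
    file.path(dir, "coarse_hourly.parquet"))
  so <- fixtures$solar
  arrow::write_parquet(
    long(so$grid, so$times,
         list(ghi = so$ghi, dni = so$dni, dhi = so$dhi, zenith = so$zenith,
              albedo = so$albedo)),
    file.path(dir, "solar_halfhourly.parquet"))
  write_tracts_geojson(fixtures$tracts, file.path(dir, "tracts.geojson"))
  data.table::fwrite(fixtures$pop_fine, file.path(dir, "population.csv"))
  data.table::fwrite(fixtures$stations, file.path(dir, "stations.csv"))
  yaml::write_yaml(unclass(fixtures$scenario)[
    !vapply(unclass(fixtures$scenario), is.function, TRUE)],
    file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Write tract polygons as GeoJSON
#'
#' @param tracts Tract list (see [read_tracts_geojson()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tracts_geojson <- function(tracts, path) {
  feat <- lapply(tracts, function(tr) {
    coords <- lapply(tr$rings, function(ring)
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
    list(type = "Feature",
         properties = list(GEOID = tr$geoid),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fixture directory written by [write_fixtures()]
#'
#' @param dir Fixture directory.
#' @return A fixtures list in the in-memory layout of [make_fixtures()]
#'   (without the `truth` element).
#' @export
read_fixture_dir <- function(dir) {
  need <- c("grid.csv", "coarse_grid.csv", "solar_grid.csv",
            "daily_constraints.csv", "coarse_hourly.parquet",
            "solar_halfhourly.parquet", "tracts.geojson", "population.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing fixture input(s): ", paste(missing, collapse = ", "))
  rg <- function(fn) {
    g <- data.table::fread(file.path(dir, fn))
    reference_grid(g$lat, g$lon, g$elevation, g$cell_id)
  }
  grid <- rg("grid.csv"); cgrid <- rg("coarse_grid.csv")
  sgrid <- rg("solar_grid.csv")
  daily <- data.table::fread(file.path(dir, "daily_constraints.csv"))
  daily[, label_date := as.Date(label_date)]
  wide <- function(path, grid, vars) {
    dt <- data.table::as.data.table(arrow::read_parquet(file.path(dir, path)))
    data.table::setorder(dt, timestamp, cell_id)
    times <- unique(dt$timestamp)
    attr(times, "tzone") <- "UTC"
    nc <- nrow(grid)
    mats <- lapply(vars, function(v) matrix(dt[[v]], nc, length(times)))
    names(mats) <- vars
    c(list(grid = grid, times = times), mats)
  }
  co <- wide("coarse_hourly.parquet", cgrid,
             c("ta", "td", "ps", "u", "v", "ldown_acc", "lnet_acc"))
  co$hours <- co$times
  hutc <- as.integer(format(co$hours, "%H", tz = "UTC"))
  co$reset <- hutc == 0L; co$reset[1] <- TRUE
  so <- wide("solar_halfhourly.parquet", sgrid,
             c("ghi", "dni", "dhi", "zenith", "albedo"))
  stations <- if (file.exists(file.path(dir, "stations.csv")))
    data.table::fread(file.path(dir, "stations.csv")) else NULL
  scenario <- if (file.exists(file.path(dir, "scenario.yaml")))
    do.call(truth_scenario, yaml::read_yaml(file.path(dir, "scenario.yaml")))
  else NULL
  list(truth = NULL, daily = daily, coarse = co, solar = so,
       tracts = read_tracts_geojson(file.path(dir, "tracts.geojson")),
       pop_fine = data.table::fread(file.path(dir, "population.csv")),
       stations = stations, scenario = scenario,
       grid = grid)
}

# shared projection over several grids, so all planar distances agree
.shared_projection <- function(...) {
  grids <- list(...)
  lat <- unlist(lapply(grids, `[[`, "lat"))
  lon <- unlist(lapply(grids, `[[`, "lon"))
  rlat <- range(lat)
  list(lat0 = mean(rlat), lon0 = mean(range(lon)),
       par1 = rlat[1] + diff(rlat) / 6, par2 = rlat[2] - diff(rlat) / 6)
}

#' Run the full pipeline
#'
#' Executes the stages in order -- align source series to the noon-to-noon
#' UTC day windows, reconstruct hourly temperature and vapor pressure on the
#' fine grid, convert and interpolate ancillary and radiation fields,
#' derive relative humidity and wind, compute the heat-stress indices, and
#' aggregate to tract-hour records -- writing one Parquet file per labelled
#' day plus stage tables and a JSON run manifest under `config$out_dir`.
#'
#' @param config A [heattract_config()].
#' @param fixtures Optional pre-built fixtures (as from [make_fixtures()]);
#'   defaults to `config$input_dir` when set, else in-memory generation from
#'   `config$scenario`.
#' @return Invisibly, a list with the fine `grid`, `hours`, per-stage
#'   matrices (`ta`, `td`, `e`, `rh`, `ps`, `wind`, `ghi`, `tmrt`, `hi`,
#'   `tw`, `tg`, `wbgt`, `utci`, ...), the tract `lookup`, all tract-hour
#'   `records`, and the written `files`.
#' @export
run_pipeline <- function(config = heattract_config(), fixtures = NULL) {
  t0 <- Sys.time()
  if (is.null(fixtures)) {
    fixtures <- if (!is.null(config$input_dir)) read_fixture_dir(config$input_dir)
    else make_fixtures(config$scenario)
  }
  grid <- if (!is.null(fixtures$truth)) fixtures$truth$grid else fixtures$grid
  co <- fixtures$coarse; so <- fixtures$solar
  # align: subset the source series to the configured run of day windows
  want <- as.Date(config$start_date) + seq_len(config$days) - 1L
  avail <- sort(unique(fixtures$daily$label_date))
  if (!all(want %in% avail))
    stop("align: daily constraints missing for ",
         paste(setdiff(format(want), format(avail)), collapse = ", "))
  want_hours <- prism_day_hours(config$start_date, config$days)
  hsel <- match(want_hours, co$hours)
  if (anyNA(hsel)) stop("align: coarse hourly series does not cover the run")
  # recover fluxes from the running accumulations on the full series, so a
  # run starting mid-archive still differences against the preceding hour
  row_flux <- function(m, f) {
    out <- m
    for (i in seq_len(nrow(m))) out[i, ] <- f(m[i, ], reset = co$reset)
    out
  }
  co$ldown_flux <- row_flux(co$ldown_acc, accumulated_to_flux)
  co$lnet_flux <- row_flux(co$lnet_acc, accumulated_to_flux_signed)
  for (nm in c("ta", "td", "ps", "u", "v", "ldown_flux", "lnet_flux"))
    co[[nm]] <- co[[nm]][, hsel, drop = FALSE]
  co$hours <- co$hours[hsel]
  ssel <- which(so$times >= want_hours[1] &
                  so$times < want_hours[length(want_hours)] + 3600)
  if (length(ssel) != 2L * length(want_hours))
    stop("align: half-hourly solar series does not cover the run")
  for (nm in c("ghi", "dni", "dhi", "zenith", "albedo"))
    so[[nm]] <- so[[nm]][, ssel, drop = FALSE]
  so$times <- so$times[ssel]
  fixtures$daily <- fixtures$daily[label_date %in% want]
  hours <- co$hours
  nh <- length(hours); nc <- nrow(grid)
  ndays <- nh %/% 24L
  label_dates <- want
  stage_rows <- list()

  ## --- reconstruct -----------------------------------------------------
  map <- nearest_source_map(grid, co$grid)
  cidx <- match(map$source_cell_id, co$grid$cell_id)
  daily <- data.table::as.data.table(fixtures$daily)
  data.table::setkey(daily, label_date, cell_id)
  ta <- matrix(NA_real_, nc, nh); td <- matrix(NA_real_, nc, nh)
  e <- matrix(NA_real_, nc, nh)
  for (d in seq_len(ndays)) {
    cols <- ((d - 1L) * 24L + 1L):(d * 24L)
    f_coarse <- diurnal_profile(co$ta[, cols, drop = FALSE])
    f <- f_coarse[cidx, , drop = FALSE]
    con <- daily[.(label_dates[d])][match(grid$cell_id, cell_id)]
    ta[, cols] <- reconstruct_temperature(f, con$ta_min, con$ta_max)
    vp <- reconstruct_vapor_pressure(co$td[cidx, cols, drop = FALSE],
                                     con$td_mean, ta[, cols, drop = FALSE])
    td[, cols] <- vp$td
    e[, cols] <- vp$e
  }
  stage_rows$reconstruct <- nc * nh

  ## --- regrid ----------------------------------------------------------
  proj <- .shared_projection(grid, co$grid, so$grid)
  gxy <- project_planar(grid$lat, grid$lon, proj)
  cxy <- project_planar(co$grid$lat, co$grid$lon, proj)
  sxy <- project_planar(so$grid$lat, so$grid$lon, proj)
  ldown_flux <- co$ldown_flux
  lnet_acc_flux <- co$lnet_flux
  idw_c <- function(m) idw_interpolate(cxy, m, gxy, config$cutoff_coarse,
                                       config$k, config$idw_power)
  ps <- idw_c(co$ps); uu <- idw_c(co$u); vv <- idw_c(co$v)
  ldown <- idw_c(ldown_flux); lnet <- idw_c(lnet_acc_flux)
  odd <- seq(1L, ncol(so$ghi), by = 2L); even <- odd + 1L
  hr <- function(m) halfhour_to_hour(m[, odd, drop = FALSE],
                                     m[, even, drop = FALSE])
  zen_h <- aggregate_zenith(so$zenith[, odd, drop = FALSE],
                            so$zenith[, even, drop = FALSE])
  idw_s <- function(m) idw_interpolate(sxy, m, gxy, config$cutoff_solar,
                                       config$k, config$idw_power)
  ghi <- idw_s(hr(so$ghi)); dni <- idw_s(hr(so$dni)); dhi <- idw_s(hr(so$dhi))
  zen <- idw_s(zen_h); albedo <- idw_s(hr(so$albedo))
  stage_rows$regrid <- nc * nh

  ## --- ancillary -------------------------------------------------------
  if (isTRUE(config$pressure_adjust)) {
    z_src <- co$grid$elevation[cidx]
    tbar <- matrix(rep(rowMeans(ta), nh), nc, nh)
    ps <- adjust_pressure(ps, z_src, grid$elevation, tbar)
  }
  rh <- relative_humidity(ta, e)
  wind <- wind_speed(uu, vv)
  stage_rows$ancillary <- nc * nh

  ## --- indices ---------------------------------------------------------
  cosz <- cos(zen * pi / 180)
  cosz_model <- ifelse(cosz <= 0, config$night_cos_zenith, cosz)
  fdir <- direct_beam_fraction(ghi, dhi)
  hi <- matrix(heat_index(as.vector(ta), as.vector(rh)), nc, nh)
  wb <- wbgt_liljegren(as.vector(ta), as.vector(rh), as.vector(ps),
                       as.vector(wind), as.vector(ghi), as.vector(fdir),
                       as.vector(cosz_model),
                       tol = config$wbgt_tol, max_iter = config$wbgt_max_iter)
  tw <- matrix(wb$tw, nc, nh); tg <- matrix(wb$tg, nc, nh)
  wbgt <- matrix(wb$wbgt, nc, nh)
  nsw <- (1 - albedo) * ghi
  dnih <- dni * pmax(cosz, 0)
  tmrt <- mean_radiant_temperature(ghi, nsw, dni, dnih, ldown, lnet, cosz)
  ut <- matrix(utci(as.vector(ta), as.vector(wind), as.vector(tmrt),
                    as.vector(e)), nc, nh)
  stage_rows$indices <- nc * nh

  ## --- aggregate -------------------------------------------------------
  pop <- resample_population(fixtures$pop_fine, grid)
  lookup <- build_lookup(grid, fixtures$tracts, population = pop)
  cellvals <- data.table::data.table(
    cell_id = rep(grid$cell_id, times = nh),
    hour = rep(seq_len(nh), each = nc),
    temp = as.vector(ta), rh = as.vector(rh), HI = as.vector(hi),
    WBGT = as.vector(wbgt), UTCI = as.vector(ut))
  agg_area <- aggregate_to_tracts(cellvals, lookup, "area", by = "hour")
  agg_pop <- aggregate_to_tracts(cellvals, lookup, "population", by = "hour")
  rec <- merge(agg_area, agg_pop, by = c("geoid", "hour"),
               suffixes = c("_area", "_pop"))
  ts <- hours[rec$hour]
  records <- data.table::data.table(
    GEOID = rec$geoid,
    year = as.integer(format(ts, "%Y", tz = "UTC")),
    month = as.integer(format(ts, "%m", tz = "UTC")),
    day = as.integer(format(ts, "%d", tz = "UTC")),
    time = as.integer(format(ts, "%H", tz = "UTC")),
    temp_C_used_area = rec$temp_area, temp_C_used_pop = rec$temp_pop,
    rh_pct_used_area = rec$rh_area, rh_pct_used_pop = rec$rh_pop,
    HI_C_area = rec$HI_area, HI_C_pop = rec$HI_pop,
    WBGT_C_area = rec$WBGT_area, WBGT_C_pop = rec$WBGT_pop,
    UTCI_C_area = rec$UTCI_area, UTCI_C_pop = rec$UTCI_pop)
  window_of <- rep(seq_len(ndays), each = 24L)[rec$hour]
  stage_rows$aggregate <- nrow(records)

  ## --- write -----------------------------------------------------------
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (d in seq_len(ndays)) {
    ld <- label_dates[d]
    yr <- as.integer(format(ld, "%Y"))
    f <- write_tract_parquet(records[window_of == d],
                             ld, pop_year_for_year(yr), vintage_for_year(yr),
                             out_dir)
    files <- c(files, f)
  }
  hourly_path <- file.path(out_dir, "grid_hourly.parquet")
  arrow::write_parquet(data.table::data.table(
    cell_id = rep(grid$cell_id, times = nh),
    timestamp = rep(hours, each = nc),
    ta = as.vector(ta), td = as.vector(td), e = as.vector(e),
    rh = as.vector(rh), ps = as.vector(ps), wind = as.vector(wind),
    ghi = as.vector(ghi), f_dir = as.vector(fdir), tmrt = as.vector(tmrt),
    hi = as.vector(hi), tw = as.vector(tw), tg = as.vector(tg),
    wbgt = as.vector(wbgt), utci = as.vector(ut)), hourly_path)
  files <- c(files, hourly_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("heattract")),
    created_utc = format(t0, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    config = config[c("start_date", "days", "seed", "idw_power", "k",
                      "cutoff_coarse", "cutoff_solar", "pressure_adjust",
                      "night_cos_zenith", "wbgt_tol", "wbgt_max_iter")],
    svp_variant = .const$buck$variant,
    stage_rows = stage_rows,
    files = basename(files))
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(grid = grid, hours = hours, ta = ta, td = td, e = e, rh = rh,
                 ps = ps, wind = wind, ghi = ghi, dni = dni, dhi = dhi,
                 albedo = albedo, cosz = cosz, f_dir = fdir, ldown = ldown,
                 lnet = lnet, tmrt = tmrt, hi = hi, tw = tw, tg = tg,
                 wbgt = wbgt, utci = ut, lookup = lookup, records = records,
                 label_dates = label_dates, files = c(files, manifest_path),
                 fixtures = fixtures))
}

# accumulated_to_flux for signed fluxes (net longwave may legitimately be
# negative, so no nonnegativity clip)
accumulated_to_flux_signed <- function(acc, reset = NULL) {
  n <- length(acc)
  if (n == 0L) return(numeric(0))
  if (is.null(reset)) reset <- c(TRUE, rep(FALSE, n - 1L))
  flux <- c(acc[1], diff(acc)) / 3600
  flux[reset] <- acc[reset] / 3600
  flux
}
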