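# Grid-to-tract lookup, population resampling, weighted aggregation, and
# the published tract-hour Parquet output schema.

# even-odd ray-casting containment test; vectorized over points.
# Points exactly on an edge follow the ray-casting parity (deterministic);
# polygon processing order resolves shared-boundary ties.
.point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.point_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) inside <- xor(inside, .point_in_ring(px, py, ring))
  inside
}

#' Read tract polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features carrying a
#' `GEOID` property. Interior rings are honoured with even-odd semantics.
#'
#' @param path Path to a GeoJSON file.
#' @return List of tracts, each `list(geoid =, rings = list(<n x 2 lon/lat
#'   matrix>, ...))`, sorted by `geoid`.
#' @export
read_tracts_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("expected a GeoJSON FeatureCollection")
  tracts <- lapply(gj$features, function(f) {
    geoid <- f$properties$GEOID
    if (is.null(geoid)) stop("feature missing GEOID property")
    geom <- f$geometry
    ring_mat <- function(r)
      matrix(unlist(r, use.names = FALSE), ncol = 2L, byrow = TRUE)
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(p) lapply(p, ring_mat)),
                            recursive = FALSE),
      stop(sprintf("unsupported geometry type '%s'", geom$type)))
    list(geoid = as.character(geoid), rings = rings)
  })
  tracts[order(vapply(tracts, `[[`, "", "geoid"))]
}

.validate_tract <- function(tr) {
  for (ring in tr$rings) {
    if (nrow(ring) < 4L || any(!is.finite(ring)))
      stop(sprintf("invalid geometry for tract %s", tr$geoid))
  }
  invisible(tr)
}

#' Build the static grid-to-tract lookup table
#'
#' Assigns each grid-cell centroid to the tract polygon containing it.
#' Polygons are processed in sorted `geoid` order and a cell already claimed
#' is never reassigned, so shared-boundary ties resolve deterministically to
#' the lowest identifier. A tract containing no centroid is assigned its
#' single nearest cell centroid so that every tract receives values (empty
#' output rows would break downstream health linkage). Area weights are the
#' cosine of the cell latitude; population weights are raw resampled counts
#' (attach with [resample_population()]), defaulting to `NA`.
#'
#' @param grid A [reference_grid()] table.
#' @param tracts Tract list as from [read_tracts_geojson()].
#' @param population Optional named vector of per-cell population counts
#'   (names = cell_id) as from [resample_population()].
#' @return `data.table` with columns `geoid`, `cell_id`, `area_weight`,
#'   `pop_weight`.
#' @export
build_lookup <- function(grid, tracts, population = NULL) {
  tracts <- tracts[order(vapply(tracts, `[[`, "", "geoid"))]
  lapply(tracts, .validate_tract)
  assigned <- rep(NA_character_, nrow(grid))
  for (tr in tracts) {
    free <- which(is.na(assigned))
    if (!length(free)) break
    bb <- do.call(rbind, tr$rings)
    cand <- free[grid$lon[free] >= min(bb[, 1]) & grid$lon[free] <= max(bb[, 1]) &
                   grid$lat[free] >= min(bb[, 2]) & grid$lat[free] <= max(bb[, 2])]
    if (!length(cand)) next
    hit <- cand[.point_in_polygon(grid$lon[cand], grid$lat[cand], tr$rings)]
    assigned[hit] <- tr$geoid
  }
  lk <- data.table::data.table(geoid = assigned, cell_id = grid$cell_id,
                               lat = grid$lat)[!is.na(geoid)]
  # fallback for tracts with no member centroid: nearest cell to the
  # polygon's vertex centroid
  empty <- setdiff(vapply(tracts, `[[`, "", "geoid"), lk$geoid)
  if (length(empty)) {
    for (gid in empty) {
      tr <- tracts[[match(gid, vapply(tracts, `[[`, "", "geoid"))]]
      ctr <- colMeans(do.call(rbind, tr$rings))
      xy <- project_planar(c(grid$lat, ctr[2]), c(grid$lon, ctr[1]))
      ng <- nrow(grid)
      d2 <- (xy[seq_len(ng), 1] - xy[ng + 1L, 1])^2 +
        (xy[seq_len(ng), 2] - xy[ng + 1L, 2])^2
      k <- which.min(d2)
      lk <- rbind(lk, data.table::data.table(geoid = gid,
                                             cell_id = grid$cell_id[k],
                                             lat = grid$lat[k]))
    }
  }
  lk[, area_weight := cos(lat * pi / 180)]
  lk[, lat := NULL]
  if (!is.null(population)) {
    lk[, pop_weight := as.numeric(population[as.character(cell_id)])]
    lk[is.na(pop_weight), pop_weight := 0]
  } else {
    lk[, pop_weight := NA_real_]
  }
  data.table::setorder(lk, geoid, cell_id)
  lk[]
}

#' Resample a fine population surface to the reference grid
#'
#' Counts on a finer lattice are summed into the reference cell whose
#' centroid is nearest (equivalently, whose cell contains the fine point on
#' a regular grid), conserving the domain total exactly.
#'
#' @param pop_fine `data.frame` with columns `lon`, `lat`, `count`.
#' @param grid A [reference_grid()] table.
#' @return Named numeric vector of counts, names = `cell_id` (all grid
#'   cells, zeros where no fine point falls).
#' @export
resample_population <- function(pop_fine, grid) {
  out <- setNames(numeric(nrow(grid)), as.character(grid$cell_id))
  if (nrow(pop_fine) == 0L) return(out)
  fine <- reference_grid(pop_fine$lat, pop_fine$lon, spacing_tol = Inf)
  map <- nearest_source_map(fine, grid)
  agg <- tapply(pop_fine$count, map$source_cell_id, sum)
  out[names(agg)] <- agg
  out
}

#' Aggregate per-cell values to tracts by area or population weighting
#'
#' Weighted mean over each tract's member cells, for every value column and
#' (optionally) every hour. Missing member values are excluded with the
#' weights renormalized over the remainder. A tract-hour whose total
#' population weight is zero falls back to area weights (flagged with a
#' message) so coverage is preserved.
#'
#' @param values `data.frame`/`data.table` with a `cell_id` column, optional
#'   grouping columns named in `by`, and numeric value columns.
#' @param lookup Lookup table from [build_lookup()].
#' @param scheme `"area"` or `"population"`.
#' @param by Character vector of grouping columns in `values` (e.g.
#'   `"hour"`); default none.
#' @return `data.table` keyed by `geoid` (and `by` columns) with the
#'   weighted means of every value column.
#' @export
aggregate_to_tracts <- function(values, lookup, scheme = c("area", "population"),
                                by = character()) {
  scheme <- match.arg(scheme)
  dt <- data.table::as.data.table(values)
  valcols <- setdiff(names(dt), c("cell_id", by))
  m <- merge(dt, lookup, by = "cell_id", allow.cartesian = TRUE)
  m[, weight := if (scheme == "area") area_weight else pop_weight]
  if (scheme == "population") {
    # fall back to area weights where a tract(-hour) has zero population
    tot <- m[, .(tot = sum(weight, na.rm = TRUE)), by = c("geoid", by)]
    zero <- tot[tot <= 0]
    if (nrow(zero)) {
      message(sprintf(
        "population weights are zero for %d tract-group(s); using area weights there",
        nrow(zero)))
      m <- merge(m, zero[, c("geoid", by), with = FALSE][, `:=`(.zw = TRUE)],
                 by = c("geoid", by), all.x = TRUE)
      m[.zw == TRUE, weight := area_weight]
      m[, .zw := NULL]
    }
  }
  wm <- function(x, w) {
    ok <- !is.na(x) & !is.na(w) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  out <- m[, lapply(.SD, wm, w = weight), by = c("geoid", by),
           .SDcols = valcols]
  data.table::setorderv(out, c("geoid", by))
  out[]
}

#' Column names of the published tract-hour schema
#'
#' @return Character vector of the 15 output columns.
#' @export
tract_schema <- function() {
  c("GEOID", "year", "month", "day", "time",
    "temp_C_used_area", "temp_C_used_pop",
    "rh_pct_used_area", "rh_pct_used_pop",
    "HI_C_area", "HI_C_pop",
    "WBGT_C_area", "WBGT_C_pop",
    "UTCI_C_area", "UTCI_C_pop")
}

#' Census vintage of the tract boundary set for a data year
#'
#' Decennial rule: the 2000 boundaries serve 2000-2009 (and, as the earliest
#' available set, 1998-1999), the 2010 boundaries 2010-2019, and the 2020
#' boundaries from 2020 on.
#'
#' @param year Integer data year.
#' @return Integer vintage year.
#' @export
vintage_for_year <- function(year) {
  ifelse(year < 2010, 2000L, ifelse(year < 2020, 2010L, 2020L))
}

#' Population-surface year for a data year
#'
#' The annual population surface for the data year, except that the 2000
#' surface backfills 1998-1999 (no earlier surface exists).
#'
#' @param year Integer data year.
#' @return Integer population year.
#' @export
pop_year_for_year <- function(year) pmax(as.integer(year), 2000L)

#' Write one output day of tract-hour records to Parquet
#'
#' One file per labelled day, named
#' `heatstress_tract_area_and_popweighted_[start]_[label]_popy[pop year]_v[vintage].parquet`
#' where `start` is the calendar date on which the 24-hour UTC window opens
#' (the day before the label). Refuses to write unless the columns match
#' [tract_schema()] exactly and every tract carries 24 hourly records.
#'
#' @param records `data.frame` in the [tract_schema()] column order.
#' @param label_date The labelled output day.
#' @param pop_year Population-surface year embedded in the file name.
#' @param vintage Boundary vintage year embedded in the file name.
#' @param dir Output directory.
#' @return Invisibly, the path written.
#' @export
write_tract_parquet <- function(records, label_date, pop_year, vintage, dir) {
  records <- data.table::as.data.table(records)
  if (!identical(names(records), tract_schema()))
    stop("records do not match the published tract-hour schema")
  cnt <- records[, .N, by = GEOID]
  if (any(cnt$N != 24L))
    stop("every tract must carry exactly 24 hourly records per output day")
  d <- as.Date(label_date)
  fn <- sprintf("heatstress_tract_area_and_popweighted_%s_%s_popy%d_v%d.parquet",
                format(d - 1L), format(d), as.integer(pop_year),
                as.integer(vintage))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, fn)
  arrow::write_parquet(records, path)
  invisible(path)
}
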