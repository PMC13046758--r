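# Reference grid, the noon-to-noon UTC day window convention, and
# nearest-source linkage between grids.

#' Construct a reference grid table
#'
#' A reference grid is a flat table of cell centroids rather than a 2-D
#' raster, so irregular (e.g. land-only) subsets are first-class. Cell
#' identifiers must be unique; coordinates must be geographic degrees; the
#' distinct latitude and longitude values must be regularly spaced within
#' `spacing_tol` (relative to the median spacing).
#'
#' @param lat,lon Numeric vectors of centroid coordinates, degrees.
#' @param elevation Numeric vector of cell elevations, metres (recycled).
#' @param cell_id Integer cell identifiers, unique.
#' @param spacing_tol Relative tolerance on the regularity of the distinct
#'   coordinate values (default 1e-3).
#' @return A `data.table` with columns `cell_id`, `lat`, `lon`, `elevation`.
#' @export
reference_grid <- function(lat, lon, elevation = 0,
                           cell_id = seq_along(lat), spacing_tol = 1e-3) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1L)
  if (anyDuplicated(cell_id)) stop("cell_id values must be unique")
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90))
    stop("lat must lie in [-90, 90]")
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180))
    stop("lon must lie in [-180, 180]")
  check_spacing <- function(x, nm) {
    ux <- sort(unique(x))
    if (length(ux) < 3L) return(invisible())
    d <- diff(ux)
    med <- stats::median(d)
    # irregular subsets may skip rows/columns: spacing must be a near-integer
    # multiple of the base step
    mult <- d / med
    if (any(abs(mult - round(mult)) > spacing_tol))
      stop(sprintf("grid %s values are not regularly spaced", nm))
    invisible()
  }
  check_spacing(lat, "lat")
  check_spacing(lon, "lon")
  data.table::data.table(cell_id = as.integer(cell_id), lat = as.numeric(lat),
                         lon = as.numeric(lon),
                         elevation = rep_len(as.numeric(elevation), length(lat)))
}

#' Hourly UTC window labelling an output day
#'
#' Each output day is a 24-hour UTC window running from 12:00 UTC on the day
#' before the label to 11:00 UTC on the labelled day, matching the convention
#' of the daily constraint product. Consecutive windows tile time exactly.
#'
#' @param label_date A `Date` (or string coercible to one).
#' @return A list with `label_date` (Date) and `hours` (POSIXct, UTC,
#'   length 24).
#' @export
#' @examples
#' w <- prism_day_window("2010-07-15")
#' format(range(w$hours), tz = "UTC")
prism_day_window <- function(label_date) {
  d <- as.Date(label_date)
  if (length(d) != 1L || is.na(d)) stop("label_date must be a single valid date")
  start <- as.POSIXct(paste(d - 1L, "12:00:00"), tz = "UTC")
  list(label_date = d, hours = start + 3600 * (0:23))
}

#' All window hours for a run of consecutive labelled days
#'
#' @param start_date First label date.
#' @param n_days Number of consecutive windows.
#' @return POSIXct vector of `24 * n_days` UTC hours.
#' @export
prism_day_hours <- function(start_date, n_days) {
  d <- as.Date(start_date)
  do.call(c, lapply(seq_len(n_days) - 1L,
                    function(k) prism_day_window(d + k)$hours))
}

#' Planar projection of geographic coordinates
#'
#' Projects degrees to metres with an Albers equal-area conic on a spherical
#' earth. Used for all nearest-neighbour and inverse-distance computations;
#' any metric projection is admissible for those purposes, and the conic is
#' configured from the data extent by default.
#'
#' @param lat,lon Coordinates in degrees.
#' @param params Optional list with `lat0`, `lon0`, `par1`, `par2` (degrees);
#'   defaults derived from the data extent.
#' @return A two-column matrix (`x`, `y`) in metres.
#' @export
project_planar <- function(lat, lon, params = NULL) {
  R <- 6371008.8
  if (is.null(params)) {
    rlat <- range(lat)
    params <- list(lat0 = mean(rlat), lon0 = mean(range(lon)),
                   par1 = rlat[1] + diff(rlat) / 6,
                   par2 = rlat[2] - diff(rlat) / 6)
  }
  d2r <- pi / 180
  phi <- lat * d2r; lam <- lon * d2r
  phi0 <- params$lat0 * d2r; lam0 <- params$lon0 * d2r
  phi1 <- params$par1 * d2r; phi2 <- params$par2 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  if (abs(n) < 1e-9) {           # degenerate (equator-symmetric) case:
    x <- R * cos(phi0) * (lam - lam0)  # equal-area cylindrical fallback
    y <- R * sin(phi)
  } else {
    C <- cos(phi1)^2 + 2 * n * sin(phi1)
    rho <- R / n * sqrt(pmax(C - 2 * n * sin(phi), 0))
    rho0 <- R / n * sqrt(max(C - 2 * n * sin(phi0), 0))
    theta <- n * (lam - lam0)
    x <- rho * sin(theta)
    y <- rho0 - rho * cos(theta)
  }
  cbind(x = x, y = y)
}

#' Map every target cell to its nearest source cell
#'
#' Distances are planar metres under [project_planar()] (one shared
#' projection fitted to the union of both grids). Ties are broken towards
#' the lowest source `cell_id` for determinism.
#'
#' @param target,source Reference grids (see [reference_grid()]).
#' @param params Optional projection parameters passed to [project_planar()].
#' @return `data.table` with `target_cell_id`, `source_cell_id`, `distance`
#'   (metres), one row per target cell.
#' @export
nearest_source_map <- function(target, source, params = NULL) {
  if (nrow(source) == 0L) stop("source grid is empty")
  if (nrow(target) == 0L) stop("target grid is empty")
  if (is.null(params)) {
    lat <- c(target$lat, source$lat); lon <- c(target$lon, source$lon)
    rlat <- range(lat)
    params <- list(lat0 = mean(rlat), lon0 = mean(range(lon)),
                   par1 = rlat[1] + diff(rlat) / 6,
                   par2 = rlat[2] - diff(rlat) / 6)
  }
  src <- source[order(source$cell_id)]
  txy <- project_planar(target$lat, target$lon, params)
  sxy <- project_planar(src$lat, src$lon, params)
  nt <- nrow(txy)
  idx <- integer(nt); dst <- numeric(nt)
  chunk <- max(1L, floor(5e6 / nrow(sxy)))
  for (s in seq(1L, nt, by = chunk)) {
    e <- min(s + chunk - 1L, nt)
    d2 <- outer(txy[s:e, 1], sxy[, 1], "-")^2 +
      outer(txy[s:e, 2], sxy[, 2], "-")^2
    j <- max.col(-d2, ties.method = "first")  # first minimum = lowest cell_id
    idx[s:e] <- j
    dst[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
  }
  data.table::data.table(target_cell_id = target$cell_id,
                         source_cell_id = src$cell_id[idx],
                         distance = dst)
}
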