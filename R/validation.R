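# Station-based validation: nearest-cell matching with distance thresholds,
# bias/RMSE/correlation, and station-hour-weighted pooling across windows.

#' Match stations to their nearest grid cell within a distance threshold
#'
#' Each station is matched to the geometrically nearest grid cell (planar
#' distances under [project_planar()]); stations farther than `max_distance`
#' from any cell are excluded. Use a threshold consistent with the grid's
#' resolution (e.g. 800 m for an 800 m grid, 9 km for a ~9 km grid).
#'
#' @param stations `data.frame` with columns `station_id`, `lat`, `lon` (one
#'   row per station).
#' @param grid A [reference_grid()] table.
#' @param max_distance Maximum matching distance, metres.
#' @return `data.table` with `station_id`, `cell_id`, `distance` for matched
#'   stations only.
#' @export
match_stations <- function(stations, grid, max_distance) {
  stopifnot(max_distance > 0)
  st <- unique(data.table::as.data.table(stations)[, .(station_id, lat, lon)])
  sg <- reference_grid(st$lat, st$lon, cell_id = seq_len(nrow(st)),
                       spacing_tol = Inf)
  map <- nearest_source_map(sg, grid)
  out <- data.table::data.table(station_id = st$station_id,
                                cell_id = map$source_cell_id,
                                distance = map$distance)
  excluded <- out[distance > max_distance]
  if (nrow(excluded))
    message(sprintf("excluded %d station(s) beyond %.0f m", nrow(excluded),
                    max_distance))
  out[distance <= max_distance]
}

#' Error statistics for matched model/observation pairs
#'
#' Bias is `mean(model - obs)` (positive = warm model), RMSE is
#' `sqrt(mean((model - obs)^2))`, and `pearson_r` is the Pearson correlation
#' over the pairs. Pairs with a missing member are dropped; fewer than two
#' valid pairs leave the correlation undefined.
#'
#' @param obs,model Numeric vectors, time-aligned.
#' @return One-row `data.table`: `n`, `bias`, `rmse`, `pearson_r`.
#' @export
error_metrics <- function(obs, model) {
  ok <- !is.na(obs) & !is.na(model)
  obs <- obs[ok]; model <- model[ok]
  n <- length(obs)
  if (n == 0L)
    return(data.table::data.table(n = 0L, bias = NA_real_, rmse = NA_real_,
                                  pearson_r = NA_real_))
  d <- model - obs
  r <- if (n >= 2L && stats::sd(obs) > 0 && stats::sd(model) > 0)
    stats::cor(obs, model) else NA_real_
  data.table::data.table(n = n, bias = mean(d), rmse = sqrt(mean(d^2)),
                         pearson_r = r)
}

#' Pool window-level error statistics with station-hour weights
#'
#' Window-level bias and mean-squared error are combined as weighted means
#' (weights = matched station-hours per window) and the pooled RMSE is the
#' square root of the pooled MSE; with pair counts as weights this equals
#' recomputing the metrics over all pooled pairs exactly. The correlation is
#' pooled as a weighted mean of window correlations (descriptive only - it
#' is not the correlation of the concatenated pairs).
#'
#' @param summaries `data.frame` of window summaries with columns `bias`,
#'   `rmse`, and optionally `pearson_r`.
#' @param weights Nonnegative weights (matched station-hours), at least one
#'   positive.
#' @return One-row `data.table`: `n`, `bias`, `rmse`, `pearson_r`.
#' @export
pool_windows <- function(summaries, weights) {
  s <- data.table::as.data.table(summaries)
  if (any(weights < 0) || all(weights == 0) || length(weights) != nrow(s))
    stop("weights must be nonnegative, sum positive, one per window")
  w <- weights / sum(weights)
  r <- if ("pearson_r" %in% names(s) && any(!is.na(s$pearson_r)))
    stats::weighted.mean(s$pearson_r, w, na.rm = TRUE) else NA_real_
  data.table::data.table(n = sum(weights),
                         bias = sum(w * s$bias),
                         rmse = sqrt(sum(w * s$rmse^2)),
                         pearson_r = r)
}
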