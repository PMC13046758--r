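# Temporal preprocessing of radiation series and inverse-distance
# interpolation of coarse fields onto the reference grid.

#' Convert accumulated radiation to mean hourly flux
#'
#' Reanalysis longwave radiation arrives as within-day running accumulations
#' (J/m2). Differencing successive hours and dividing by 3600 s yields the
#' mean flux over each hour. At an accumulation reset (the first step of an
#' accumulation day, where the series restarts near zero) the accumulated
#' value itself is the hour's integral, so the flux is `acc/3600`. Negative
#' differences (a reset not declared in `reset`) are clipped to zero with a
#' warning.
#'
#' @param acc Numeric vector of hourly accumulated values, J/m2.
#' @param reset Logical vector marking the first hour of each accumulation
#'   day; defaults to the first element only.
#' @return Numeric vector of fluxes, W/m2, same length as `acc`.
#' @export
#' @examples
#' accumulated_to_flux(c(3600, 7200, 10800))  # 1 1 1
accumulated_to_flux <- function(acc, reset = NULL) {
  n <- length(acc)
  if (n == 0L) return(numeric(0))
  if (is.null(reset)) reset <- c(TRUE, rep(FALSE, n - 1L))
  if (length(reset) != n) stop("reset must match acc in length")
  flux <- c(acc[1], diff(acc)) / 3600
  flux[reset] <- acc[reset] / 3600
  neg <- which(flux < 0)
  if (length(neg)) {
    warning(sprintf("clipped %d negative accumulation difference(s) to zero",
                    length(neg)))
    flux[neg] <- 0
  }
  flux
}

#' Aggregate adjacent half-hour samples to an hourly value
#'
#' Arithmetic mean of the two half-hours; if exactly one sample is missing
#' the remaining sample is used; both missing yields missing.
#'
#' @param first_half,second_half Numeric vectors of the two half-hour samples.
#' @return Hourly means.
#' @export
halfhour_to_hour <- function(first_half, second_half) {
  out <- (first_half + second_half) / 2
  only1 <- is.na(second_half) & !is.na(first_half)
  only2 <- is.na(first_half) & !is.na(second_half)
  out[only1] <- first_half[only1]
  out[only2] <- second_half[only2]
  out
}

#' Aggregate half-hourly solar zenith angles to hourly
#'
#' Averaging is performed on `cos(theta_z)` and converted back to degrees,
#' preserving radiative consistency:
#' `theta = acos(mean(cos(theta1), cos(theta2)))`.
#'
#' @param theta1,theta2 Half-hour zenith angles, degrees in `[0, 180]`.
#' @return Hourly zenith angle, degrees.
#' @export
#' @examples
#' aggregate_zenith(0, 90)  # 60
aggregate_zenith <- function(theta1, theta2) {
  if (any(c(theta1, theta2) < 0 | c(theta1, theta2) > 180, na.rm = TRUE))
    stop("zenith angles must lie in [0, 180] degrees")
  d2r <- pi / 180
  acos(halfhour_to_hour(cos(theta1 * d2r), cos(theta2 * d2r))) / d2r
}

#' Four-neighbour inverse-distance interpolation with a distance cutoff
#'
#' For each target point the `k` nearest source points within `cutoff`
#' contribute with weights proportional to `1/d^power`. Missing neighbour
#' values are ignored (weights renormalized over the valid neighbours), so
#' the scheme degenerates to nearest-neighbour weighting when only one valid
#' source remains. A target coincident with a source point returns that
#' source's value exactly. No valid source within the cutoff yields a
#' missing value, not an error.
#'
#' @param source_points Two-column matrix of projected source coordinates
#'   (metres), e.g. from [project_planar()].
#' @param source_values Numeric vector (one value per source point) or
#'   matrix (source points x time steps).
#' @param target_points Two-column matrix of projected target coordinates.
#' @param cutoff Maximum contributing distance, metres.
#' @param k Number of nearest neighbours (default 4).
#' @param power Inverse-distance weight exponent (default 2).
#' @return Vector (or matrix, targets x time steps) of interpolated values.
#' @export
idw_interpolate <- function(source_points, source_values, target_points,
                            cutoff, k = 4L, power = 2) {
  stopifnot(cutoff > 0, k >= 1L)
  src <- as.matrix(source_points)
  tgt <- as.matrix(target_points)
  vec_in <- !is.matrix(source_values)
  vals <- if (vec_in) matrix(source_values, ncol = 1L) else source_values
  if (nrow(vals) != nrow(src)) stop("source_values rows must match source_points")
  nt <- nrow(tgt); ns <- nrow(src)
  k <- min(as.integer(k), ns)
  nb_idx <- matrix(NA_integer_, nt, k)
  nb_w <- matrix(0, nt, k)
  coincident <- integer(nt)  # 0 = none, else source row index
  chunk <- max(1L, floor(5e6 / ns))
  for (s in seq(1L, nt, by = chunk)) {
    e <- min(s + chunk - 1L, nt)
    d2 <- outer(tgt[s:e, 1], src[, 1], "-")^2 + outer(tgt[s:e, 2], src[, 2], "-")^2
    for (r in seq_len(e - s + 1L)) {
      d <- sqrt(d2[r, ])
      ord <- order(d)[seq_len(k)]
      keep <- ord[d[ord] <= cutoff]
      if (!length(keep)) next
      i <- s + r - 1L
      if (d[keep[1]] < 1e-9) coincident[i] <- keep[1]
      nb_idx[i, seq_along(keep)] <- keep
      nb_w[i, seq_along(keep)] <- 1 / pmax(d[keep], 1e-9)^power
    }
  }
  # weighted mean with NA neighbours dropped: accumulate numerator and the
  # weight mass of valid values, then renormalize
  ntime <- ncol(vals)
  num <- matrix(0, nt, ntime)
  den <- matrix(0, nt, ntime)
  valid <- !is.na(vals)
  v0 <- vals; v0[!valid] <- 0
  for (j in seq_len(k)) {
    idx <- nb_idx[, j]
    has <- !is.na(idx)
    if (!any(has)) next
    w <- nb_w[has, j]
    num[has, ] <- num[has, ] + w * v0[idx[has], , drop = FALSE]
    den[has, ] <- den[has, ] + w * valid[idx[has], , drop = FALSE]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  # exact pass-through at coincident points (where the source value is valid)
  co <- which(coincident > 0L)
  for (i in co) {
    sv <- vals[coincident[i], ]
    ok <- !is.na(sv)
    out[i, ok] <- sv[ok]
  }
  if (vec_in) out[, 1] else out
}
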