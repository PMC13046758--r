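# Hourly temperature and vapor-pressure reconstruction: daily fine-grid
# constraints rescale the diurnal shape borrowed from a coarse hourly source.

#' Unitless diurnal scaling profile from an hourly temperature day
#'
#' Normalizes a 24-hour temperature series to its own extrema:
#' `f(h) = (T(h) - Tmin) / (Tmax - Tmin)`, so the coolest hour maps to 0 and
#' the warmest to 1. A flat day (`Tmax == Tmin`) yields `f(h) = 0.5`
#' everywhere, which reconstructs the midpoint of the daily constraint range.
#'
#' @param ta_hourly Numeric vector of 24 hourly values (deg C), or a matrix
#'   with 24 columns (cells x hours).
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
diurnal_profile <- function(ta_hourly) {
  if (is.matrix(ta_hourly)) {
    if (ncol(ta_hourly) != 24L) stop("expected 24 hourly columns")
    lo <- apply(ta_hourly, 1L, min)
    hi <- apply(ta_hourly, 1L, max)
    rng <- hi - lo
    f <- (ta_hourly - lo) / ifelse(rng > 0, rng, 1)
    f[rng == 0, ] <- 0.5
    return(f)
  }
  if (length(ta_hourly) != 24L) stop("expected 24 hourly values")
  lo <- min(ta_hourly); hi <- max(ta_hourly)
  if (!is.finite(lo) || !is.finite(hi)) stop("profile input must be finite")
  if (hi == lo) return(rep(0.5, 24L))
  (ta_hourly - lo) / (hi - lo)
}

#' Rescale a diurnal profile to daily temperature extrema
#'
#' `Ta(h) = Ta_min + f(h) * (Ta_max - Ta_min)`. When the profile attains 0
#' and 1 the reconstructed day conserves the daily extrema exactly.
#'
#' @param profile Profile from [diurnal_profile()] (vector of 24 or matrix).
#' @param ta_min,ta_max Daily extrema (deg C); scalars for a vector profile,
#'   vectors of `nrow(profile)` for a matrix.
#' @return Hourly temperatures, same shape as `profile`.
#' @export
reconstruct_temperature <- function(profile, ta_min, ta_max) {
  if (any(ta_min > ta_max, na.rm = TRUE))
    stop("invalid daily constraint: ta_min > ta_max")
  ta_min + profile * (ta_max - ta_min)
}

#' Saturation vapor pressure (Buck, over water)
#'
#' The pipeline-wide saturation curve:
#' `es(T) = 6.1121 exp((18.678 - T/234.5) T / (257.14 + T))` hPa, the Buck
#' 1996 over-water expression. The chosen variant is recorded in
#' [heattract_constants()] and used consistently for vapor pressure,
#' relative humidity and station dew-point conversion. (The wet-bulb/globe
#' solver keeps the Liljegren model's own internal saturation curve.)
#'
#' @param t_c Temperature, deg C.
#' @return Saturation vapor pressure, hPa. Non-finite input propagates.
#' @export
#' @examples
#' svp_buck(0)    # 6.1121
#' svp_buck(20)
svp_buck <- function(t_c) {
  b <- .const$buck
  b$b0 * exp((b$b1 - t_c / b$b2) * t_c / (b$b3 + t_c))
}

#' Reconstruct hourly dew point and vapor pressure for one day window
#'
#' The source hourly dew-point profile is shifted additively so that its
#' window mean equals the daily mean constraint
#' (`dTd = Td_mean - mean(Td_source)`), converted to vapor pressure with
#' [svp_buck()], and capped at saturation with respect to the reconstructed
#' air temperature (the cap acts in vapor-pressure space; the corrected
#' dew-point series itself is left untouched, so its mean is conserved
#' exactly).
#'
#' @param td_source_hourly 24 source dew points (deg C), vector or
#'   cells x 24 matrix.
#' @param td_mean Daily mean dew-point constraint (deg C); scalar or vector
#'   of `nrow`.
#' @param ta_recon Reconstructed hourly air temperature, same shape as
#'   `td_source_hourly`.
#' @return List with elements `td` (corrected dew point, deg C) and `e`
#'   (vapor pressure, hPa, capped at `es(Ta)`), each the shape of the input.
#' @export
reconstruct_vapor_pressure <- function(td_source_hourly, td_mean, ta_recon) {
  if (is.matrix(td_source_hourly)) {
    delta <- td_mean - rowMeans(td_source_hourly)
    td <- td_source_hourly + delta
  } else {
    td <- td_source_hourly + (td_mean - mean(td_source_hourly))
  }
  e <- pmin(svp_buck(td), svp_buck(ta_recon))
  list(td = td, e = e)
}
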