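# Derived surface variables: relative humidity, wind speed, and the optional
# elevation adjustment of interpolated surface pressure.

#' Relative humidity from air temperature and vapor pressure
#'
#' `RH = 100 e / es(Ta)` with the pipeline Buck curve ([svp_buck()]),
#' clipped to `[0, 100]`. Because vapor pressure is already capped at
#' saturation upstream, the clip is a numerical guard rather than a physical
#' correction.
#'
#' @param ta_c Air temperature, deg C.
#' @param e_hpa Vapor pressure, hPa.
#' @return Relative humidity, percent.
#' @export
relative_humidity <- function(ta_c, e_hpa) {
  pmin(pmax(100 * e_hpa / svp_buck(ta_c), 0), 100)
}

#' Wind speed from zonal and meridional components
#'
#' @param u,v Wind components, m/s.
#' @return Vector magnitude `sqrt(u^2 + v^2)`, m/s.
#' @export
wind_speed <- function(u, v) sqrt(u^2 + v^2)

#' Hypsometric elevation adjustment of surface pressure
#'
#' Rescales pressure from the source elevation to the target elevation under
#' hydrostatic balance with temperature-dependent density:
#' `P_adj = P_ref exp(-g (z_target - z_source) / (Rd T))`, `T` in kelvin.
#' A target below its source therefore receives higher pressure, and the
#' adjustment is its own inverse under swapped elevations. The pipeline
#' default leaves interpolated pressure unadjusted (`pressure_adjust`
#' config flag, off by default, applied over land cells only); the
#' adjustment made no meaningful difference to the heat-stress outputs.
#'
#' @param ps_ref Reference surface pressure, Pa.
#' @param z_source Elevation of the source grid, m.
#' @param z_target Elevation of the target cell, m.
#' @param t_mean_c Layer mean temperature, deg C.
#' @return Adjusted pressure, Pa.
#' @export
adjust_pressure <- function(ps_ref, z_source, z_target, t_mean_c) {
  t_k <- t_mean_c + .const$t0_k
  if (any(t_k <= 0, na.rm = TRUE))
    stop("nonpositive absolute temperature")
  ps_ref * exp(-.const$g * (z_target - z_source) / (.const$Rd * t_k))
}
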