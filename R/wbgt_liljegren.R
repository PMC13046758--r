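# Liljegren natural wet-bulb / black-globe energy-balance model.
#
# Vectorized port of the published Liljegren et al. (2008) algorithm: the
# wick balances convective and radiative gains against evaporation, the
# globe balances absorbed solar and longwave against convection and
# emission, both solved by the original damped fixed-point iteration
# (update 0.9*prev + 0.1*new, convergence 0.02 K, cap 50 iterations).
# Internal units follow the C code: kelvin, hPa, relative humidity as a
# fraction. The model's own Buck-1981 saturation curve (1.004 enhancement
# factor) and Stefan-Boltzmann value are kept as published; see
# heattract_constants()$liljegren.

.lil <- function() .const$liljegren

# saturation vapor pressure over water, hPa (Liljegren's internal form)
.esat_lil <- function(tk) {
  1.004 * 6.1121 * exp(17.502 * (tk - 273.15) / (tk - 32.18))
}

.dewpoint_lil <- function(e_hpa) {
  z <- log(e_hpa / (6.1121 * 1.004))
  273.15 + 240.97 * z / (17.502 - z)
}

# dynamic viscosity of air, kg/(m s)
.viscosity <- function(tk) {
  L <- .lil()
  tr <- tk / 97
  omega <- (tr - 2.9) / 0.4 * (-0.034) + 1.048
  2.6693e-6 * sqrt(L$m_air * tk) / (3.617^2 * omega)
}

.thermal_cond <- function(tk) {
  L <- .lil()
  (L$cp + 1.25 * L$r_air) * .viscosity(tk)
}

# diffusivity of water vapor in air, m2/s
.diffusivity <- function(tk, pair_hpa) {
  pcrit13 <- (36.4 * 218)^(1 / 3)
  tcrit512 <- (132 * 647.3)^(5 / 12)
  tcrit12 <- sqrt(132 * 647.3)
  mmix <- sqrt(1 / 28.97 + 1 / 18.015)
  3.64e-4 * (tk / tcrit12)^2.334 * pcrit13 * tcrit512 * mmix /
    (pair_hpa / 1013.25) * 1e-4
}

# latent heat of vaporization, J/kg
.evap_heat <- function(tk) (313.15 - tk) / 30 * (-71100) + 2.4073e6

.emis_atm <- function(tk, rh_frac) 0.575 * (rh_frac * .esat_lil(tk))^0.143

# convective coefficients; speed already floored at min_speed by callers
.h_sphere <- function(tk, pair_hpa, speed) {
  L <- .lil()
  density <- pair_hpa * 100 / (L$r_air * tk)
  re <- speed * density * L$diam_globe / .viscosity(tk)
  nu <- 2 + 0.6 * sqrt(re) * L$Pr^0.3333
  nu * .thermal_cond(tk) / L$diam_globe
}

.h_cylinder <- function(tk, pair_hpa, speed) {
  L <- .lil()
  density <- pair_hpa * 100 / (L$r_air * tk)
  re <- speed * density * L$diam_wick / .viscosity(tk)
  nu <- 0.281 * re^(1 - 0.4) * L$Pr^0.3333
  nu * .thermal_cond(tk) / L$diam_wick
}

# Pasquill stability class from wind and insolation (srdt method); night
# falls on the stable side because no vertical temperature gradient is
# available to the pipeline.
.stability_class <- function(daytime, speed10, solar) {
  day_table <- matrix(c(1, 1, 2, 4,
                        1, 2, 3, 4,
                        2, 2, 3, 4,
                        3, 3, 4, 4,
                        3, 4, 4, 4), nrow = 5, byrow = TRUE)
  j <- ifelse(solar >= 925, 1L, ifelse(solar >= 675, 2L,
                                       ifelse(solar >= 175, 3L, 4L)))
  i <- ifelse(speed10 >= 6, 5L, ifelse(speed10 >= 5, 4L,
                                       ifelse(speed10 >= 3, 3L,
                                              ifelse(speed10 >= 2, 2L, 1L))))
  cls <- day_table[cbind(i, j)]
  night <- !daytime
  cls[night] <- ifelse(speed10[night] >= 2.5, 4L, 6L)
  cls
}

#' Estimate 2 m wind speed from 10 m wind
#'
#' Power-law profile with a stability-class-dependent (rural) exponent as in
#' the Liljegren model: the class is estimated from wind speed and solar
#' irradiance during daytime and taken as stable at night. The result is
#' floored at the model minimum of 0.13 m/s.
#'
#' @param u10 10 m wind speed, m/s.
#' @param solar Global horizontal irradiance, W/m2.
#' @param cos_zenith Cosine of the solar zenith (negative sentinel at night).
#' @return 2 m wind speed, m/s.
#' @export
wind_speed_2m <- function(u10, solar, cos_zenith) {
  L <- .lil()
  n <- max(length(u10), length(solar), length(cos_zenith))
  u10 <- rep_len(u10, n); solar <- rep_len(solar, n)
  cos_zenith <- rep_len(cos_zenith, n)
  daytime <- solar > 0 & cos_zenith > 0
  cls <- .stability_class(daytime, u10, solar)
  est <- u10 * (L$ref_height / 10)^L$rural_exponents[cls]
  pmax(est, L$min_speed)
}

# single damped fixed-point sweep for the globe temperature, kelvin
.tglobe_solve <- function(tk, rh, pair, speed, solar, fdir, cza, tol, max_iter) {
  L <- .lil()
  n <- length(tk)
  tsfc <- tk
  ea <- .emis_atm(tk, rh)
  prev <- tk
  out <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    a <- which(active)
    tref <- 0.5 * (prev[a] + tk[a])
    h <- .h_sphere(tref, pair[a], speed[a])
    rhs <- 0.5 * (ea[a] * tk[a]^4 + L$emis_sfc * tsfc[a]^4) -
      h / (L$stefanb * L$emis_globe) * (prev[a] - tk[a]) +
      solar[a] / (2 * L$stefanb * L$emis_globe) * (1 - L$alb_globe) *
      (fdir[a] * (1 / (2 * cza[a]) - 1) + 1 + L$alb_sfc)
    tnew <- pmax(rhs, 0)^0.25
    done <- abs(tnew - prev[a]) < tol
    out[a[done]] <- tnew[done]
    prev[a] <- 0.9 * prev[a] + 0.1 * tnew
    active[a[done]] <- FALSE
  }
  out
}

# single damped fixed-point sweep for the natural wet-bulb, kelvin
.twb_solve <- function(tk, rh, pair, speed, solar, fdir, cza, tol, max_iter) {
  L <- .lil()
  n <- length(tk)
  a_exp <- 0.56  # Bedingfield & Drew exponent
  tsfc <- tk
  sza <- acos(pmin(pmax(cza, -1), 1))
  eair <- rh * .esat_lil(tk)
  ea <- .emis_atm(tk, rh)
  prev <- .dewpoint_lil(pmax(eair, 1e-6))
  out <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    a <- which(active)
    tref <- 0.5 * (prev[a] + tk[a])
    h <- .h_cylinder(tref, pair[a], speed[a])
    fatm <- L$stefanb * L$emis_wick *
      (0.5 * (ea[a] * tk[a]^4 + L$emis_sfc * tsfc[a]^4) - prev[a]^4) +
      (1 - L$alb_wick) * solar[a] *
      ((1 - fdir[a]) * (1 + 0.25 * L$diam_wick / L$len_wick) +
         fdir[a] * (tan(sza[a]) / pi + 0.25 * L$diam_wick / L$len_wick) +
         L$alb_sfc)
    ewick <- .esat_lil(prev[a])
    density <- pair[a] * 100 / (L$r_air * tref)
    sc <- .viscosity(tref) / (density * .diffusivity(tref, pair[a]))
    tnew <- tk[a] -
      .evap_heat(tref) / L$ratio * (ewick - eair[a]) / (pair[a] - ewick) *
      (L$Pr / sc)^a_exp +
      fatm / h
    done <- abs(tnew - prev[a]) < tol
    out[a[done]] <- tnew[done]
    prev[a] <- 0.9 * prev[a] + 0.1 * tnew
    active[a[done]] <- FALSE
  }
  out
}

#' Wet-bulb globe temperature (Liljegren energy-balance model)
#'
#' Solves the natural wet-bulb temperature `Tw` (wick energy balance:
#' convection + radiation = evaporation) and black-globe temperature `Tg`
#' (solar and longwave absorption = convection + emission) by the original
#' damped fixed-point iteration, then combines
#' `WBGT = 0.7 Tw + 0.2 Tg + 0.1 Ta`.
#'
#' Inputs are Celsius/percent/Pa; conversion to the model's internal
#' kelvin/hPa/fraction units happens here. The supplied 10 m wind is reduced
#' to the 2 m sensor level with [wind_speed_2m()]. Relative humidity is
#' clipped to 0-100 %. Nighttime is represented by a small negative
#' `cos_zenith` sentinel; the direct-beam fraction is forced to zero when
#' `GHI <= 1` W/m2 or the sun is below ~89.5 degrees zenith, and the zenith
#' cosine is floored at 0.00873 inside the solar term as in the published
#' code. Cell-hours that fail to converge within the iteration cap are
#' returned missing, with a warning giving the count.
#'
#' @param ta_c Air temperature, deg C.
#' @param rh Relative humidity, percent.
#' @param ps_pa Surface pressure, Pa.
#' @param u10 10 m wind speed, m/s.
#' @param ghi Global horizontal irradiance, W/m2.
#' @param f_dir Direct-beam fraction of GHI (see [direct_beam_fraction()]).
#' @param cos_zenith Cosine of the solar zenith angle (sentinel at night).
#' @param tol Convergence tolerance, K (default 0.02).
#' @param max_iter Iteration cap (default 50).
#' @return A list with numeric vectors `tw`, `tg`, `wbgt` (deg C).
#' @export
wbgt_liljegren <- function(ta_c, rh, ps_pa, u10, ghi, f_dir, cos_zenith,
                           tol = .const$liljegren$convergence,
                           max_iter = .const$liljegren$max_iter) {
  n <- max(length(ta_c), length(rh), length(ps_pa), length(u10),
           length(ghi), length(f_dir), length(cos_zenith))
  ta_c <- rep_len(ta_c, n); rh <- rep_len(rh, n); ps_pa <- rep_len(ps_pa, n)
  u10 <- rep_len(u10, n); ghi <- rep_len(ghi, n)
  f_dir <- rep_len(f_dir, n); cos_zenith <- rep_len(cos_zenith, n)

  tk <- ta_c + .const$t0_k
  rhf <- pmin(pmax(rh, 0), 100) / 100
  pair <- ps_pa / 100
  u2 <- wind_speed_2m(u10, ghi, cos_zenith)
  fdir <- ifelse(ghi <= 1 | cos_zenith <= 0.00873, 0, f_dir)
  cza <- pmax(cos_zenith, 0.00873)

  ok <- is.finite(tk) & is.finite(rhf) & is.finite(pair) & is.finite(u2) &
    is.finite(ghi) & is.finite(fdir) & is.finite(cza)
  tw <- tg <- rep(NA_real_, n)
  if (any(ok)) {
    tg[ok] <- .tglobe_solve(tk[ok], rhf[ok], pair[ok], u2[ok], ghi[ok],
                            fdir[ok], cza[ok], tol, max_iter) - .const$t0_k
    tw[ok] <- .twb_solve(tk[ok], rhf[ok], pair[ok], u2[ok], ghi[ok],
                         fdir[ok], cza[ok], tol, max_iter) - .const$t0_k
    nonconv <- sum(ok & (is.na(tw) | is.na(tg)))
    if (nonconv > 0)
      warning(sprintf("%d cell-hour(s) did not converge within %d iterations",
                      nonconv, max_iter))
  }
  list(tw = tw, tg = tg, wbgt = 0.7 * tw + 0.2 * tg + 0.1 * ta_c)
}
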