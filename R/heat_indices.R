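# Heat Index, direct-beam fraction, mean radiant temperature, and the UTCI
# polynomial with its validity mask. The wet-bulb/globe model lives in
# wbgt_liljegren.R.

#' Heat Index (NWS Rothfusz algorithm)
#'
#' The full U.S. National Weather Service procedure: temperature is
#' converted to Fahrenheit internally; the simple Steadman-average formula
#' `0.5 (T + 61 + 1.2 (T - 68) + 0.094 RH)` applies in the cool regime, and
#' where it reaches 80 F the Rothfusz regression replaces it, with the
#' low-humidity (RH < 13 %, 80-112 F) and high-humidity (RH > 85 %, 80-87 F)
#' adjustment terms. Every temperature/humidity combination returns a
#' number; no output masking is applied.
#'
#' @param ta_c Air temperature, deg C.
#' @param rh Relative humidity, percent (0-100).
#' @return Heat Index, deg C.
#' @export
#' @examples
#' heat_index(35, 70)
heat_index <- function(ta_c, rh) {
  t <- ta_c * 9 / 5 + 32
  hi <- 0.5 * (t + 61 + (t - 68) * 1.2 + rh * 0.094)
  hot <- !is.na(hi) & hi >= 80
  if (any(hot)) {
    tf <- t[hot]; rhh <- rh[hot]
    h <- -42.379 + 2.04901523 * tf + 10.14333127 * rhh -
      0.22475541 * tf * rhh - 6.83783e-3 * tf^2 - 5.481717e-2 * rhh^2 +
      1.22874e-3 * tf^2 * rhh + 8.5282e-4 * tf * rhh^2 -
      1.99e-6 * tf^2 * rhh^2
    lowrh <- rhh < 13 & tf >= 80 & tf <= 112
    h[lowrh] <- h[lowrh] - ((13 - rhh[lowrh]) / 4) *
      sqrt((17 - abs(tf[lowrh] - 95)) / 17)
    highrh <- rhh > 85 & tf >= 80 & tf <= 87
    h[highrh] <- h[highrh] + ((rhh[highrh] - 85) / 10) * ((87 - tf[highrh]) / 5)
    hi[hot] <- h
  }
  (hi - 32) * 5 / 9
}

#' Direct-beam fraction of global irradiance
#'
#' `f_dir = 1 - DHI/GHI`, clamped to `[0, 1]`, and forced to zero whenever
#' `GHI <= 1` W/m2 (night and twilight, where the ratio is numerically
#' meaningless).
#'
#' @param ghi Global horizontal irradiance, W/m2.
#' @param dhi Diffuse horizontal irradiance, W/m2.
#' @return Unitless fraction in `[0, 1]`.
#' @export
direct_beam_fraction <- function(ghi, dhi) {
  f <- 1 - dhi / ghi
  f[!is.finite(f)] <- 0
  f[ghi <= 1] <- 0
  pmin(pmax(f, 0), 1)
}

#' Mean radiant temperature from shortwave and longwave fluxes
#'
#' Fourth-root radiant flux balance for the reference person: half-sky and
#' half-ground longwave terms plus absorbed shortwave (diffuse, reflected,
#' and the direct beam projected with the Fanger area factor), using
#' absorption 0.7 and emissivity 0.97:
#' \deqn{T_{mrt}^4 = \frac{1}{\sigma}\left[0.5 L^{\downarrow} + 0.5 L^{up} +
#'   \frac{0.7}{0.97}(0.5 SW_{dif} + 0.5 SW_{ref} + f_p DNI)\right]}
#' Surface-emitted longwave is recovered from the supplied pair as
#' `Lup = Ldown - Lnet` (net = down - up convention). The cosine of the
#' solar zenith is truncated at zero and negative shortwave fluxes are set
#' to zero before use.
#'
#' @param ghi Downwelling shortwave (global horizontal) irradiance, W/m2.
#' @param net_shortwave Net shortwave `(1 - albedo) GHI`, W/m2.
#' @param dni Direct normal irradiance, W/m2.
#' @param dni_horizontal Its horizontal projection `DNI cos(theta_z)`, W/m2.
#' @param ldown Downwelling longwave, W/m2.
#' @param lnet Net longwave (down minus up), W/m2.
#' @param cos_zenith Cosine of the solar zenith angle.
#' @return Mean radiant temperature, deg C.
#' @export
mean_radiant_temperature <- function(ghi, net_shortwave, dni, dni_horizontal,
                                     ldown, lnet, cos_zenith) {
  m <- .const$mrt
  cz <- pmin(pmax(cos_zenith, 0), 1)
  ghi <- pmax(ghi, 0); nsw <- pmax(net_shortwave, 0)
  dni <- pmax(dni, 0); dnih <- pmax(dni_horizontal, 0)
  sw_dif <- pmax(ghi - dnih, 0)       # diffuse shortwave
  sw_ref <- pmax(ghi - nsw, 0)        # ground-reflected shortwave
  lup <- ldown - lnet                 # surface-emitted longwave
  gamma <- asin(cz) * 180 / pi        # solar elevation, degrees
  fp <- m$fp$a * cos((gamma * m$fp$b - gamma^2 / m$fp$c) * pi / 180)
  mrt4 <- (m$view_factor * ldown + m$view_factor * lup +
             (m$absorption_sw / m$emissivity) *
             (m$view_factor * sw_dif + m$view_factor * sw_ref + fp * dni)) /
    .const$sigma
  pmax(mrt4, 0)^0.25 - .const$t0_k
}

#' Raw UTCI polynomial approximation (no validity masking)
#'
#' Evaluates the published sixth-order polynomial in air temperature, wind
#' speed, the radiant excess `Tmrt - Ta`, and vapor pressure (converted to
#' kPa internally), returning the UTCI equivalent temperature as an offset
#' from `Ta`. All 210 coefficients are in `R/utci_coefficients.R`.
#'
#' @param ta_c Air temperature, deg C.
#' @param va 10 m wind speed, m/s.
#' @param tmrt_c Mean radiant temperature, deg C.
#' @param e_hpa Vapor pressure, hPa.
#' @return UTCI, deg C.
#' @export
utci_polynomial <- function(ta_c, va, tmrt_c, e_hpa) {
  dt <- tmrt_c - ta_c
  pa <- e_hpa / 10  # kPa
  # precompute powers 0..6 of each regressor once
  pw <- function(x) {
    out <- vector("list", 7L); out[[1]] <- rep(1, length(x))
    for (p in 2:7) out[[p]] <- out[[p - 1]] * x
    out
  }
  n <- max(length(ta_c), length(va), length(dt), length(pa))
  tap <- pw(rep_len(ta_c, n)); vap <- pw(rep_len(va, n))
  dtp <- pw(rep_len(dt, n)); pap <- pw(rep_len(pa, n))
  acc <- numeric(n)
  for (t in seq_len(nrow(.utci_exponents))) {
    ex <- .utci_exponents[t, ]
    acc <- acc + .utci_coefs[t] *
      tap[[ex[1] + 1L]] * vap[[ex[2] + 1L]] * dtp[[ex[3] + 1L]] * pap[[ex[4] + 1L]]
  }
  rep_len(ta_c, n) + acc
}

#' UTCI with operational validity limits
#'
#' Evaluates [utci_polynomial()] and masks (returns `NA`) every cell-hour
#' outside the validated domain: `-50 <= Ta <= 50` deg C,
#' `-30 <= Tmrt - Ta <= 70` deg C, vapor pressure `e < 50` hPa, relative
#' humidity above 5 % (evaluated on the clipped RH implied by `Ta` and `e`),
#' wind speed within `0.5 <= U10 <= 17` m/s, or any non-finite input.
#'
#' @inheritParams utci_polynomial
#' @return UTCI, deg C, `NA` where any validity limit fails.
#' @export
utci <- function(ta_c, va, tmrt_c, e_hpa) {
  n <- max(length(ta_c), length(va), length(tmrt_c), length(e_hpa))
  ta_c <- rep_len(ta_c, n); va <- rep_len(va, n)
  tmrt_c <- rep_len(tmrt_c, n); e_hpa <- rep_len(e_hpa, n)
  bad <- !is.finite(ta_c) | !is.finite(va) | !is.finite(tmrt_c) |
    !is.finite(e_hpa)
  ok <- !bad
  dt <- tmrt_c - ta_c
  rh <- relative_humidity(ifelse(ok, ta_c, 0), ifelse(ok, e_hpa, 1))
  invalid <- bad |
    ta_c < -50 | ta_c > 50 |
    dt < -30 | dt > 70 |
    e_hpa >= 50 |
    rh <= 5 |
    va < 0.5 | va > 17
  out <- rep(NA_real_, n)
  if (any(!invalid))
    out[!invalid] <- utci_polynomial(ta_c[!invalid], va[!invalid],
                                     tmrt_c[!invalid], e_hpa[!invalid])
  out
}
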