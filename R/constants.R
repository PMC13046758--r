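# Physical constants shared across the pipeline. All values are pinned to the
# published sources of the respective models and are never mutated at run time.

.const <- list(
  g       = 9.80665,       # gravitational acceleration, m s-2
  Rd      = 287.05,        # specific gas constant of dry air, J kg-1 K-1
  sigma   = 5.67e-8,       # Stefan-Boltzmann constant used by the MRT balance
  t0_k    = 273.15,

  # Buck (1996) over-water saturation vapor pressure, hPa from deg C:
  # es(T) = b0 * exp((b1 - T/b2) * T / (b3 + T))
  buck = list(variant = "Buck 1996 over water",
              b0 = 6.1121, b1 = 18.678, b2 = 234.5, b3 = 257.14),

  # Liljegren et al. (2008) wet-bulb/globe model constants (from the
  # published C implementation; its internal Stefan-Boltzmann value and
  # Buck-1981 saturation curve with the 1.004 enhancement factor are kept
  # deliberately distinct from the pipeline-wide values above).
  liljegren = list(
    stefanb = 5.6696e-8,
    cp = 1003.5, m_air = 28.97, m_h2o = 18.015, r_gas = 8314.34,
    emis_globe = 0.95, alb_globe = 0.05, diam_globe = 0.0508,
    emis_wick = 0.95, alb_wick = 0.4, diam_wick = 0.007, len_wick = 0.0254,
    emis_sfc = 0.999, alb_sfc = 0.45,
    convergence = 0.02, max_iter = 50L,
    min_speed = 0.13, ref_height = 2,
    rural_exponents = c(0.07, 0.07, 0.10, 0.15, 0.35, 0.55)
  ),

  # Mean-radiant-temperature flux balance (operational UTCI literature):
  # half-sky/half-ground view factors, shortwave absorption and longwave
  # emissivity of the reference person, Fanger projected-area factor.
  mrt = list(absorption_sw = 0.7, emissivity = 0.97, view_factor = 0.5,
             fp = list(a = 0.308, b = 0.998, c = 50000)),

  # nighttime sentinel for the cosine of the solar zenith angle
  night_cos_zenith = -1e-4
)

.const$liljegren$r_air <- .const$liljegren$r_gas / .const$liljegren$m_air
.const$liljegren$Pr <-
  .const$liljegren$cp / (.const$liljegren$cp + 1.25 * .const$liljegren$r_air)
.const$liljegren$ratio <-
  .const$liljegren$cp * .const$liljegren$m_air / .const$liljegren$m_h2o

#' Physical constants used by the heat-stress pipeline
#'
#' Returns the pinned constants table: thermodynamic constants (`g`, `Rd`,
#' `sigma`), the Buck saturation-vapor-pressure variant used throughout the
#' pipeline, the Liljegren wet-bulb/globe model constants (sensor geometry,
#' emissivities, iteration controls, wind-profile exponents), the
#' mean-radiant-temperature coefficients, and the nighttime cosine-zenith
#' sentinel.
#'
#' @return A named list; see source for the full structure.
#' @export
#' @examples
#' heattract_constants()$Rd
heattract_constants <- function() .const
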