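# Frozen expected values below were computed with the independent reference
# implementations in data-raw/oracle_reference.py.

test_that("heat index matches the reference algorithm in both regimes", {
  expect_equal(heat_index(15, 50), 13.861111111111112, tolerance = 1e-10)
  expect_equal(heat_index(35, 70), 50.34057805555565, tolerance = 1e-3)
  # every combination returns a number: no regime masking
  grid <- expand.grid(ta = seq(-20, 50, by = 5), rh = seq(0, 100, by = 10))
  expect_true(all(is.finite(heat_index(grid$ta, grid$rh))))
})

test_that("heat index increases with humidity in the hot regime", {
  expect_lt(heat_index(32, 0), heat_index(32, 100))
  hi <- heat_index(rep(38, 11), seq(0, 100, by = 10))
  expect_true(all(diff(hi) > 0))
})

test_that("direct-beam fraction clamps and zeroes at negligible irradiance", {
  expect_equal(direct_beam_fraction(0.5, 0), 0)   # GHI <= 1 rule
  expect_equal(direct_beam_fraction(800, 200), 0.75)
  expect_equal(direct_beam_fraction(300, 400), 0) # DHI > GHI clamps
  expect_equal(direct_beam_fraction(0, 0), 0)
})

test_that("mean radiant temperature reproduces isotropic equilibria", {
  sig <- heattract_constants()$sigma
  ld <- sig * 300^4
  # all shortwave zero, Lnet 0: enclosure at 300 K
  expect_equal(mean_radiant_temperature(0, 0, 0, 0, ld, 0, 0) + 273.15, 300,
               tolerance = 1e-9)
  # doubling the longwave load scales Tmrt by 2^(1/4) in kelvin
  t2 <- mean_radiant_temperature(0, 0, 0, 0, 2 * ld, 0, 0) + 273.15
  expect_equal(t2, 300 * 2^0.25, tolerance = 1e-9)
  # frozen daytime reference case (GHI 700, DNI 600, cos z 0.7, albedo 0.2)
  expect_equal(
    mean_radiant_temperature(700, 560, 600, 420, 380, -60, 0.7),
    54.94119304309464, tolerance = 1e-6)
})

test_that("UTCI polynomial reproduces the reference-condition value", {
  e25 <- 0.5 * svp_buck(25)
  expect_equal(utci_polynomial(25, 1, 25, e25), 24.610723163330427,
               tolerance = 1e-9)
})

test_that("UTCI missingness is exactly the union of the validity limits", {
  base <- list(ta = 25, va = 1, tmrt = 25, e = 12)
  val <- function(ta = base$ta, va = base$va, tmrt = base$tmrt, e = base$e)
    utci(ta, va, tmrt, e)
  expect_false(is.na(val()))
  # wind limits 0.5 and 17 m/s inclusive
  expect_true(is.na(val(va = 0.49)))
  expect_false(is.na(val(va = 0.5)))
  expect_false(is.na(val(va = 17)))
  expect_true(is.na(val(va = 17.01)))
  # vapor pressure must stay below 50 hPa
  expect_false(is.na(val(ta = 45, e = 49.9)))
  expect_true(is.na(val(ta = 45, e = 50)))
  # air temperature window
  expect_true(is.na(val(ta = -50.5, tmrt = -50.5, e = 0.2)))
  expect_true(is.na(val(ta = 50.5, tmrt = 50.5)))
  expect_false(is.na(val(ta = 49.9, tmrt = 49.9, e = 30)))
  # radiant excess window
  expect_false(is.na(val(tmrt = 25 + 70)))
  expect_true(is.na(val(tmrt = 25 + 70.1)))
  expect_false(is.na(val(tmrt = 25 - 30)))
  expect_true(is.na(val(tmrt = 25 - 30.1)))
  # dry-air limit: RH must exceed 5 %
  e5 <- 0.04 * svp_buck(25)
  expect_true(is.na(val(e = e5)))
  # non-finite input propagates
  expect_true(is.na(val(ta = NA)))
  expect_true(is.na(val(e = Inf)))
})

test_that("wet-bulb/globe combination uses the published weights", {
  # frozen reference: Ta 30 C, RH 50 %, sea level, 2 m/s, sunny
  out <- wbgt_liljegren(30, 50, 101325, 2, 800, 0.75, 0.8)
  expect_equal(out$tw, 24.173860059090316, tolerance = 0.05)
  expect_equal(out$tg, 45.09145354799176, tolerance = 0.05)
  expect_equal(out$wbgt, 0.7 * out$tw + 0.2 * out$tg + 0.1 * 30)
})

test_that("wet bulb and globe respond physically to their drivers", {
  day <- wbgt_liljegren(30, 50, 101325, 2, 800, 0.75, 0.8)
  night <- wbgt_liljegren(30, 50, 101325, 2, 0, 0, -1e-4)
  # the globe sheds its solar load at night
  expect_lt(night$tg, day$tg)
  # night-time globe sits near the radiatively weighted air temperature
  expect_lt(abs(night$tg - 30), 5)
  # wetter air warms the wet bulb
  humid <- wbgt_liljegren(30, 90, 101325, 2, 800, 0.75, 0.8)
  expect_gt(humid$tw, day$tw)
  # WBGT lies within the convex hull of its components
  for (o in list(day, night, humid)) {
    expect_gte(o$wbgt, min(o$tw, o$tg, 30) - 1e-9)
    expect_lte(o$wbgt, max(o$tw, o$tg, 30) + 1e-9)
  }
})

test_that("the 2 m wind profile follows the stability classes", {
  # strong sun, light wind: unstable, shallow profile
  expect_equal(wind_speed_2m(1, 950, 0.9), 1 * (2 / 10)^0.07)
  # night: stable, steep profile
  expect_equal(wind_speed_2m(1, 0, -1e-4), 1 * (2 / 10)^0.55)
  # floor at the model minimum speed
  expect_equal(wind_speed_2m(0.01, 0, -1e-4), 0.13)
})
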