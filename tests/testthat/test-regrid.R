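test_that("accumulated series convert to mean hourly fluxes", {
  expect_equal(accumulated_to_flux(c(3600, 7200, 10800)), c(1, 1, 1))
  expect_equal(accumulated_to_flux(c(7200, 7200, 7200))[-1], c(0, 0))
})

test_that("accumulation resets restart the differencing", {
  # hand-built two-day accumulation of a constant 2 W/m2 flux, reset at the
  # start of the second day
  flux_true <- rep(2, 8)
  acc <- c(cumsum(rep(2 * 3600, 4)), cumsum(rep(2 * 3600, 4)))
  reset <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(accumulated_to_flux(acc, reset), flux_true)
  # an undeclared reset produces a negative difference, clipped with warning
  expect_warning(out <- accumulated_to_flux(acc), "negative")
  expect_equal(out[5], 0)
})

test_that("malformed accumulation input is rejected", {
  expect_error(accumulated_to_flux(1:4, reset = c(TRUE, FALSE)), "length")
})

test_that("half-hour pairs average to hourly values with missing fallback", {
  expect_equal(halfhour_to_hour(100, 200), 150)
  expect_equal(halfhour_to_hour(7, 7), 7)
  expect_equal(halfhour_to_hour(c(NA, 5, NA), c(3, NA, NA)), c(3, 5, NA))
})

test_that("zenith aggregation averages in cosine space", {
  expect_equal(aggregate_zenith(60, 60), 60)
  expect_equal(aggregate_zenith(0, 90), 60)
  expect_error(aggregate_zenith(-1, 50), "0, 180")
  set.seed(5)
  t1 <- runif(50, 0, 180); t2 <- runif(50, 0, 180)
  z <- aggregate_zenith(t1, t2)
  expect_true(all(z >= pmin(t1, t2) - 1e-9 & z <= pmax(t1, t2) + 1e-9))
})

test_that("IDW returns the source value exactly at coincident points", {
  sxy <- cbind(c(0, 100, 0, 100), c(0, 0, 100, 100))
  v <- c(1, 2, 3, 4)
  out <- idw_interpolate(sxy, v, rbind(c(0, 0), c(50, 50)), cutoff = 1000)
  expect_identical(out[1], 1)
  expect_equal(out[2], 2.5)  # four equidistant neighbours: plain mean
})

test_that("IDW respects the cutoff and degenerates to nearest-neighbour", {
  sxy <- cbind(c(0, 5000), c(0, 0))
  v <- c(10, 99)
  # second source beyond cutoff never contributes
  out <- idw_interpolate(sxy, v, rbind(c(100, 0)), cutoff = 1000)
  expect_equal(out, 10)
  # no source within cutoff: missing, not an error
  out2 <- idw_interpolate(sxy, v, rbind(c(2500, 0)), cutoff = 1000)
  expect_true(is.na(out2))
  # one NA neighbour: weight renormalizes onto the valid one
  out3 <- idw_interpolate(cbind(c(0, 10), c(0, 0)), c(NA, 7),
                          rbind(c(2, 0)), cutoff = 1000)
  expect_equal(out3, 7)
})

test_that("IDW matches the exhaustive oracle on random layouts", {
  set.seed(99)
  for (rep in 1:10) {
    ns <- sample(5:30, 1)
    sxy <- cbind(runif(ns, 0, 10000), runif(ns, 0, 10000))
    v <- rnorm(ns)
    v[sample(ns, max(1, ns %/% 5))] <- NA
    txy <- cbind(runif(40, 0, 10000), runif(40, 0, 10000))
    cutoff <- runif(1, 1500, 6000)
    got <- idw_interpolate(sxy, v, txy, cutoff)
    want <- idw_brute(sxy, v, txy, cutoff)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("IDW output is convex in the contributing source values", {
  set.seed(13)
  sxy <- cbind(runif(20, 0, 1000), runif(20, 0, 1000))
  v <- rnorm(20)
  txy <- cbind(runif(50, 0, 1000), runif(50, 0, 1000))
  out <- idw_interpolate(sxy, v, txy, cutoff = 2000)
  expect_true(all(out >= min(v) - 1e-12 & out <= max(v) + 1e-12))
})

test_that("IDW handles matrix-valued (time series) sources", {
  sxy <- cbind(c(0, 100), c(0, 0))
  vals <- rbind(c(1, 10, NA), c(3, 30, 5))
  out <- idw_interpolate(sxy, vals, rbind(c(50, 0), c(0, 0)), cutoff = 500)
  expect_equal(dim(out), c(2L, 3L))
  expect_equal(out[1, 1:2], c(2, 20))   # midpoint: equal weights
  expect_equal(out[1, 3], 5)            # NA neighbour ignored
  expect_equal(out[2, 1:2], c(1, 10))   # coincident pass-through
  expect_equal(out[2, 3], 5)            # coincident NA falls back
})
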