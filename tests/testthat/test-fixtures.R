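test_that("generators are bit-reproducible under a fixed seed", {
  s <- truth_scenario(seed = 5L, days = 1L)
  a <- make_truth_fields(s); b <- make_truth_fields(s)
  expect_identical(a$ta, b$ta)
  expect_identical(a$td, b$td)
  ta1 <- make_tracts_and_population(a$grid, 6L, seed = 5L, 1000)
  ta2 <- make_tracts_and_population(a$grid, 6L, seed = 5L, 1000)
  expect_identical(ta1$pop_fine, ta2$pop_fine)
  st1 <- make_stations(a, 5L, 1, seed = 5L)
  st2 <- make_stations(a, 5L, 1, seed = 5L)
  expect_identical(st1, st2)
})

test_that("zero diurnal amplitude produces flat days", {
  s <- truth_scenario(days = 1L, diurnal_amplitude = 0)
  tr <- make_truth_fields(s)
  expect_equal(apply(tr$ta, 1, function(x) diff(range(x))), rep(0, nrow(tr$ta)))
  # the flat-day rule then reconstructs the constraint midpoint
  co <- degrade_to_coarse_hourly(tr)
  f <- diurnal_profile(co$ta[, 1:24])
  expect_true(all(f == 0.5))
})

test_that("daily degradation equals a direct scan of the truth", {
  s <- truth_scenario(days = 2L, nx = 6L, ny = 6L)
  tr <- make_truth_fields(s)
  d <- degrade_to_daily(tr)
  expect_equal(nrow(d), 36L * 2L)
  for (cell in c(1L, 17L, 36L)) {
    expect_equal(d[cell_id == cell & label_date == min(label_date), ta_min],
                 min(tr$ta[cell, 1:24]))
    expect_equal(d[cell_id == cell & label_date == max(label_date), ta_max],
                 max(tr$ta[cell, 25:48]))
    expect_equal(d[cell_id == cell & label_date == min(label_date), td_mean],
                 mean(tr$td[cell, 1:24]))
  }
})

test_that("coarse degradation is the block mean and accumulations integrate", {
  s <- truth_scenario(days = 1L, nx = 4L, ny = 4L, coarse_nx = 1L,
                      coarse_ny = 1L)
  tr <- make_truth_fields(s)
  co <- degrade_to_coarse_hourly(tr)
  # single coarse cell: the domain mean series
  expect_equal(co$ta[1, ], colMeans(tr$ta))
  # accumulations recover the block-mean flux through the conversion step
  flux <- accumulated_to_flux(co$ldown_acc[1, ], reset = co$reset)
  expect_equal(flux, colMeans(tr$ldown), tolerance = 1e-10)
  # a reset boundary exists at the accumulation-day start (00 UTC)
  h0 <- which(format(co$hours, "%H", tz = "UTC") == "00")
  expect_true(all(co$reset[h0]))
  expect_lt(co$ldown_acc[1, h0[1]], co$ldown_acc[1, h0[1] - 1])
})

test_that("solar product is physically consistent", {
  s <- truth_scenario(days = 1L)
  tr <- make_truth_fields(s)
  so <- make_halfhourly_solar(tr)
  night <- so$zenith >= 90
  expect_true(all(so$ghi[night] == 0))
  expect_true(all(so$dni[night] == 0))
  expect_true(all(so$ghi >= so$dhi))
  expect_true(all(so$ghi >= 0 & so$dhi >= 0 & so$dni >= 0))
  # irradiance peaks where the zenith is smallest
  expect_equal(which.max(so$ghi[1, ]), which.min(so$zenith[1, ]))
})

test_that("tracts tessellate the grid and population is conserved", {
  s <- truth_scenario(days = 1L)
  tr <- make_truth_fields(s)
  tp <- make_tracts_and_population(tr$grid, 12L, seed = 1L,
                                   total_population = 54321)
  # every centroid covered exactly once
  hits <- integer(nrow(tr$grid))
  for (t in tp$tracts) {
    inside <- heattract:::.point_in_polygon(tr$grid$lon, tr$grid$lat, t$rings)
    hits <- hits + inside
  }
  expect_true(all(hits == 1L))
  expect_equal(sum(tp$pop_fine$count), 54321)
})

test_that("one-tract aggregation equals the domain weighted mean", {
  s <- truth_scenario(days = 1L, nx = 5L, ny = 5L)
  tr <- make_truth_fields(s)
  tp <- make_tracts_and_population(tr$grid, 1L, seed = 2L, 1000)
  pop <- resample_population(tp$pop_fine, tr$grid)
  lk <- build_lookup(tr$grid, tp$tracts, population = pop)
  v <- tr$ta[, 13]
  out <- aggregate_to_tracts(
    data.table::data.table(cell_id = tr$grid$cell_id, x = v), lk, "area")
  expect_equal(out$x, weighted.mean(v, cos(tr$grid$lat * pi / 180)))
})

test_that("noise-free stations reproduce the truth exactly", {
  s <- truth_scenario(days = 1L, n_stations = 5L)
  tr <- make_truth_fields(s)
  st <- make_stations(tr, 5L, noise_sd = 0, seed = 9L)
  host <- attr(st, "host_cell")
  suppressMessages(
    m <- match_stations(unique(st[, .(station_id, lat, lon)]), tr$grid, 800))
  expect_equal(setNames(m$cell_id, m$station_id), host[m$station_id])
  for (sid in names(host)) {
    obs <- st[station_id == sid][order(timestamp)]$value
    expect_equal(obs, tr$ta[host[[sid]], ])
  }
})
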