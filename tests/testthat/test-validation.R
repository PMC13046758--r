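test_that("stations match their nearest cell within the distance threshold", {
  g <- reference_grid(lat = c(40, 40.05), lon = c(-95, -95))  # ~5.6 km apart
  st <- data.frame(station_id = c("at_cell", "near", "far"),
                   lat = c(40, 40.0005, 40.02), lon = c(-95, -95, -95))
  suppressMessages(m <- match_stations(st, g, max_distance = 800))
  expect_setequal(m$station_id, c("at_cell", "near"))
  expect_lt(m[station_id == "at_cell", distance], 1e-6)
  expect_equal(m[station_id == "near", cell_id], 1L)
  # ~1 km away station excluded at 800 m, included at 9 km
  st2 <- data.frame(station_id = "s", lat = 40.009, lon = -95)
  suppressMessages(expect_equal(nrow(match_stations(st2, g, 800)), 0L))
  expect_equal(nrow(match_stations(st2, g, 9000)), 1L)
})

test_that("station matching equals exhaustive search plus filter", {
  set.seed(17)
  g <- reference_grid(lat = runif(30, 40, 40.2), lon = runif(30, -95, -94.8),
                      spacing_tol = Inf)
  st <- data.frame(station_id = sprintf("s%02d", 1:15),
                   lat = runif(15, 40, 40.2), lon = runif(15, -95, -94.8))
  suppressMessages(m <- match_stations(st, g, max_distance = 5000))
  proj <- list(lat0 = 40.1, lon0 = -94.9, par1 = 40.03, par2 = 40.17)
  # brute force with an explicit projection for reference distances
  gxy <- project_planar(g$lat, g$lon)
  for (i in seq_len(15)) {
    xy <- project_planar(c(g$lat, st$lat[i]), c(g$lon, st$lon[i]))
    d <- sqrt((xy[1:30, 1] - xy[31, 1])^2 + (xy[1:30, 2] - xy[31, 2])^2)
    if (min(d) <= 5000 * 1.001) {
      expect_equal(m[station_id == st$station_id[i], cell_id],
                   g$cell_id[which.min(d)])
    }
  }
})

test_that("error metrics follow the model-minus-observation convention", {
  obs <- c(1, 2, 3, 4)
  expect_equal(error_metrics(obs, obs),
               data.table::data.table(n = 4L, bias = 0, rmse = 0,
                                      pearson_r = 1))
  m <- error_metrics(obs, obs + 1)
  expect_equal(m$bias, 1)
  expect_equal(m$rmse, 1)
  expect_equal(m$pearson_r, 1)
  # random pairs against the direct formulas
  set.seed(23)
  o <- rnorm(200); p <- o + rnorm(200, 0.3, 0.7)
  m2 <- error_metrics(o, p)
  expect_equal(m2$bias, mean(p - o))
  expect_equal(m2$rmse, sqrt(mean((p - o)^2)))
  expect_equal(m2$pearson_r, cor(o, p))
  expect_gte(m2$rmse, abs(m2$bias))
  # missing pairs are dropped; < 2 pairs leaves r undefined
  m3 <- error_metrics(c(1, NA, 3), c(1.5, 2, NA))
  expect_equal(m3$n, 1L)
  expect_true(is.na(m3$pearson_r))
})

test_that("metrics are invariant under pair reordering", {
  set.seed(29)
  o <- rnorm(50); p <- o + rnorm(50)
  idx <- sample(50)
  expect_equal(error_metrics(o, p), error_metrics(o[idx], p[idx]))
})

test_that("station-hour-weighted pooling combines windows correctly", {
  w1 <- error_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(pool_windows(w1, weights = 3), w1, ignore_attr = TRUE)
  # two equal-weight windows with MSE 1 and 9 pool to rmse sqrt(5)
  s <- data.table::data.table(bias = c(0, 0), rmse = c(1, 3))
  expect_equal(pool_windows(s, c(5, 5))$rmse, sqrt(5))
  expect_error(pool_windows(s, c(0, 0)), "weights")
})

test_that("pooling with pair-count weights equals the unpooled computation", {
  set.seed(37)
  wins <- lapply(1:6, function(i) {
    n <- sample(10:60, 1)
    o <- rnorm(n, 20, 3); p <- o + rnorm(n, 0.2, 1.1)
    list(o = o, p = p, m = error_metrics(o, p))
  })
  summaries <- data.table::rbindlist(lapply(wins, `[[`, "m"))
  pooled <- pool_windows(summaries, weights = summaries$n)
  all_o <- unlist(lapply(wins, `[[`, "o"))
  all_p <- unlist(lapply(wins, `[[`, "p"))
  direct <- error_metrics(all_o, all_p)
  expect_equal(pooled$bias, direct$bias, tolerance = 1e-12)
  expect_equal(pooled$rmse, direct$rmse, tolerance = 1e-12)
})
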