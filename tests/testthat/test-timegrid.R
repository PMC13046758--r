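test_that("day window runs from 12:00 UTC the day before to 11:00 UTC", {
  w <- prism_day_window("2010-07-15")
  expect_length(w$hours, 24L)
  expect_identical(format(w$hours[1], "%Y-%m-%d %H:%M", tz = "UTC"),
                   "2010-07-14 12:00")
  expect_identical(format(w$hours[24], "%Y-%m-%d %H:%M", tz = "UTC"),
                   "2010-07-15 11:00")
  expect_true(all(diff(as.numeric(w$hours)) == 3600))
})

test_that("consecutive windows tile time without gap or overlap", {
  w1 <- prism_day_window("2010-07-15")
  w2 <- prism_day_window("2010-07-16")
  expect_equal(as.numeric(w2$hours[1] - w1$hours[24]), 1,
               ignore_attr = TRUE)  # exactly one hour later
  all_hours <- prism_day_hours("2010-07-15", 10L)
  expect_length(all_hours, 240L)
  expect_true(all(diff(as.numeric(all_hours)) == 3600))
  expect_identical(anyDuplicated(all_hours), 0L)
})

test_that("window rejects invalid dates", {
  expect_error(prism_day_window("not-a-date"))
})

test_that("reference grid validates coordinates, ids and spacing", {
  expect_error(reference_grid(c(91, 0), c(0, 0)), "lat")
  expect_error(reference_grid(c(0, 0), c(181, 0)), "lon")
  expect_error(reference_grid(c(0, 1), c(0, 0), cell_id = c(1L, 1L)),
               "unique")
  expect_error(reference_grid(c(0, 1, 2.5), rep(0, 3)), "spaced")
  # irregular land-only subsets (missing rows) are fine
  g <- reference_grid(c(0, 1, 3, 4), rep(0, 4))
  expect_equal(nrow(g), 4L)
})

test_that("nearest source mapping matches identity and degenerate cases", {
  src <- reference_grid(c(40, 40.1, 40.2), c(-95, -95, -95))
  tgt <- reference_grid(40.1, -95)
  m <- nearest_source_map(tgt, src)
  expect_equal(m$source_cell_id, 2L)
  expect_lt(m$distance, 1e-6)

  one <- reference_grid(41, -94)
  m2 <- nearest_source_map(src, one)
  expect_true(all(m2$source_cell_id == 1L))
  expect_error(nearest_source_map(tgt, one[0]), "empty")
})

test_that("nearest source mapping equals exhaustive search on random layouts", {
  set.seed(42)
  for (rep in 1:5) {
    tgt <- reference_grid(40 + runif(20, 0, 0.5), -95 + runif(20, 0, 0.5),
                          spacing_tol = Inf)
    src <- reference_grid(40 + runif(5, 0, 0.5), -95 + runif(5, 0, 0.5),
                          spacing_tol = Inf)
    m <- nearest_source_map(tgt, src)
    proj <- list(lat0 = 40.25, lon0 = -94.75, par1 = 40.1, par2 = 40.4)
    mp <- nearest_source_map(tgt, src, params = proj)
    txy <- project_planar(tgt$lat, tgt$lon, proj)
    sxy <- project_planar(src$lat, src$lon, proj)
    for (i in seq_len(20)) {
      d <- sqrt((sxy[, 1] - txy[i, 1])^2 + (sxy[, 2] - txy[i, 2])^2)
      expect_equal(mp$source_cell_id[i], src$cell_id[which.min(d)])
      expect_equal(mp$distance[i], min(d), tolerance = 1e-9)
    }
  }
})

test_that("nearest-source ties break to the lowest source cell id", {
  # two sources equidistant from the target
  src <- reference_grid(c(40, 40), c(-95.1, -94.9), cell_id = c(7L, 3L),
                        spacing_tol = Inf)
  tgt <- reference_grid(40, -95)
  m <- nearest_source_map(tgt, src)
  expect_equal(m$source_cell_id, 3L)
})
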