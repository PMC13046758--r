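make_rect <- function(geoid, x0, x1, y0, y1) {
  list(geoid = geoid,
       rings = list(cbind(lon = c(x0, x1, x1, x0, x0),
                          lat = c(y0, y0, y1, y1, y0))))
}

test_that("centroids are assigned to the containing polygon", {
  g <- reference_grid(lat = c(0.25, 0.75, 0.25, 0.75),
                      lon = c(0.25, 0.25, 0.75, 0.75), spacing_tol = Inf)
  tr <- list(make_rect("A", 0, 0.5, 0, 1), make_rect("B", 0.5, 1, 0, 1))
  lk <- build_lookup(g, tr)
  expect_equal(lk[geoid == "A", sort(cell_id)], c(1L, 2L))
  expect_equal(lk[geoid == "B", sort(cell_id)], c(3L, 4L))
  expect_equal(lk$area_weight, cos(g$lat[match(lk$cell_id, g$cell_id)] * pi / 180))
})

test_that("boundary centroids get a deterministic single assignment", {
  # cell 1 sits inside A; cell 2 sits exactly on the A/B shared edge
  g <- reference_grid(lat = c(0.5, 0.5), lon = c(0.25, 0.5), spacing_tol = Inf)
  tr <- list(make_rect("B", 0.5, 1, 0, 1), make_rect("A", 0, 0.5, 0, 1))
  lk <- build_lookup(g, tr)
  expect_equal(nrow(lk[cell_id == 2L]), 1L)
  # even-odd ray casting counts a point on a polygon's left edge as inside
  # and on its right edge as outside, so the shared-edge centroid resolves
  # to "B" regardless of the list order
  expect_equal(lk[cell_id == 2L, geoid], "B")
  expect_equal(lk[cell_id == 1L, geoid], "A")
})

test_that("assignment matches a brute-force containment oracle", {
  set.seed(21)
  for (rep in 1:5) {
    g <- reference_grid(lat = runif(40), lon = runif(40), spacing_tol = Inf)
    xb <- sort(c(0, runif(2), 1)); yb <- sort(c(0, runif(1), 1))
    tr <- list(); k <- 0
    for (i in 1:3) for (j in 1:2) {
      k <- k + 1
      tr[[k]] <- make_rect(sprintf("R%02d", k), xb[i], xb[i + 1], yb[j], yb[j + 1])
    }
    lk <- build_lookup(g, tr)
    # rectangles: containment is a coordinate comparison (oracle); tracts
    # with no interior centroid receive exactly one fallback cell
    for (k in seq_along(tr)) {
      r <- tr[[k]]$rings[[1]]
      inside <- which(g$lon > min(r[, 1]) & g$lon < max(r[, 1]) &
                        g$lat > min(r[, 2]) & g$lat < max(r[, 2]))
      members <- lk[geoid == tr[[k]]$geoid, cell_id]
      if (length(inside)) {
        expect_setequal(members, g$cell_id[inside])
      } else {
        expect_length(members, 1L)
      }
    }
  }
})

test_that("tracts without any centroid receive their nearest cell", {
  g <- reference_grid(lat = c(0.1, 0.9), lon = c(0.1, 0.9), spacing_tol = Inf)
  tr <- list(make_rect("A", 0, 1, 0, 1),
             make_rect("Z", 5, 6, 5, 6))   # far away, no centroid inside
  lk <- build_lookup(g, tr)
  expect_equal(lk[geoid == "Z", cell_id], 2L)  # nearest corner cell
})

test_that("invalid geometry is rejected with its identifier", {
  g <- reference_grid(lat = 0.5, lon = 0.5)
  bad <- list(list(geoid = "BAD", rings = list(cbind(c(0, 1), c(0, 1)))))
  expect_error(build_lookup(g, bad), "BAD")
})

test_that("population resampling sums fine counts into coarse cells", {
  g <- reference_grid(lat = c(0, 0), lon = c(0, 1))
  # 64 fine points of 10 persons all nearest to cell 1
  fine <- data.table::data.table(
    lon = runif(64, -0.2, 0.2), lat = runif(64, -0.2, 0.2), count = 10)
  pop <- resample_population(fine, g)
  expect_equal(unname(pop["1"]), 640)
  expect_equal(unname(pop["2"]), 0)
  # empty surface: zeros
  expect_equal(sum(resample_population(fine[0], g)), 0)
  # conservation on random scatter
  set.seed(8)
  fine2 <- data.table::data.table(lon = runif(500, -0.5, 1.5),
                                  lat = runif(500, -0.5, 0.5),
                                  count = rexp(500, 1 / 20))
  expect_equal(sum(resample_population(fine2, g)), sum(fine2$count))
})

test_that("uniform fields pass through both weighting schemes unchanged", {
  g <- reference_grid(lat = runif(30, 40, 40.1), lon = runif(30, -95, -94.9),
                      spacing_tol = Inf)
  tr <- list(make_rect("A", -95.05, -94.95, 39.95, 40.15),
             make_rect("B", -94.95, -94.85, 39.95, 40.15))
  pop <- setNames(runif(30, 0, 100), as.character(g$cell_id))
  lk <- build_lookup(g, tr, population = pop)
  vals <- data.table::data.table(cell_id = g$cell_id, x = 30)
  for (scheme in c("area", "population")) {
    out <- aggregate_to_tracts(vals, lk, scheme)
    expect_equal(out$x, rep(30, nrow(out)))
  }
})

test_that("population weighting matches direct arithmetic and brute force", {
  g <- reference_grid(lat = c(40, 40), lon = c(-95, -94.99))
  tr <- list(make_rect("A", -95.5, -94.5, 39.5, 40.5))
  lk <- build_lookup(g, tr, population = c("1" = 100, "2" = 300))
  out <- aggregate_to_tracts(
    data.table::data.table(cell_id = 1:2, x = c(10, 20)), lk, "population")
  expect_equal(out$x, 17.5)

  set.seed(31)
  g2 <- reference_grid(lat = runif(25, 40, 40.2), lon = runif(25, -95, -94.8),
                       spacing_tol = Inf)
  tr2 <- list(make_rect("A", -95.1, -94.9, 39.9, 40.3),
              make_rect("B", -94.9, -94.7, 39.9, 40.3))
  pop2 <- setNames(rexp(25, 1 / 50), as.character(g2$cell_id))
  lk2 <- build_lookup(g2, tr2, population = pop2)
  v <- rnorm(25, 20, 5)
  out2 <- aggregate_to_tracts(
    data.table::data.table(cell_id = g2$cell_id, x = v), lk2, "population")
  for (gid in out2$geoid) {
    cells <- lk2[geoid == gid, cell_id]
    expect_equal(out2[geoid == gid, x],
                 sum(v[cells] * pop2[as.character(cells)]) /
                   sum(pop2[as.character(cells)]))
  }
  # bounds: tract means live inside the member-cell range
  for (gid in out2$geoid) {
    cells <- lk2[geoid == gid, cell_id]
    expect_gte(out2[geoid == gid, x], min(v[cells]))
    expect_lte(out2[geoid == gid, x], max(v[cells]))
  }
})

test_that("missing member values are excluded with weight renormalization", {
  g <- reference_grid(lat = c(40, 40, 40), lon = c(-95, -94.99, -94.98))
  tr <- list(make_rect("A", -95.5, -94.5, 39.5, 40.5))
  lk <- build_lookup(g, tr, population = c("1" = 10, "2" = 10, "3" = 0))
  vals <- data.table::data.table(cell_id = 1:3, x = c(5, NA, 100))
  expect_equal(aggregate_to_tracts(vals, lk, "area")$x,
               weighted.mean(c(5, 100), cos(40 * pi / 180) * c(1, 1)))
  expect_equal(aggregate_to_tracts(vals, lk, "population")$x, 5)
})

test_that("zero population falls back to area weights", {
  g <- reference_grid(lat = c(40, 40.01), lon = c(-95, -95))
  tr <- list(make_rect("A", -95.5, -94.5, 39.5, 40.5))
  lk <- build_lookup(g, tr, population = c("1" = 0, "2" = 0))
  vals <- data.table::data.table(cell_id = 1:2, x = c(10, 30))
  expect_message(out <- aggregate_to_tracts(vals, lk, "population"),
                 "area weights")
  expect_equal(out$x, weighted.mean(c(10, 30), cos(c(40, 40.01) * pi / 180)))
})

test_that("boundary vintages and population years follow the decennial rule", {
  expect_equal(vintage_for_year(c(1998, 1999, 2000, 2009, 2010, 2019, 2020)),
               c(2000L, 2000L, 2000L, 2000L, 2010L, 2010L, 2020L))
  expect_equal(pop_year_for_year(c(1998, 1999, 2000, 2015)),
               c(2000L, 2000L, 2000L, 2015L))
})

test_that("tract parquet writer enforces schema and naming and round-trips", {
  rec <- data.table::CJ(GEOID = c("T1", "T2"), time = 0:23)
  rec[, `:=`(year = 2010L, month = 7L, day = 15L,
             temp_C_used_area = 25, temp_C_used_pop = 25.1,
             rh_pct_used_area = 60, rh_pct_used_pop = 61,
             HI_C_area = 26, HI_C_pop = 26.1,
             WBGT_C_area = 23, WBGT_C_pop = 23.1,
             UTCI_C_area = 27, UTCI_C_pop = NA_real_)]
  data.table::setcolorder(rec, tract_schema())
  dir <- tempfile()
  p <- write_tract_parquet(rec, "2010-07-15", 2010, 2010, dir)
  expect_equal(basename(p),
    "heatstress_tract_area_and_popweighted_2010-07-14_2010-07-15_popy2010_v2010.parquet")
  back <- data.table::as.data.table(arrow::read_parquet(p))
  expect_identical(names(back), tract_schema())
  expect_equal(back, rec, ignore_attr = TRUE)
  # schema violations refuse to write
  expect_error(write_tract_parquet(rec[, -"UTCI_C_pop"], "2010-07-15",
                                   2010, 2010, dir), "schema")
  expect_error(write_tract_parquet(rec[time != 3], "2010-07-15", 2010, 2010,
                                   dir), "24")
})
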