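grid100 <- function(m, cell = 30) {
  raster_grid(m, origin = c(0, nrow(m) * cell), cell_size = cell)
}

test_that("road rasterisation takes the fastest class on overlap", {
  g <- grid100(matrix(0, 5, 5))
  segs <- data.frame(x0 = 5, y0 = 135, x1 = 145, y1 = 135,
                     class = "tertiary", stringsAsFactors = FALSE)
  r <- rasterize_roads(segs, g)
  expect_equal(sum(r$values == road_class_codes()[["tertiary"]]), 5)
  # a primary road over the same cells wins
  segs2 <- rbind(segs, data.frame(x0 = 5, y0 = 135, x1 = 145, y1 = 135,
                                  class = "primary"))
  r2 <- rasterize_roads(segs2, g)
  expect_equal(sum(r2$values == road_class_codes()[["primary"]]), 5)
  # empty input -> all cells none
  r0 <- rasterize_roads(segs[0, ], g)
  expect_true(all(r0$values == road_class_codes()[["none"]]))
  expect_error(rasterize_roads(transform(segs, class = "dirt"), g),
               "unknown road class")
})

test_that("speed raster applies the stated speeds and the water/road rule", {
  rcd <- road_class_codes(); lcd <- land_class_codes()
  road <- grid100(matrix(c(rcd[["primary"]], rcd[["none"]], rcd[["none"]],
                           rcd[["none"]]), 2, 2))
  land <- grid100(matrix(c(lcd[["water"]], lcd[["forest"]], lcd[["water"]],
                           lcd[["open"]]), 2, 2))
  sp <- build_speed_raster(road, land)
  expect_equal(sp$values[1, 1], 60)    # road over water keeps road speed
  expect_equal(sp$values[2, 1], 3)     # forest: 50% slower than open
  expect_equal(sp$values[1, 2], 1.2)   # open-water: one fifth of 6 km/h
  expect_equal(sp$values[2, 2], 6)
  bad <- grid100(matrix(0, 3, 3))
  expect_error(build_speed_raster(road, bad), "not aligned")
})

test_that("slope raster matches the analytic gradient", {
  flat <- grid100(matrix(7, 6, 6))
  expect_true(all(slope_raster(flat)$values == 0))
  # plane rising 3 m per 30 m eastwards: interior slope atan(0.1)
  z <- matrix(rep(seq(0, by = 3, length.out = 8), each = 8), 8, 8)
  sl <- slope_raster(grid100(z))
  expect_equal(sl$values[4, 4], atan(0.1) * 180 / pi, tolerance = 1e-12)
  # doubling elevation increases slope wherever it is nonzero
  sl2 <- slope_raster(grid100(2 * z))
  expect_true(all(sl2$values[sl$values > 0] > sl$values[sl$values > 0]))
  expect_true(all(sl$values >= 0 & sl$values < 90))
})

test_that("cell cost reproduces the analytic values", {
  expect_equal(cell_cost(60, 0, TRUE), 1.8, tolerance = 1e-12)
  expect_equal(cell_cost(6, 0, FALSE), 18.0, tolerance = 1e-12)
  hand <- 30 / cos(10 * pi / 180) / (6 * 1000 / 3600) + 0.02 * 10^2
  expect_equal(cell_cost(6, 10, FALSE), hand, tolerance = 1e-12)
  # strictly increasing in slope, decreasing in speed
  expect_gt(cell_cost(6, 20, FALSE), cell_cost(6, 10, FALSE))
  expect_lt(cell_cost(40, 5, TRUE), cell_cost(20, 5, TRUE))
  expect_error(cell_cost(6, 95, FALSE), "\\[0, 90\\)")
  expect_error(cell_cost(0, 10, FALSE), "positive")
})

test_that("accumulated time equals hand sums and respects sources", {
  cost <- grid100(matrix(1.8, 1, 3))
  acc <- accumulate_time(cost, data.frame(x = 15, y = 15))
  expect_equal(as.vector(acc$values), c(0, 1.8, 3.6))
  expect_error(accumulate_time(cost, data.frame(x = numeric(0),
                                                y = numeric(0))),
               "no source")
  expect_error(accumulate_time(cost, data.frame(x = 1e5, y = 15)), "outside")
})

test_that("Dijkstra agrees with Bellman-Ford on random grids", {
  set.seed(123)
  for (r in 1:30) {
    m <- matrix(runif(64, 0.5, 10), 8, 8)
    if (r %% 3 == 0) m[sample(64, 5)] <- NA  # impassable patches
    cost <- grid100(m)
    src <- data.frame(x = c(15, 200), y = c(15, 120))
    acc <- accumulate_time(cost, src)
    rc <- cell_at(cost, src$x, src$y)
    oracle <- bellman_ford_time(m, rc)
    expect_equal(acc$values, oracle, tolerance = 1e-9)
  }
})

test_that("accumulated time is monotone under extra sources and faster cells", {
  set.seed(7)
  m <- matrix(runif(100, 1, 20), 10, 10)
  cost <- grid100(m)
  a1 <- accumulate_time(cost, data.frame(x = 15, y = 15))
  a2 <- accumulate_time(cost, data.frame(x = c(15, 285), y = c(15, 285)))
  expect_true(all(a2$values <= a1$values + 1e-12))
  # raising a speed (lowering a cost) never increases any accumulated time
  m2 <- m; m2[5, 5] <- m[5, 5] / 10
  a3 <- accumulate_time(grid100(m2), data.frame(x = 15, y = 15))
  expect_true(all(a3$values <= a1$values + 1e-12))
  # removing road cells (raising their cost) never decreases values
  m3 <- m; m3[3, ] <- m[3, ] * 50
  a4 <- accumulate_time(grid100(m3), data.frame(x = 15, y = 15))
  expect_true(all(a4$values >= a1$values - 1e-12))
})

test_that("total time sums the two legs and double-counts off-road", {
  g <- grid100(matrix(1800, 1, 5))  # 1800 s per cell
  s <- accumulate_time(g, data.frame(x = 15, y = 15))
  f <- accumulate_time(g, data.frame(x = 15, y = 15))
  tot <- total_time(s, f)
  expect_equal(tot$values[1, 1], 0)           # co-located station + facility
  expect_equal(tot$values[1, 3], 2 * 3600 / 3600)  # 2T: counted twice
  # plain sum in hours
  a <- grid100(matrix(1800, 2, 2)); b <- grid100(matrix(3600, 2, 2))
  expect_true(all(total_time(a, b)$values == 1.5))
  expect_error(total_time(a, grid100(matrix(0, 3, 3))), "not aligned")
})

test_that("mean extraction and categorisation follow the conventions", {
  tt <- grid100(matrix(c(1, 3, NA, 2), 2, 2), cell = 1000)
  units <- data.frame(unit_id = "U1", x = 1000, y = 1000)
  mt <- extract_mean_time(tt, units, radius = 5000)
  expect_equal(mt$mean_hours, mean(c(1, 3, 2)))
  expect_false(mt$unreachable)
  # all-NA buffer -> unreachable
  tt2 <- grid100(matrix(NA_real_, 2, 2), cell = 1000)
  mt2 <- extract_mean_time(tt2, units, radius = 5000)
  expect_true(mt2$unreachable)

  expect_equal(as.character(categorize_time(c(1.5, 2.5, 3.5, 2, 3))),
               c("<2 h", "2-3 h", ">3 h", "2-3 h", ">3 h"))
  expect_error(categorize_time(-1), "negative")
  expect_error(categorize_time(1, bounds = c(3, 2)), "increasing")

  mtimes <- data.frame(unit_id = c("U1", "U2", "U3"),
                       mean_hours = c(1, 2.5, NA),
                       unreachable = c(FALSE, FALSE, TRUE))
  units3 <- data.frame(unit_id = c("U1", "U2", "U3"),
                       population = c(100L, 100L, 200L))
  s <- population_time_summary(mtimes, units3)
  expect_equal(s[["<2 h"]], 0.25)
  expect_equal(s[["2-3 h"]], 0.25)
  expect_equal(s[["unreachable"]], 0.5)
  expect_equal(sum(unlist(s)), 1, tolerance = 1e-12)
})
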