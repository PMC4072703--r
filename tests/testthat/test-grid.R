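# Grid construction, zonal extraction, availability sampling, the error
# filter, and the linear stretch.

test_that("linear stretch maps extremes to 0/1 and preserves order", {
  expect_equal(linear_stretch(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- linear_stretch(c(5, 5, 5)), "degenerate")
  expect_equal(out, c(0, 0, 0))
  expect_error(linear_stretch(c(NA_real_, Inf)), "finite")
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(50) * 10^sample(-3:3, 1)
    s <- linear_stretch(v)
    expect_equal(order(s), order(v))      # monotone vs sort oracle
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(min(s), 0)
    expect_equal(max(s), 1)
  }
})

test_that("error filter keeps the boundary and reports removals", {
  tel <- data.frame(fawn_id = "a", x = 1:3, y = 1:3,
                    ellipse_area = c(1000, 2115, 3000))
  expect_message(out <- filter_by_error(tel, 2115), "discarded 1")
  expect_equal(nrow(out), 2)
  expect_true(all(out$ellipse_area <= 2115))

  quiet <- filter_by_error(tel[1:2, ], 2115)  # nothing above threshold
  expect_equal(nrow(quiet), 2)
  expect_equal(nrow(filter_by_error(tel[0, ], 2115)), 0)
  expect_error(filter_by_error(data.frame(x = 1), 2115), "ellipse_area")
})

test_that("availability points are uniform over the disc and reproducible", {
  used <- data.frame(x = rep(5000, 10000), y = rep(5000, 10000))
  av <- sample_availability(used, radius = 415, extent = c(10000, 10000),
                            seed = 99)
  d2 <- (av$x - 5000)^2 + (av$y - 5000)^2
  expect_true(all(d2 <= 415^2 + 1e-6))
  # squared distance / r^2 ~ Uniform(0,1) for uniform disc sampling
  ks <- suppressWarnings(stats::ks.test(d2 / 415^2, "punif"))
  expect_gt(ks$p.value, 0.01)
  av2 <- sample_availability(used, radius = 415, extent = c(10000, 10000),
                             seed = 99)
  expect_identical(av, av2)
})

test_that("availability resamples into the extent and rejects hopeless points", {
  used <- data.frame(x = c(10, 300), y = c(10, 300))
  av <- sample_availability(used, radius = 415, extent = c(2000, 2000),
                            seed = 1)
  expect_true(all(av$x >= 0 & av$x <= 2000 & av$y >= 0 & av$y <= 2000))
  dd <- sqrt((av$x - used$x)^2 + (av$y - used$y)^2)
  expect_true(all(dd <= 415 + 1e-6))
  expect_error(
    sample_availability(data.frame(x = -5000, y = -5000), radius = 415,
                        extent = c(2000, 2000), seed = 1),
    "no in-extent"
  )
})

test_that("buffers straddling a class boundary split proportions evenly", {
  land <- split_landscape(extent = 1000, res = 10, bx = 500)
  b <- extract_buffer(c(500, 500), radius = 26, land)
  expect_equal(b$a, 0.5, tolerance = 0.03)
  expect_equal(b$a + b$b, 1)
  # fully inside one class
  b1 <- extract_buffer(c(200, 500), radius = 26, land)
  expect_equal(b1$a, 1)
  expect_equal(b1$b, 0)
  # uniform predator surfaces -> exact means; composite = sum
  expect_equal(b$risk_bobcat, 0.2)
  expect_equal(composite_risk(b), 1.0)
  expect_equal(b$dist_road, 500) # road along y = 0
})

test_that("buffer mean over two equally-overlapped cells averages them", {
  # one raster with two giant cells valued 0.2 / 0.4, boundary at x = 500
  land <- split_landscape(extent = 1000, res = 10, bx = 500)
  land$predators$bobcat <- fs_raster(matrix(c(0.2, 0.4), 1, 2),
                                     cellsize = 500)
  b <- extract_buffer(c(500, 250), radius = 26, land)
  expect_equal(b$risk_bobcat, 0.3, tolerance = 0.02)
})

test_that("buffers wholly outside the extent error", {
  land <- split_landscape()
  expect_error(extract_buffer(c(5000, 5000), radius = 26, land), "outside")
})

test_that("zonal extraction agrees with a 1 m brute-force oracle", {
  w <- tiny_world()
  set.seed(21)
  centers <- cbind(x = runif(12, 100, 1900), y = runif(12, 100, 1900))
  got <- extract_buffer(centers, radius = 26, w$landscape)
  # oracle: 1 m rasterization of the disc
  t <- seq(-26, 26, by = 1)
  off <- as.matrix(expand.grid(t, t))
  off <- off[rowSums(off^2) <= 26^2, ]
  K <- length(w$landscape$class_names)
  for (i in seq_len(nrow(centers))) {
    cls <- raster_lookup(w$landscape$landcover,
                         centers[i, 1] + off[, 1], centers[i, 2] + off[, 2])
    oracle_p <- tabulate(cls, K) / sum(!is.na(cls))
    for (k in seq_len(K)) {
      expect_lt(abs(got[[w$landscape$class_names[k]]][i] - oracle_p[k]), 0.02)
    }
    oracle_risk <- mean(raster_lookup(w$landscape$predators$wolf,
                                      centers[i, 1] + off[, 1],
                                      centers[i, 2] + off[, 2]), na.rm = TRUE)
    expect_lt(abs(got$risk_wolf[i] - oracle_risk), 0.02)
  }
  # proportions sum to 1
  props <- as.matrix(got[, w$landscape$class_names])
  expect_equal(unname(rowSums(props)), rep(1, nrow(props)), tolerance = 1e-9)
})

test_that("grid cells have side sqrt(cell_area) and cover the extent", {
  land <- split_landscape(extent = 460, res = 10, bx = 230)
  grid <- build_grid(land, cell_area = 46^2)
  expect_equal(attr(grid, "n_rows"), 10)
  expect_equal(attr(grid, "n_cols"), 10)
  expect_equal(nrow(grid), 100)

  grid2 <- build_grid(land, cell_area = 2115)
  expect_equal(attr(grid2, "cellsize"), 45.99, tolerance = 1e-4)

  # cell fully inside one landcover class
  inside <- grid[grid$x < 180 & grid$y < 180, ]
  expect_true(all(inside$a == 1))
  # proportions sum to 1 everywhere
  props <- as.matrix(as.data.frame(grid)[, land$class_names])
  expect_equal(unname(rowSums(props)), rep(1, nrow(grid)), tolerance = 1e-9)
  # distance to road (y = 0) equals the centroid y
  expect_equal(grid$dist_road, grid$y, tolerance = 1e-6)
})

test_that("grid construction flags misaligned layers", {
  land <- split_landscape(extent = 1000, res = 10)
  land$predators$wolf <- fs_raster(matrix(0.5, 10, 10), cellsize = 10)
  expect_error(build_grid(land), "wolf")
})

test_that("grid columns rasterize back in row-major order", {
  land <- split_landscape(extent = 460, res = 10, bx = 230)
  grid <- build_grid(land, cell_area = 46^2)
  r <- grid_to_raster(grid, "dist_road")
  expect_equal(dim(r$values), c(10, 10))
  # top row of the raster = northernmost cells (largest y = largest distance)
  expect_equal(r$values[1, 1], max(grid$dist_road))
  expect_equal(raster_lookup(r, grid$x[5], grid$y[5]), grid$dist_road[5])
})
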