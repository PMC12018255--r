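test_that("ASCII grid round trip reproduces values, mask and georeferencing", {
  path <- withr::local_tempfile(fileext = ".asc")
  m <- matrix(c(1.25, -3.1, 0.3333333333333333, NA, 5, 6, 7, 8, 9), 3, 3)
  g <- grid_layer(m, lat_max = 10, lon_min = -80.5, resolution = 1 / 12)
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_identical(g2$values, g$values)
  expect_identical(g2$lat_min, g$lat_min)
  expect_identical(g2$lon_min, g$lon_min)
  expect_identical(g2$resolution, g$resolution)

  g1 <- grid_layer(matrix(pi, 1, 1), lat_max = 0.5, lon_min = 3,
                   resolution = 0.25)
  write_grid(g1, path)
  expect_identical(read_grid(path)$values, g1$values)
})

test_that("files without a georeferencing header are rejected", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("1 2 3", "4 5 6", "7 8 9", "1 2 3", "4 5 6", "7 8 9"), path)
  expect_error(read_grid(path), "georeferencing")
  expect_error(read_grid(file.path(tempdir(), "does-not-exist.asc")),
               "not found")
})

test_that("cell areas follow the spherical band formula", {
  # independent check by numerical integration of the surface element
  for (lat in c(0, -20, 20, 45, 60, 89)) {
    expect_equal(cell_area(lat, 1 / 12), oracle_cell_area(lat, 1 / 12),
                 tolerance = 1e-10)
  }
  expect_equal(cell_area(0, 1 / 12), 85.9, tolerance = 1e-3)
  # high-latitude cells shrink roughly as cos(latitude)
  expect_equal(cell_area(60, 1 / 12) / cell_area(0, 1 / 12), cos(pi / 3),
               tolerance = 1e-3)
  expect_identical(cell_area(-20, 1 / 12), cell_area(20, 1 / 12))
  expect_error(cell_area(90, 1 / 12), "latitude")
})

test_that("cell areas over a full global lattice sum to the sphere's area", {
  res <- 2
  lats <- seq(-90 + res / 2, 90 - res / 2, by = res)
  total <- sum(cell_area(lats, res)) * (360 / res)
  expect_equal(total, 4 * pi * 6371.0088^2, tolerance = 1e-4)
})

test_that("aggregation conserves sums and preserves constants", {
  g <- mk_grid(matrix(1, 4, 4))
  a <- aggregate_grid(g, 2, "sum")
  expect_equal(a$values, matrix(4, 2, 2))
  expect_equal(a$resolution, g$resolution * 2)

  set.seed(5)
  m <- matrix(runif(64), 8, 8)
  m[sample(64, 6)] <- NA
  g <- mk_grid(m)
  expect_equal(sum(aggregate_grid(g, 4, "sum")$values),
               sum(m, na.rm = TRUE))
  expect_equal(aggregate_grid(mk_grid(matrix(7.5, 6, 6)), 3, "mean")$values,
               matrix(7.5, 2, 2))
  expect_error(aggregate_grid(g, 3), "divide")
})

test_that("weighted layer summaries match direct and replication oracles", {
  set.seed(9)
  m <- matrix(rnorm(100), 10, 10)
  w <- matrix(rexp(100), 10, 10)
  layer <- mk_grid(m)
  weights <- mk_grid(w)
  expect_equal(weighted_layer_summary(layer, mk_grid(matrix(1, 10, 10)),
                                      "mean"),
               mean(m))
  expect_equal(weighted_layer_summary(layer, weights, "mean"),
               sum(w * m) / sum(w))
  expect_equal(weighted_layer_summary(layer, weights, "median"),
               oracle_weighted_quantile(as.vector(m), as.vector(w), 0.5,
                                        K = 2e5),
               tolerance = 1e-6)
  one <- matrix(0, 10, 10)
  one[3, 7] <- 2
  expect_identical(weighted_layer_summary(layer, mk_grid(one), "mean"),
                   m[3, 7])
  expect_error(weighted_layer_summary(layer, mk_grid(matrix(0, 10, 10)),
                                      "mean"),
               "zero total weight")
})

test_that("misaligned grids are rejected by multi-layer operations", {
  a <- mk_grid(matrix(1, 4, 4))
  expect_false(grids_aligned(a, mk_grid(matrix(1, 4, 5))))
  expect_false(grids_aligned(a, mk_grid(matrix(1, 4, 4), lat_max = 2)))
  expect_false(grids_aligned(a, mk_grid(matrix(1, 4, 4), lon_min = 1)))
  expect_false(grids_aligned(a, mk_grid(matrix(1, 4, 4), resolution = 0.1)))
  expect_true(grids_aligned(a, mk_grid(matrix(2, 4, 4))))
  expect_error(weighted_layer_summary(a, mk_grid(matrix(1, 4, 5))),
               "not aligned")
})

test_that("nearest-port distances are haversine minima over the port set", {
  g <- grid_layer(matrix(0, 3, 3), lat_max = 1.5, lon_min = -1.5,
                  resolution = 1)
  # centre cell sits at (0, 0)
  at_centre <- tibble::tibble(name = "p", lat = 0, lon = 0)
  d <- nearest_port_distance(g, at_centre)
  expect_equal(d$values[2, 2], 0)

  one_deg <- tibble::tibble(name = "p", lat = 0, lon = 1)
  d1 <- nearest_port_distance(g, one_deg)
  expect_equal(d1$values[2, 2], 111.195, tolerance = 1e-4)

  two <- tibble::tibble(name = c("a", "b"), lat = c(0, 1), lon = c(1, -1))
  dab <- nearest_port_distance(g, two)
  da <- nearest_port_distance(g, two[1, ])
  db <- nearest_port_distance(g, two[2, ])
  expect_true(all(dab$values <= da$values + 1e-9))
  expect_true(all(dab$values <= db$values + 1e-9))
  # permutation invariance
  dba <- nearest_port_distance(g, two[c(2, 1), ])
  expect_identical(dab$values, dba$values)
  expect_error(nearest_port_distance(g, two[0, ]), "empty")
})
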