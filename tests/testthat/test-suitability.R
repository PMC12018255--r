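# Hand-built criteria around known envelopes for contract-level checks.
toy_criteria <- function(crop_cover_min = 0.01) {
  env <- tibble::tibble(
    variable = c("bio1", "bio1", "bio4", "bio4", "bio12", "bio12",
                 "elevation", "soil_ph", "population", "port_distance"),
    stratum = c("low", "high", "low", "high", "low", "high",
                "all", "all", "all", "all"),
    lower = c(23, 24, 300, 300, 912, 543, 0, 5, 20, 0),
    upper = c(28, 28, 1500, 1500, 3690, 3690, 1200, 7, 1500, 600),
    level = 0.9
  )
  bananaclim:::new_suitability_criteria(env, crop_cover_min, "observed",
                                        0.05, FALSE)
}

toy_layers <- function(nr = 4, nc = 4, ...) {
  base <- list(bio1 = 26, bio4 = 700, bio12 = 2000, elevation = 100,
               soil_ph = 6, population = 100, port_distance = 50,
               cropland = 0.5, aei = 0)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  lapply(base, function(x) {
    m <- if (is.matrix(x)) x else matrix(x, nr, nc)
    mk_grid(m)
  })
}

test_that("a cell failing only the crop-cover test is unsuitable", {
  crit <- toy_criteria()
  layers <- toy_layers()
  strata <- stratify_by_irrigation(layers$aei, mk_grid(matrix(1, 4, 4)),
                                   threshold = 0.05)
  expect_true(all(classify_suitability(crit, layers, strata)$values))
  low_cover <- toy_layers(cropland = 0.005)
  expect_false(any(classify_suitability(crit, low_cover, strata)$values))
})

test_that("cells at banana-weighted medians of a scenario are suitable", {
  sc <- unit_scenario()
  strata <- stratify_by_irrigation(sc$layers$aei, sc$layers$banana_area,
                                   threshold = 0.05)
  crit <- build_criteria(sc$layers, sc$layers$banana_area, strata)
  meds <- lapply(sc$layers[c("bio1", "bio4", "bio12", "elevation", "soil_ph",
                             "population", "port_distance")],
                 function(l) weighted_layer_summary(l, sc$layers$banana_area,
                                                    "median"))
  layers <- do.call(toy_layers, c(list(nr = 2, nc = 2), meds,
                                  list(cropland = 0.5, aei = 0)))
  s2 <- stratify_by_irrigation(layers$aei, mk_grid(matrix(1, 2, 2)),
                               threshold = strata$threshold)
  expect_true(all(classify_suitability(crit, layers, s2)$values))
})

test_that("tightening any single envelope never adds suitable cells", {
  sc <- unit_scenario()
  strata <- stratify_by_irrigation(sc$layers$aei, sc$layers$banana_area,
                                   threshold = 0.05)
  crit <- build_criteria(sc$layers, sc$layers$banana_area, strata)
  base <- classify_suitability(crit, sc$layers, strata)$values
  for (i in seq_len(nrow(crit$envelopes))) {
    tight <- crit
    width <- tight$envelopes$upper[i] - tight$envelopes$lower[i]
    tight$envelopes$upper[i] <- tight$envelopes$upper[i] - 0.2 * width
    got <- classify_suitability(tight, sc$layers, strata)$values
    expect_true(all(base[!is.na(base) & !is.na(got) & got]))
  }
})

test_that("eight-way categorization labels and partitions correctly", {
  obs <- mk_grid(matrix(c(5, 0, 2, 0), 2, 2))
  cur <- mk_grid(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  fut <- mk_grid(matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  cats <- categorize(obs, cur, fut)
  lab <- function(r, c) {
    cats$table$label[match(cats$grid$values[r, c], cats$table$code)]
  }
  expect_identical(lab(1, 1), "o+c+f-")
  expect_identical(lab(2, 1), "o-c+f+")
  expect_identical(lab(1, 2), "o+c-f+")
  expect_identical(lab(2, 2), "o-c-f-")

  none <- categorize(mk_grid(matrix(0, 2, 2)),
                     mk_grid(matrix(FALSE, 2, 2)),
                     mk_grid(matrix(FALSE, 2, 2)))
  expect_true(all(none$table$label[none$grid$values] == "o-c-f-"))

  areas <- category_areas(cats)
  expect_equal(sum(areas$area_km2),
               sum(grid_cell_areas(obs)$values))
  expect_identical(sum(areas$n_cells), 4L)
})

test_that("area change reports fractional loss on both bases", {
  full <- mk_grid(matrix(TRUE, 2, 4))
  none_change <- area_change(full, full)
  expect_equal(none_change$change, c(0, 0))

  # keep half the cells in each row so both bases halve exactly
  half <- mk_grid(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 4))
  ac <- area_change(full, half)
  expect_equal(ac$change, c(-0.5, -0.5))
  expect_error(area_change(mk_grid(matrix(FALSE, 2, 2)),
                           mk_grid(matrix(FALSE, 2, 2))),
               "zero")
})

test_that("single-driver masks isolate temperature and precipitation", {
  sc <- unit_scenario()
  strata <- stratify_by_irrigation(sc$layers$aei, sc$layers$banana_area,
                                   threshold = 0.05)
  crit <- build_criteria(sc$layers, sc$layers$banana_area, strata)
  cur <- classify_suitability(crit, sc$layers, strata)

  # future identical to current -> masks identical
  same <- single_driver_mask(crit, sc$layers,
                             sc$layers[c("bio1", "bio4", "bio12")],
                             strata, "temperature")
  expect_identical(same$values, cur$values)

  # warming-only scenario: precipitation-only mask equals current
  prec_only <- single_driver_mask(crit, sc$layers, sc$future, strata,
                                  "precipitation")
  expect_identical(prec_only$values, cur$values)

  # per-cell cross-check: temperature-only mask recomputed brute force
  temp_only <- single_driver_mask(crit, sc$layers, sc$future, strata,
                                  "temperature")
  swapped <- sc$layers
  swapped$bio1 <- sc$future$bio1
  swapped$bio4 <- sc$future$bio4
  expect_identical(temp_only$values,
                   classify_suitability(crit, swapped, strata)$values)
  expect_error(single_driver_mask(crit, sc$layers, sc$future, strata,
                                  "wind"))
})

test_that("occupancy fraction counts banana-bearing suitable cells", {
  obs <- mk_grid(matrix(c(1, 0, 3, 0, 0, 2), 2, 3))
  all_suit <- mk_grid(matrix(TRUE, 2, 3))
  expect_equal(occupancy_fraction(mk_grid(matrix(2, 2, 3)), all_suit), 1)
  expect_equal(occupancy_fraction(mk_grid(matrix(0, 2, 3)), all_suit), 0)

  set.seed(31)
  om <- matrix(rbinom(100, 1, 0.3) * runif(100, 0, 9), 10, 10)
  mm <- matrix(runif(100) < 0.6, 10, 10)
  got <- occupancy_fraction(mk_grid(om), mk_grid(mm))
  expect_equal(got, sum(om > 0 & mm) / sum(mm))
})

test_that("exposure summary reports weighted mean BIO5 per mask and period", {
  b5 <- mk_grid(matrix(30.9, 5, 5))
  fut <- mk_grid(matrix(30.9 + 2.5, 5, 5))
  mask <- mk_grid(matrix(TRUE, 5, 5))
  expo <- exposure_summary(b5, fut, list(suitable = mask))
  expect_equal(expo$mean_bio5[expo$period == "current"], 30.9)
  expect_equal(diff(expo$mean_bio5), 2.5)

  set.seed(8)
  vm <- matrix(rnorm(25, 31), 5, 5)
  wm <- matrix(rexp(25), 5, 5)
  got <- exposure_summary(mk_grid(vm), mk_grid(vm), list(all = mask),
                          weights = mk_grid(wm))
  expect_equal(got$mean_bio5[1], sum(vm * wm) / sum(wm))
})
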