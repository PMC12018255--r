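test_that("weighted quantile follows the left-continuous inverse CDF", {
  expect_identical(weighted_quantile(1:10, rep(1, 10), 0.5), 5)
  expect_identical(weighted_quantile(7, 1, 0.33), 7)
  # all weight on one value dominates every positive level
  for (q in c(0.01, 0.5, 0.99)) {
    expect_identical(weighted_quantile(c(1, 2, 3), c(0, 0, 5), q), 3)
  }
  expect_error(weighted_quantile(c(1, NA), c(1, 1), 0.5), "NA")
  expect_error(weighted_quantile(1:3, c(0, 0, 0), 0.5), "zero")
  expect_error(weighted_quantile(1:3, 1:2, 0.5), "length")
  expect_error(weighted_quantile(1:3, c(-1, 1, 1), 0.5), "nonnegative")
})

test_that("weighted quantile agrees with the replication-expansion oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:1000, 1)
    values <- round(rnorm(n, sd = 10), 2)
    weights <- rexp(n)
    q <- runif(1)
    got <- weighted_quantile(values, weights, q)
    want <- oracle_weighted_quantile(values, weights, q, K = 5e4)
    # agreement within one value-step of the sorted sample
    sorted <- sort(unique(values))
    i_got <- match(got, sorted)
    i_want <- match(want, sorted)
    expect_lte(abs(i_got - i_want), 1)
  }
})

test_that("R90 envelopes are central weighted intervals with >= level coverage", {
  g <- mk_grid(matrix(1:100, 10, 10))
  w <- mk_grid(matrix(1, 10, 10))
  env <- estimate_r90(g, w)
  expect_equal(env$lower, 5)
  expect_equal(env$upper, 95)

  const <- estimate_r90(mk_grid(matrix(2.5, 5, 5)), mk_grid(matrix(1, 5, 5)))
  expect_equal(const$lower, 2.5)
  expect_equal(const$upper, 2.5)

  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rnorm(400), 20, 20)
    wm <- matrix(rexp(400), 20, 20)
    env <- estimate_r90(mk_grid(m), mk_grid(wm))
    inside <- m >= env$lower & m <= env$upper
    expect_gte(sum(wm[inside]) / sum(wm), 0.90)
  }
})

test_that("raising the envelope level never narrows the envelope", {
  set.seed(4)
  m <- matrix(rnorm(400), 20, 20)
  wm <- matrix(rexp(400), 20, 20)
  e90 <- estimate_r90(mk_grid(m), mk_grid(wm), level = 0.90)
  e95 <- estimate_r90(mk_grid(m), mk_grid(wm), level = 0.95)
  expect_lte(e95$lower, e90$lower)
  expect_gte(e95$upper, e90$upper)
})

test_that("irrigation stratification splits at the threshold, boundary low", {
  aei <- mk_grid(matrix(c(0.02, 0.08, 0.05, 0.0), 2, 2))
  w <- mk_grid(matrix(1, 2, 2))
  s <- stratify_by_irrigation(aei, w, threshold = 0.05)
  expect_identical(s$low_mask$values, aei$values <= 0.05)
  expect_identical(s$high_mask$values, aei$values > 0.05)
  expect_true(s$low_mask$values[1, 1])   # 0.02 -> low
  expect_true(s$high_mask$values[2, 1])  # 0.08 -> high
  expect_true(s$low_mask$values[1, 2])   # exactly at threshold -> low

  zero <- stratify_by_irrigation(mk_grid(matrix(0, 2, 2)), w,
                                 threshold = 0.05)
  expect_true(all(zero$low_mask$values))

  # default threshold is the weighted median AEI
  set.seed(12)
  am <- matrix(runif(100), 10, 10)
  wm <- matrix(rexp(100), 10, 10)
  s2 <- stratify_by_irrigation(mk_grid(am), mk_grid(wm))
  expect_equal(s2$threshold,
               oracle_weighted_quantile(as.vector(am), as.vector(wm), 0.5,
                                        K = 2e5),
               tolerance = 1e-6)
  expect_error(stratify_by_irrigation(mk_grid(am * 2), mk_grid(wm)),
               "\\[0, 1\\]")
})

test_that("criteria apply the irrigated precipitation adjustment", {
  # two-column landscape: left column rainfed (aei 0), right irrigated
  nr <- 100
  aei <- mk_grid(cbind(matrix(0, nr, 1), matrix(0.2, nr, 1)))
  w <- mk_grid(matrix(1, nr, 2))
  # rainfed precipitation spans 912..3690, irrigated 543..2356
  bio12 <- mk_grid(cbind(seq(912, 3690, length.out = nr),
                         seq(543, 2356, length.out = nr)))
  fill <- function(x) mk_grid(matrix(x, nr, 2))
  layers <- list(bio1 = fill(26), bio4 = fill(700), bio12 = bio12,
                 elevation = fill(100), soil_ph = fill(6),
                 population = fill(100), port_distance = fill(50))
  strata <- stratify_by_irrigation(aei, w, threshold = 0.05)
  crit <- build_criteria(layers, w, strata)
  env <- tidy(crit)
  lo <- env[env$variable == "bio12" & env$stratum == "low", ]
  hi <- env[env$variable == "bio12" & env$stratum == "high", ]
  raw <- attr(crit, "raw_stratum_envelopes")$bio12
  # applied irrigated envelope: own lower bound, rainfed upper bound
  expect_equal(hi$lower, raw$high$lower)
  expect_equal(hi$upper, lo$upper)
  expect_lt(hi$lower, lo$lower)
  expect_gt(lo$upper, raw$high$upper)

  # merged (unrestricted-irrigation) envelopes contain both strata
  merged <- tidy(build_criteria(layers, w, strata,
                                scenario = "unrestricted_irrigation"))
  for (v in c("bio1", "bio4", "bio12")) {
    mv <- merged[merged$variable == v, ]
    sv <- env[env$variable == v, ]
    expect_lte(mv$lower, min(sv$lower))
    expect_gte(mv$upper, max(sv$upper))
  }
  # identical strata -> merged equals either stratum
  same <- stratify_by_irrigation(mk_grid(matrix(0, nr, 2)), w)
  msgs <- capture_warnings(crit_same <- build_criteria(layers, w, same))
  expect_match(msgs, "falling back", all = TRUE)
  env_same <- tidy(crit_same)
  b1 <- env_same[env_same$variable == "bio1", ]
  expect_equal(b1$lower[1], b1$lower[2])
})

test_that("a stratum with no weight falls back to the unstratified envelope", {
  nr <- 50
  w <- mk_grid(matrix(1, nr, 2))
  fill <- function(x) mk_grid(matrix(x, nr, 2))
  layers <- list(bio1 = mk_grid(matrix(seq(20, 30, length.out = 2 * nr),
                                       nr, 2)),
                 bio4 = fill(700), bio12 = fill(2000),
                 elevation = fill(100), soil_ph = fill(6),
                 population = fill(100), port_distance = fill(50))
  strata <- stratify_by_irrigation(mk_grid(matrix(0, nr, 2)), w,
                                   threshold = 0.05)
  msgs <- capture_warnings(crit <- build_criteria(layers, w, strata))
  expect_match(msgs, "falling back", all = TRUE)
  env <- tidy(crit)
  b1 <- env[env$variable == "bio1", ]
  un <- estimate_r90(layers$bio1, w)
  expect_equal(b1$lower[b1$stratum == "high"], un$lower)
  expect_equal(b1$upper[b1$stratum == "high"], un$upper)
})

test_that("distribution summaries compare banana, cropland and all-land groups", {
  set.seed(21)
  m <- matrix(rnorm(400, 25, 4), 20, 20)
  layer <- mk_grid(m)
  cropland <- mk_grid(matrix(runif(400), 20, 20))
  banana <- matrix(0, 20, 20)
  narrow <- m > 24 & m < 26
  banana[narrow] <- 5
  summaries <- distribution_summaries(list(bio1 = layer), mk_grid(banana),
                                      cropland)
  expect_identical(nrow(summaries), 3L)
  b <- summaries[summaries$group == "banana", ]
  a <- summaries[summaries$group == "all", ]
  # banana confined to a narrow band nests inside the all-land interval
  expect_gt(b$q05, a$q05)
  expect_lt(b$q95, a$q95)
  # quantiles are monotone within every row
  qcols <- as.matrix(summaries[, c("q05", "q25", "q50", "q75", "q95")])
  expect_true(all(t(apply(qcols, 1, diff)) >= 0))

  unif <- distribution_summaries(list(x = mk_grid(matrix(3, 4, 4))),
                                 mk_grid(matrix(1, 4, 4)),
                                 mk_grid(matrix(0.5, 4, 4)))
  expect_true(all(unif[unif$group == "all", c("q05", "q95")] == 3))
})

test_that("criteria serialize and replay through the text format", {
  sc <- unit_scenario()
  strata <- stratify_by_irrigation(sc$layers$aei, sc$layers$banana_area,
                                   threshold = 0.05)
  crit <- build_criteria(sc$layers, sc$layers$banana_area, strata)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_criteria(crit, path)
  back <- read_criteria(path)
  expect_equal(tidy(back), tidy(crit), tolerance = 1e-12)
  expect_equal(back$crop_cover_min, crit$crop_cover_min)
  expect_identical(back$scenario, crit$scenario)
})
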