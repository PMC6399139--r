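test_that("demographic aggregation is exact and matches a group-by oracle", {
  units <- data.frame(unit_id = 1:3)
  dogs <- data.frame(
    unit_id = c(1, 1, 1, 3),
    age = c(2, 4, 6, 10),
    sex = c("female", "female", "male", "male"),
    breed = c("mixed", "pure", "pure", "pure"))
  d <- demographic_covariates(dogs, units)
  expect_equal(d$e, c(3L, 0L, 1L))
  expect_equal(d$DogAverageAge[1], 4.0)
  expect_equal(d$FemaleDogRatio[1], 100 * 2 / 3)
  expect_equal(d$MixedBreedRatio[1], 100 * 1 / 3)
  expect_true(d$flagged[2])

  cfg <- small_region_config()
  reg <- suppressWarnings(generate_region(cfg, seed = 9))
  rd <- generate_dogs(reg$grid, reg$units, cfg, seed = 10)
  fast <- demographic_covariates(rd, reg$units)
  for (u in reg$units$unit_id) {
    sub <- rd[rd$unit_id == u, ]
    expect_identical(fast$e[u], nrow(sub))
    if (nrow(sub) > 0) {
      expect_equal(fast$DogAverageAge[u], mean(sub$age))
      expect_equal(fast$FemaleDogRatio[u], 100 * mean(sub$sex == "female"))
      expect_equal(fast$MixedBreedRatio[u], 100 * mean(sub$breed == "mixed"))
    }
  }
  expect_error(demographic_covariates(transform(dogs, unit_id = 99), units),
               "unknown units")
})

test_that("population density arithmetic and support monotonicity", {
  expect_equal(population_density(5000, 2), 2.5)
  expect_equal(population_density(5000, 0.5), 10)
  expect_equal(population_density(0, 2), 0)
  expect_error(population_density(100, 0), "positive")
})

test_that("distance grid: closed-form cases", {
  # 1 x 6 straight road, vet at the west end
  road <- matrix(TRUE, 1, 6)
  vets <- matrix(FALSE, 1, 6); vets[1, 1] <- TRUE
  g <- cell_grid(1, 6, 100, road = road, vets = vets)
  expect_equal(as.vector(distance_grid(g)), seq(0, 0.5, by = 0.1))
  # a vet cell itself is at distance zero
  expect_equal(distance_grid(g)[1, 1], 0)
  expect_error(distance_grid(cell_grid(1, 6, 100, road = road)), "no veterinary")
})

test_that("distance grid matches the brute-force Dijkstra + snap oracle", {
  # hand-drawn 7 x 7 L-shaped road with off-road cells
  road <- matrix(FALSE, 7, 7)
  road[2, 2:6] <- TRUE
  road[2:6, 6] <- TRUE
  vets <- matrix(FALSE, 7, 7); vets[6, 6] <- TRUE
  g <- cell_grid(7, 7, 100, road = road, vets = vets)
  expect_equal(distance_grid(g), bf_distance_grid(g), tolerance = 1e-12)

  # randomized small grids, including shapes with diagonal shortcuts
  for (s in 1:10) {
    gg <- random_test_grid(sample(5:15, 1), sample(5:15, 1), seed = 1000 + s)
    expect_equal(suppressWarnings(distance_grid(gg)),
                 suppressWarnings(bf_distance_grid(gg)), tolerance = 1e-12)
  }
})

test_that("distance grid invariants: zeros at vets, triangle steps, snap rule", {
  reg <- suppressWarnings(generate_region(small_region_config(), seed = 4))
  d <- distance_grid(reg$grid)
  expect_true(all(d >= 0))
  expect_equal(unname(d[reg$grid$vets]), rep(0, sum(reg$grid$vets)))
  expect_true(all(d[!reg$grid$vets] > 0))
  # along roads, neighbouring cells differ by at most one step length
  road_cells <- which(reg$grid$road)
  rows <- reg$grid$rows
  for (cell in road_cells) {
    r <- (cell - 1L) %% rows + 1L; co <- (cell - 1L) %/% rows + 1L
    for (dd in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
      r2 <- r + dd[1]; c2 <- co + dd[2]
      if (r2 < 1 || r2 > rows || c2 < 1 || c2 > ncol(d)) next
      if (!reg$grid$road[r2, c2]) next
      expect_lte(abs(d[r, co] - d[r2, c2]),
                 0.1 * sqrt(sum(dd^2)) + 1e-9)
    }
  }
})

test_that("zonal means and the support contrast in distances", {
  dg <- matrix(2, 4, 4)
  expect_equal(zonal_mean_distance(dg, 1:16), 2)
  dg2 <- matrix(c(0.1, 0.3, 0.5, 9), 2, 2)
  expect_equal(zonal_mean_distance(dg2, 1:3), 0.3)
  expect_error(zonal_mean_distance(dg, integer(0)), "empty")

  # vets sit in residential cores, so refined-support means average fewer
  # remote cells: refined <= municipal on average across regions
  diffs <- vapply(1:5, function(s) {
    tabs <- small_pipeline_tables(seed = 300 + s)
    mean(tabs$municipal$DistanceToVetCare) -
      mean(tabs$refined_tab$DistanceToVetCare)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("unit tables share every support-independent column bitwise", {
  tabs <- small_pipeline_tables(seed = 7)
  tm <- tabs$municipal; tr <- tabs$refined_tab
  expect_identical(tm$unit_id, tr$unit_id)
  for (col in c("y", "e", "DogAverageAge", "FemaleDogRatio",
                "MixedBreedRatio", "AverageIncomeTax"))
    expect_identical(tm[[col]], tr[[col]])
  # and the two recomputed columns genuinely differ
  expect_false(identical(tm$HumanPopulationDensity, tr$HumanPopulationDensity))
  expect_identical(tm$support, rep("municipal", nrow(tm)))
  # schema: id + support + y + e + six covariates
  expect_equal(ncol(tm), 10)
  # units without dogs are absent
  expect_true(all(tm$e > 0))
})
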