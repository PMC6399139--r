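test_that("cell allocation is the identity on the lattice and flags orphans", {
  cfg <- small_region_config()
  reg <- suppressWarnings(generate_region(cfg, seed = 2))
  map <- allocate_cells(reg$grid, reg$units)
  expect_identical(map, as.vector(reg$grid$unit))
  broken <- reg$grid
  broken$unit[3, 4] <- NA
  expect_error(allocate_cells(broken, reg$units), "no unit")
})

test_that("nearest-centre assignment matches a brute-force oracle and its tie-break", {
  rows <- 9; cols <- 7
  centers <- c(5L, 30L, 47L, 60L)
  fast <- dasycan:::voronoi_assign(centers, rows, cols)
  slow <- vapply(seq_len(rows * cols), function(cell) {
    r <- (cell - 1L) %% rows; co <- (cell - 1L) %/% rows
    cr <- (centers - 1L) %% rows; cc <- (centers - 1L) %/% rows
    d2 <- (r - cr)^2 + (co - cc)^2
    which(d2 == min(d2))[1] # first index = lowest unit id on ties
  }, integer(1))
  expect_identical(fast, slow)
  # explicit tie: centres in the same row two columns apart
  tie <- dasycan:::voronoi_assign(c(1L, 2L * rows + 1L), rows, cols)
  expect_identical(tie[rows + 1L], 1L) # midpoint cell goes to unit 1
})

test_that("refinement recomputes area, centroid and fraction from residential cells", {
  # 6 x 5 grid, one unit; 3 of 30 cells residential
  res <- matrix(FALSE, 6, 5)
  res[cbind(c(1, 6, 6), c(1, 1, 5))] <- TRUE
  grid <- cell_grid(6, 5, 100, residential = res,
                    unit = matrix(1L, 6, 5))
  units <- data.frame(unit_id = 1L, n_cells = 30L, area_km2 = 0.30,
                      centroid_x = 0.25, centroid_y = 0.30)
  ref <- refine_units(units, grid)
  expect_equal(ref$residential_fraction, 0.10)
  expect_equal(ref$area_km2, 3 * 0.01)
  # centroid = mean of the three residential cell centres (hand-computed)
  expect_equal(ref$centroid_x, mean(c(0.05, 0.05, 0.45)))
  expect_equal(ref$centroid_y, mean(c(0.05, 0.55, 0.55)))

  # fully residential unit: refined identical to parent
  grid2 <- cell_grid(6, 5, 100, residential = matrix(TRUE, 6, 5),
                     unit = matrix(1L, 6, 5))
  ref2 <- refine_units(units, grid2)
  expect_equal(ref2$residential_fraction, 1.0)
  expect_equal(ref2$area_km2, units$area_km2)
  expect_equal(c(ref2$centroid_x, ref2$centroid_y),
               c(units$centroid_x, units$centroid_y))

  # empty refinement is flagged, not dropped silently
  grid0 <- cell_grid(6, 5, 100, unit = matrix(1L, 6, 5))
  expect_warning(ref0 <- refine_units(units, grid0), "no residential")
  expect_true(ref0$empty)
})

test_that("area monotonicity holds for every unit in generated regions", {
  for (s in 1:5) {
    reg <- suppressWarnings(generate_region(small_region_config(), seed = s))
    ref <- suppressWarnings(refine_units(reg$units, reg$grid))
    expect_true(all(ref$area_km2 <= reg$units$area_km2 + 1e-12))
    full <- ref$residential_fraction == 1
    expect_equal(ref$area_km2[full], reg$units$area_km2[full])
  }
})

test_that("the pycnophylactic check passes for refinement and catches corruption", {
  counts <- c(a = 4, b = 0, c = 7)
  expect_true(check_pycnophylactic(counts, counts)$ok)
  bad <- counts; bad["c"] <- 8
  chk <- check_pycnophylactic(counts, bad)
  expect_false(chk$ok)
  expect_equal(chk$deltas$unit_id, "c")
  expect_equal(chk$deltas$delta, 1)
  expect_error(check_pycnophylactic(counts, counts[-1]), "id sets differ")

  # property: counts attached to both supports never differ for shared units
  for (s in 1:20) {
    tabs <- small_pipeline_tables(seed = 100 + s)
    chk <- check_pycnophylactic(
      stats::setNames(tabs$municipal$y, tabs$municipal$unit_id),
      stats::setNames(tabs$refined_tab$y, tabs$refined_tab$unit_id))
    expect_true(chk$ok)
  }
})

test_that("centroid displacement has the right geometry and terrain contrast", {
  units <- data.frame(unit_id = 1L, centroid_x = 0, centroid_y = 0)
  refined <- data.frame(unit_id = 1L, centroid_x = 3, centroid_y = 4,
                        empty = FALSE)
  d <- centroid_displacement(units, refined)
  expect_equal(d$magnitude_km, 5)
  expect_equal(d$bearing_deg, (90 - atan2(4, 3) * 180 / pi) %% 360)

  same <- data.frame(unit_id = 1L, centroid_x = 0, centroid_y = 0,
                     empty = FALSE)
  expect_equal(centroid_displacement(units, same)$magnitude_km, 0)
  refined$empty <- TRUE
  expect_error(centroid_displacement(units, refined), "empty")

  # sparse mountain units displace more than dense plateau units on average
  mags <- list(mountain = c(), plateau = c())
  for (s in 1:4) {
    reg <- suppressWarnings(generate_region(
      region_config(n_units = 40, grid_rows = 60, grid_cols = 60), seed = s))
    ref <- suppressWarnings(refine_units(reg$units, reg$grid))
    keep <- !ref$empty
    disp <- centroid_displacement(reg$units[keep, ], ref[keep, ])
    terr <- reg$units$terrain[keep]
    mags$mountain <- c(mags$mountain, disp$magnitude_km[terr == "mountain"])
    mags$plateau <- c(mags$plateau, disp$magnitude_km[terr == "plateau"])
  }
  expect_gt(mean(mags$mountain), mean(mags$plateau))
})

test_that("density on the refined support dominates the municipal density", {
  for (s in 1:3) {
    tabs <- small_pipeline_tables(seed = 200 + s)
    expect_true(all(tabs$refined_tab$HumanPopulationDensity >=
                      tabs$municipal$HumanPopulationDensity - 1e-12))
  }
})
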