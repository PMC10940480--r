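test_that("voxelization reproduces an axis-aligned slab exactly", {
  fx <- fixture_channel(10, spacing = 2.5, wall = 10)
  expect_equal(mean(!fx$grid$solid), 0.5)     # fluid slab fraction one half
  expect_equal(measure_porosity(fx$grid)$porosity, 0.5)
})

test_that("voxel porosity agrees with analytic and Monte-Carlo membership", {
  cell <- preset_cell("O_380_50_500")
  eps_a <- analytic_porosity(cell$spec, cell$layout)
  grid <- voxelize(cell, 2.5, store_gap = FALSE)
  eps_v <- measure_porosity(grid)$porosity
  expect_equal(eps_v, eps_a, tolerance = 0.005 / eps_a)
  set.seed(7)
  eps_mc <- porosity_monte_carlo(cell, n = 2e6)$porosity
  expect_equal(eps_v, eps_mc, tolerance = 0.005 / eps_a)
})

test_that("voxel porosity converges with refinement", {
  cell <- preset_cell("O_380_50_500")
  e1 <- measure_porosity(voxelize(cell, 380 / 48, store_gap = FALSE))$porosity
  e2 <- measure_porosity(voxelize(cell, 380 / 96, store_gap = FALSE))$porosity
  expect_lt(abs(e2 - e1) / e1, 0.005)   # halving the spacing moves it < 0.5%
  eps_a <- analytic_porosity(cell$spec, cell$layout)
  expect_lt(abs(e2 - eps_a), abs(e1 - eps_a) + 1e-4)
})

test_that("coarse spacing is rejected", {
  cell <- preset_cell("O_380_50_500")
  expect_error(voxelize(cell, 60), "too coarse")
})

test_that("minimum-gap rule solidifies contact slivers without opening gaps", {
  cell <- preset_cell("O_380_50_500")
  grid <- voxelize(cell, 380 / 64)
  out <- enforce_min_gap(grid, 1)
  dchg <- attr(out, "min_gap_porosity_change")
  expect_gte(dchg, 0)                       # never increases porosity
  expect_lt(dchg, 0.005)
  # every remaining fluid voxel sees a fiber-to-fiber gap of at least 1 um
  expect_true(all(out$gap[!out$solid] >= 1))
  # percolation in every direction is preserved
  for (ax in c("x", "y", "z"))
    expect_true(check_percolation(out, ax))
  # degenerate gap
  expect_error(enforce_min_gap(grid, 1e6), "degenerate")
})

test_that("grids without contact information pass through unchanged", {
  fx <- fixture_cylinder_array(0.4, resolution = 16)   # single fiber, no contacts
  out <- enforce_min_gap(fx$grid, 1)
  expect_identical(out$solid, fx$grid$solid)
})

test_that("percolation detects open and sealed directions", {
  fx <- fixture_channel(10, spacing = 2.5, wall = 10)
  expect_true(check_percolation(fx$grid, "x"))
  expect_true(check_percolation(fx$grid, "y"))
  expect_false(check_percolation(fx$grid, "z"))   # walls seal the stack
  allsolid <- fx$grid
  allsolid$solid[] <- TRUE
  expect_false(check_percolation(allsolid, "x"))
  # strongly compressed low-porosity bundle still percolates in Z
  cell <- preset_cell("O_380_50_450", 0.15, "interpenetrated")
  grid <- enforce_min_gap(voxelize(cell, 380 / 32), 1)
  expect_lt(measure_porosity(grid)$porosity, 0.26)
  expect_true(check_percolation(grid, "z"))
})

test_that("porosity result bookkeeping is consistent", {
  fx <- fixture_channel(10, spacing = 2.5, wall = 0)
  pr <- measure_porosity(fx$grid)
  expect_equal(pr$porosity, 1)              # channel spanning the whole box
  expect_equal(pr$fluid_volume, pr$box_volume)
})
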