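test_that("fixtures expose consistent closed-form oracles", {
  fx <- fixture_channel(10, spacing = 1)
  expect_equal(fx$K_oracle, 100 / 3 * 1e-12)    # h^2/3 for h = 10 um
  expect_error(fixture_channel(10, spacing = 8), "resolution floor")
  fc <- fixture_cylinder_array(0.4, resolution = 16)
  expect_equal(fc$porosity_oracle, 0.6, tolerance = 0.01)
  expect_error(fixture_cylinder_array(0.8), "touch")
  # axial exceeds transverse over the whole fraction range of interest
  for (vf in seq(0.2, 0.6, by = 0.1))
    expect_gt(drummond_tahir_axial_permeability(100, vf),
              gebart_transverse_permeability(100, vf))
})

test_that("a small study plan runs end to end and normalizes to 1 at 0%", {
  plan <- study_plan(bundles = "O_380_50_500", degrees = c(0, 0.15),
                     methods = "interpenetrated",
                     directions = list(O_380_50_500 = "z"),
                     resolution_flow = 12, resolution_porosity = 24)
  rep <- run_study(plan)
  expect_equal(nrow(rep$errors), 0)
  expect_equal(nrow(rep$porosity_table), 1)
  expect_named(rep$porosity_table, c("bundle_id", "method", "pf_0", "pf_0.15"))
  expect_equal(rep$normalized$K_normalized[rep$normalized$press_fit_degree == 0], 1)
  expect_lt(rep$normalized$K_normalized[rep$normalized$press_fit_degree == 0.15], 1)
  # degrees [0] only: every normalized K is 1
  plan0 <- study_plan(bundles = "O_380_50_500", degrees = 0,
                      directions = list(O_380_50_500 = "z"),
                      resolution_flow = 12, resolution_porosity = 24)
  rep0 <- run_study(plan0)
  expect_true(all(rep0$normalized$K_normalized == 1))
})

test_that("unknown presets give structured errors without aborting the run", {
  plan <- study_plan(bundles = c("NOT_A_BUNDLE", "O_380_50_500"),
                     degrees = c(0),
                     directions = list(NOT_A_BUNDLE = "z", O_380_50_500 = "z"),
                     resolution_flow = 12, resolution_porosity = 24)
  rep <- run_study(plan)
  expect_equal(rep$errors$bundle_id, "NOT_A_BUNDLE")
  expect_match(rep$errors$message, "unknown")
  expect_true("O_380_50_500" %in% rep$results$bundle_id)
})

test_that("study plans validate their degrees", {
  expect_error(study_plan(degrees = c(0.15, 0)), "ascending")
  expect_error(study_plan(degrees = c(0.05, 0.15)), "contain 0")
})

test_that("repeated runs produce byte-identical CSV output", {
  plan <- study_plan(bundles = "O_380_50_500", degrees = c(0, 0.1),
                     directions = list(O_380_50_500 = "z"),
                     resolution_flow = 12, resolution_porosity = 24)
  d1 <- tempfile(); d2 <- tempfile()
  write_study_csv(run_study(plan), d1)
  write_study_csv(run_study(plan), d2)
  for (f in c("porosity.csv", "permeability.csv", "normalized.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("geometry exports round-trip the cell description", {
  cell <- preset_cell("O_380_50_500", 0.10, "interpenetrated")
  js <- tempfile(fileext = ".json")
  write_cell_json(cell, js)
  obj <- jsonlite::read_json(js)
  expect_equal(obj$box_um$Lz, 684)
  expect_equal(obj$press_fit$degree, 0.1)
  expect_gt(length(obj$fibers), 0)
  stl <- tempfile(fileext = ".stl")
  write_cell_stl(cell, stl, sides = 8, axial_step = 200)
  lines <- readLines(stl)
  expect_equal(lines[1], "solid unit_cell")
  expect_gt(sum(grepl("^facet", lines)), 10)
  vtk <- tempfile(fileext = ".vtk")
  write_grid_vtk(voxelize(cell, 380 / 12), vtk)
  expect_match(readLines(vtk, n = 4)[4], "STRUCTURED_POINTS")
})
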