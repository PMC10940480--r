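test_that("Darcy's law arithmetic and error handling", {
  expect_equal(darcy_permeability(Q = 1, A = 1, L = 1, dP = 1, mu = 1e-3), 1e-3)
  # plane channel, half-width 10 um
  fx <- fixture_channel(10, spacing = 10 / 16)
  fld <- solve_flow(flow_problem(fx$grid, "x", "periodic"))
  K <- darcy_permeability(fld$Q, fx$A, fx$L, fld$dP)
  expect_equal(K, 3.33e-11, tolerance = 0.02)
  # proportionality in Q
  expect_equal(darcy_permeability(2, 1, 1, 1, 1e-3),
               2 * darcy_permeability(1, 1, 1, 1, 1e-3))
  expect_error(darcy_permeability(1, 1, 1, 0), "singular")
})

test_that("permeability is a geometric property, independent of viscosity", {
  cell <- preset_cell("O_380_50_500")
  r1 <- directional_permeability(cell, "z", resolution = 12,
                                 fluid = water_properties(viscosity = 1e-3))
  r2 <- directional_permeability(cell, "z", resolution = 12,
                                 fluid = water_properties(viscosity = 2e-3))
  expect_equal(r1$K, r2$K, tolerance = 1e-10)
})

test_that("directional permeability carries Darcy inputs from the nominal box", {
  cell <- preset_cell("O_380_50_500", 0.10, "interpenetrated")
  res <- directional_permeability(cell, "z", resolution = 12)
  expect_equal(res$L, 760 * 0.9 * 1e-6)        # compressed stack height
  expect_equal(res$A, 500 * 500 * 1e-12)
  res_x <- directional_permeability(cell, "x", resolution = 12)
  expect_equal(res_x$L, 500e-6)
  expect_equal(res_x$A, 500 * 760 * 0.9 * 1e-12)
  expect_equal(res$press_fit_degree, 0.10)
  expect_equal(res$bundle_id, "O_380_50_500")
  expect_gt(res$K, 0)
})

test_that("anisotropy orderings of the undeformed reference bundles hold", {
  # coarse grids suffice for the qualitative orderings
  cO <- preset_cell("O_380_50_500")
  kz <- directional_permeability(cO, "z", resolution = 16)$K
  kx <- directional_permeability(cO, "x", resolution = 16)$K
  expect_gt(kz, kx)                             # main > transverse
  cA <- preset_cell("A_380_50_500")
  ka <- vapply(c("x", "y", "z"), function(d)
    directional_permeability(cA, d, resolution = 12)$K, numeric(1))
  expect_gt(ka[["y"]], ka[["z"]])               # axial is the most permeable
  expect_gt(ka[["z"]], ka[["x"]])               # circumferential the least
})

test_that("normalization references the undeformed cell and is monotone", {
  cell0 <- preset_cell("O_380_50_500")
  sweep <- lapply(c(0, 0.05, 0.10, 0.15), function(f)
    directional_permeability(preset_cell("O_380_50_500", f, "interpenetrated"),
                             "z", resolution = 16))
  tbl <- normalize_permeability(sweep)
  expect_equal(tbl$K_normalized[tbl$press_fit_degree == 0], 1)
  ord <- order(tbl$press_fit_degree)
  expect_true(all(diff(tbl$K_normalized[ord]) < 0))   # strictly decreasing
  expect_true(all(tbl$K > 0 & is.finite(tbl$K)))
  # single 0% entry normalizes to exactly 1
  single <- normalize_permeability(sweep[1])
  expect_equal(single$K_normalized, 1)
  # missing reference is an error
  expect_error(normalize_permeability(sweep[-1]), "incomplete sweep")
})

test_that("tidy() flattens results into one-row tibbles", {
  cell <- preset_cell("O_380_50_500")
  res <- directional_permeability(cell, "z", resolution = 12)
  tb <- tidy(res)
  expect_s3_class(tb, "tbl_df")
  expect_equal(nrow(tb), 1)
  expect_named(tb, c("bundle_id", "direction", "method", "press_fit_degree",
                     "porosity", "K", "K0", "K_normalized", "resolution",
                     "dP", "Q"))
})
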