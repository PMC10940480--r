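test_that("constructors validate their invariants", {
  expect_error(fiber_spec(-1, 50), "positive")
  expect_error(fiber_spec(380, 200), "wall_thickness")
  expect_error(fiber_spec(380, 0), "wall_thickness")
  expect_error(bundle_layout("angled", 500, 0), "degenerate")
  expect_error(bundle_layout("angled", 500, 90), "degenerate")
  expect_error(press_fit(-0.1), "degree")
  expect_error(press_fit(0.25), "degree")
  expect_error(press_fit(0.1, "none"), "degree 0")
})

test_that("orthogonal unit cell has the forced box and touching layers", {
  cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
  expect_equal(unname(cell$box), c(500, 500, 760))
  z0 <- sort(vapply(cell$families, `[[`, numeric(1), "z0"))
  expect_equal(z0, c(190, 570))               # layer planes at d/2 and 3d/2
  expect_equal(diff(z0), 380)                 # adjacent layers touch
})

test_that("angled unit cell uses the minimal periodic rectangle", {
  cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("angled", 500, 20))
  expect_equal(unname(cell$box[1]), 500 / cos(20 * pi / 180), tolerance = 1e-12)
  expect_equal(unname(cell$box[2]), 500 / sin(20 * pi / 180), tolerance = 1e-12)
  expect_equal(unname(cell$box[3]), 760)
  expect_equal(unname(round(cell$box[1:2], 1)), c(532.1, 1461.9))
})

test_that("in-layer fiber overlap is rejected", {
  expect_error(build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 300)),
               "overlap")
})

test_that("analytic porosity reproduces the bundle matrix values", {
  spec <- fiber_spec(380, 50)
  expect_equal(round(analytic_porosity(spec, bundle_layout("orthogonal", 500)), 2), 0.40)
  expect_equal(round(analytic_porosity(spec, bundle_layout("orthogonal", 450)), 2), 0.34)
  expect_equal(round(analytic_porosity(spec, bundle_layout("orthogonal", 550)), 2), 0.46)
  # configuration-independent
  expect_equal(analytic_porosity(spec, bundle_layout("angled", 500, 20)),
               analytic_porosity(spec, bundle_layout("orthogonal", 500)))
  # no solid in the thin-fiber limit
  expect_equal(analytic_porosity(fiber_spec(1e-6, 1e-7), bundle_layout("orthogonal", 500)),
               1, tolerance = 1e-6)
  # strictly increasing in pitch, decreasing in diameter
  pitches <- seq(400, 700, by = 50)
  eps_p <- vapply(pitches, function(p)
    analytic_porosity(spec, bundle_layout("orthogonal", p)), numeric(1))
  expect_true(all(diff(eps_p) > 0))
  diam <- seq(200, 380, by = 30)
  eps_d <- vapply(diam, function(d)
    analytic_porosity(fiber_spec(d, d / 8), bundle_layout("orthogonal", 500)), numeric(1))
  expect_true(all(diff(eps_d) < 0))
})

test_that("interpenetrated press-fit compresses the stack rigidly", {
  cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
  out <- apply_press_fit(cell, press_fit(0.15, "interpenetrated"))
  expect_equal(unname(out$box), c(500, 500, 646))
  z0 <- sort(vapply(out$families, `[[`, numeric(1), "z0"))
  expect_equal(diff(z0), 323)                 # 0.85 * 380
  # in-plane box and fiber radii unchanged
  expect_equal(out$box[1:2], cell$box[1:2])
  expect_equal(out$families[[1]]$r, 190)
})

test_that("degree 0 is the identity for both press-fit models", {
  cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
  expect_identical(apply_press_fit(cell, press_fit(0, "interpenetrated")), cell)
  expect_identical(apply_flattened_contact(cell, press_fit(0, "flattened")), cell)
})

test_that("flattened contacts are area-preserving ellipses at the mid-plane", {
  cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
  out <- apply_flattened_contact(cell, press_fit(0.15, "flattened"))
  b <- 190 * 0.85            # 161.5
  a <- 190^2 / b             # 223.53: area preservation a*b = r^2
  # the X-layer fiber (axis y = 0, z = 161.5) contacts the Y-layer at x = 0;
  # probe the cross-section there
  eps <- 0.5
  expect_true(cell_is_solid(out, c(0, a - eps, 161.5)))
  expect_false(cell_is_solid(out, c(0, a + eps, 161.5)))
  # minor semi-axis: the flattened sections of adjacent layers touch exactly
  # at z = z0 + b = 323 um (no interpenetration), so the total solid volume
  # equals the undeformed solid volume divided into the compressed box:
  # porosity = 1 - (pi d / 4p) / (1 - degree)
  eps_flat <- measure_porosity(voxelize(out, 380 / 48, store_gap = FALSE))$porosity
  expect_equal(eps_flat, 1 - (pi * 380 / 2000) / 0.85, tolerance = 0.01)
  # the blend preserves the cross-sectional area along the axis: integrate
  # the solid indicator over a transverse plane between two contacts (the
  # region z < 323 um contains only the X-layer fiber there)
  yy <- seq(-249.75, 249.75, by = 0.5)
  zz <- seq(0.25, 322.75, by = 0.5)
  pts <- cbind(125, rep(yy, times = length(zz)), rep(zz, each = length(yy)))
  area <- sum(cell_is_solid(out, pts)) * 0.25
  expect_equal(area, pi * 190^2, tolerance = 0.01)
})

test_that("flattening rejects wall-inverting degrees", {
  cell <- build_unit_cell(fiber_spec(380, 170), bundle_layout("orthogonal", 500))
  # 1 - 2*170/380 = 0.105; press_fit() itself allows 0.15
  expect_error(apply_flattened_contact(cell, press_fit(0.12, "flattened")),
               "lumen")
})

test_that("generated cells are periodic under all box translations", {
  set.seed(42)
  for (name in c("O_380_50_500", "A_380_50_500")) {
    for (pf in list(NULL, c(0.15, "interpenetrated"), c(0.15, "flattened"))) {
      cell <- if (is.null(pf)) preset_cell(name)
              else preset_cell(name, as.numeric(pf[1]), pf[2])
      n <- 1e6
      pts <- cbind(runif(n, -500, 1500), runif(n, -500, 2000), runif(n, -500, 1500))
      base <- cell_is_solid(cell, pts)
      for (ax in 1:3) {
        shift <- c(0, 0, 0); shift[ax] <- cell$box[ax]
        moved <- sweep(pts, 2, shift, `+`)
        expect_identical(cell_is_solid(cell, moved), base)
      }
    }
  }
})

test_that("voxel porosity of deformed cells matches the exact-overlap oracle", {
  # oracle: quadrature of the crossing-cylinder overlap (helper-oracles.R)
  for (degree in c(0.05, 0.10, 0.15)) {
    exact <- porosity_interpenetrated_exact(380, 500, degree)
    cell <- preset_cell("O_380_50_500", degree, "interpenetrated")
    vox <- measure_porosity(voxelize(cell, 380 / 64, store_gap = FALSE))$porosity
    expect_equal(vox, exact, tolerance = 0.004)
  }
  # angled and orthogonal layups agree (equal porosity microstructures)
  cA <- preset_cell("A_380_50_500", 0.10, "interpenetrated")
  cO <- preset_cell("O_380_50_500", 0.10, "interpenetrated")
  expect_equal(measure_porosity(voxelize(cA, 380 / 48, store_gap = FALSE))$porosity,
               measure_porosity(voxelize(cO, 380 / 48, store_gap = FALSE))$porosity,
               tolerance = 0.01)
})

test_that("press-fit porosity is non-increasing in degree for every preset", {
  for (name in bundle_presets()$bundle_id) {
    eps <- vapply(c(0, 0.05, 0.10, 0.15), function(f) {
      cell <- preset_cell(name, f, "interpenetrated")
      measure_porosity(voxelize(cell, cell$spec$outer_diameter / 32,
                                store_gap = FALSE))$porosity
    }, numeric(1))
    expect_true(all(diff(eps) < 0), info = name)
  }
})

test_that("presets and config files reproduce the bundle matrix", {
  tbl <- bundle_presets()
  expect_equal(nrow(tbl), 6)
  ps <- bundle_preset("O_200_25_263")
  expect_equal(ps$spec$outer_diameter, 200)
  expect_equal(ps$layout$pitch, 263)
  expect_error(bundle_preset("O_999"), "unknown")
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("preset: A_380_50_500", "press_fit:", "  degree: 0.10",
               "  method: interpenetrated"), cfg)
  cell <- read_bundle_config(cfg)
  expect_equal(cell$press_fit$degree, 0.10)
  expect_equal(cell$layout$configuration, "angled")
  expect_equal(attr(cell, "bundle_id"), "A_380_50_500")
})
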