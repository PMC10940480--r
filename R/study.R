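#' Closed-form transverse permeability of a square cylinder array (Gebart)
#'
#' Lubrication-theory closed form for creeping flow perpendicular to a square
#' array of parallel cylinders of radius `R` at fiber volume fraction `Vf`:
#' `K = 16/(9 pi sqrt(2)) * (sqrt(Vf_max / Vf) - 1)^(5/2) * R^2` with
#' `Vf_max = pi/4`.
#'
#' @param R Cylinder radius in micrometres.
#' @param Vf Fiber volume fraction in (0, pi/4).
#' @return Permeability in m^2.
#' @export
gebart_transverse_permeability <- function(R, Vf) {
  stopifnot(R > 0, Vf > 0)
  if (Vf >= pi / 4)
    stop("cylinders touch at Vf = pi/4: transverse flow is sealed", call. = FALSE)
  16 / (9 * pi * sqrt(2)) * (sqrt(pi / (4 * Vf)) - 1)^2.5 * R^2 * .UM2_TO_M2
}

#' Closed-form axial permeability of a square cylinder array (Drummond-Tahir)
#'
#' Series solution for creeping flow parallel to a square array of cylinders:
#' `K = R^2/(4 Vf) * (-ln Vf - 1.476 + 2 Vf - Vf^2/2)`.
#'
#' @inheritParams gebart_transverse_permeability
#' @return Permeability in m^2.
#' @export
drummond_tahir_axial_permeability <- function(R, Vf) {
  stopifnot(R > 0, Vf > 0, Vf < 1)
  R^2 / (4 * Vf) * (-log(Vf) - 1.476 + 2 * Vf - 0.5 * Vf^2) * .UM2_TO_M2
}

# bare voxel_grid constructor for synthetic fixtures
make_grid <- function(solid, spacing, box) {
  structure(list(dims = dim(solid), spacing = rep(spacing, 3),
                 nominal_spacing = spacing, origin = c(0, 0, 0),
                 box = box, solid = solid, gap = NULL, cell = NULL,
                 min_gap = NULL),
            class = "voxel_grid")
}

#' Plane-channel fixture with closed-form permeability
#'
#' A slab of fluid of half-width `h` between solid walls, flow along X.  The
#' exact plane-Poiseuille permeability referred to the channel cross-section
#' is `K = h^2 / 3`; the maximum-to-mean velocity ratio is 3/2.
#'
#' @param half_width Channel half-width in micrometres.
#' @param spacing Voxel edge in micrometres; at most `half_width / 2`.
#' @param wall Solid wall thickness on each side in micrometres (default
#'   `half_width`, which makes the fluid slab exactly half the box).
#' @param length_voxels Box extent along the flow and transverse directions.
#' @return A `fixture`: `grid`, `flow_direction`, oracles `K_oracle` (m^2,
#'   on the channel cross-section `A`), `porosity_oracle`, and the Darcy
#'   geometry `A`, `L` (m).
#' @examples
#' fx <- fixture_channel(10, spacing = 1)
#' fx$K_oracle
#' @export
fixture_channel <- function(half_width, spacing = half_width / 8,
                            wall = half_width, length_voxels = 4) {
  stopifnot(half_width > 0, spacing > 0, wall >= 0)
  if (spacing > half_width / 2)
    stop("resolution floor: spacing must be at most half_width / 2", call. = FALSE)
  nch <- as.integer(round(2 * half_width / spacing))
  nw <- as.integer(round(wall / spacing))
  nz <- nch + 2L * nw
  nx <- as.integer(length_voxels); ny <- as.integer(length_voxels)
  solid <- array(FALSE, dim = c(nx, ny, nz))
  if (nw > 0) {
    solid[, , seq_len(nw)] <- TRUE
    solid[, , nz - seq_len(nw) + 1L] <- TRUE
  }
  box <- c(nx, ny, nz) * spacing
  grid <- make_grid(solid, spacing, box)
  structure(list(name = "plane_channel", grid = grid, flow_direction = "x",
                 half_width = half_width,
                 K_oracle = half_width^2 / 3 * .UM2_TO_M2,
                 porosity_oracle = nch / nz,
                 A = (ny * spacing) * (nch * spacing) * 1e-12,
                 L = box[1] * 1e-6),
            class = "fixture")
}

#' Square cylinder-array fixture with closed-form permeabilities
#'
#' One cylinder (radius `R`, along Z) centred in a square periodic cell sized
#' for the requested fiber volume fraction.  Transverse flow (X) is checked
#' against the Gebart closed form, axial flow (Z) against Drummond-Tahir.
#'
#' @param fiber_fraction Cylinder volume fraction in (0, pi/4).
#' @param resolution Voxels across the cylinder diameter.
#' @param R Cylinder radius in micrometres.
#' @param axial_voxels Grid extent along the cylinder axis.
#' @return A `fixture` with `grid`, `K_transverse_oracle`,
#'   `K_axial_oracle` (m^2, referred to the full cell cross-section),
#'   `porosity_oracle`, and `A`, `L` per direction.
#' @examples
#' fx <- fixture_cylinder_array(0.4, resolution = 16)
#' fx$porosity_oracle
#' @export
fixture_cylinder_array <- function(fiber_fraction, resolution = 32, R = 100,
                                   axial_voxels = 4) {
  stopifnot(R > 0)
  if (fiber_fraction <= 0)
    stop("`fiber_fraction` must be positive", call. = FALSE)
  if (fiber_fraction >= pi / 4)
    stop("cylinders touch at fiber_fraction = pi/4", call. = FALSE)
  Lside <- R * sqrt(pi / fiber_fraction)
  spacing <- 2 * R / resolution
  n <- as.integer(round(Lside / spacing))
  h <- Lside / n
  cc <- (seq_len(n) - 0.5) * h - Lside / 2
  dist2 <- outer(cc^2, cc^2, `+`)
  solid2d <- dist2 <= R^2
  nz <- as.integer(axial_voxels)
  solid <- array(rep(solid2d, nz), dim = c(n, n, nz))
  grid <- structure(list(dims = c(n, n, nz), spacing = c(h, h, h),
                         nominal_spacing = spacing, origin = c(0, 0, 0),
                         box = c(Lside, Lside, nz * h), solid = solid,
                         gap = NULL, cell = NULL, min_gap = NULL),
                    class = "voxel_grid")
  structure(list(name = "square_cylinder_array", grid = grid,
                 R = R, fiber_fraction = fiber_fraction,
                 K_transverse_oracle = gebart_transverse_permeability(R, fiber_fraction),
                 K_axial_oracle = drummond_tahir_axial_permeability(R, fiber_fraction),
                 porosity_oracle = 1 - mean(solid2d)),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("<fixture> %s, %d x %d x %d voxels\n", x$name,
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Define a bundle study plan
#'
#' The full study design: which bundle presets to run, at which press-fit
#' degrees and deformation methods, which flow directions per bundle, and the
#' resolution policy.  Defaults reproduce the packaged study matrix: all six
#' presets, degrees 0/5/10/15%, interpenetrated press-fit, anisotropy
#' directions for the two reference bundles and main-direction (Z) flow for
#' the others.
#'
#' @param bundles Character vector of preset names.
#' @param degrees Press-fit degrees, ascending, containing 0.
#' @param methods `"interpenetrated"` and/or `"flattened"`.
#' @param directions Named list of direction vectors per bundle; `NULL` for
#'   the default policy.
#' @param resolution_flow Voxels per diameter for flow solves.
#' @param resolution_porosity Voxels per diameter for porosity counting.
#' @param min_gap Minimum contact gap in micrometres.
#' @return An object of class `study_plan`.
#' @export
study_plan <- function(bundles = bundle_presets()$bundle_id,
                       degrees = c(0, 0.05, 0.10, 0.15),
                       methods = "interpenetrated",
                       directions = NULL,
                       resolution_flow = 32,
                       resolution_porosity = 64,
                       min_gap = 1) {
  stopifnot(is.character(bundles), length(bundles) > 0)
  degrees <- as.numeric(degrees)
  if (is.unsorted(degrees) || !0 %in% degrees)
    stop("`degrees` must be sorted ascending and contain 0", call. = FALSE)
  stopifnot(all(methods %in% c("interpenetrated", "flattened")))
  if (is.null(directions)) {
    ref <- bundle_presets()
    directions <- lapply(bundles, function(b) {
      row <- ref[ref$bundle_id == b, ]
      if (nrow(row) == 0) return("z")
      if (row$reference && row$configuration == "angled") c("x", "y", "z")
      else if (row$reference) c("z", "x")
      else "z"
    })
    names(directions) <- bundles
  }
  structure(list(bundles = bundles, degrees = degrees, methods = methods,
                 directions = directions,
                 resolution_flow = resolution_flow,
                 resolution_porosity = resolution_porosity,
                 min_gap = min_gap),
            class = "study_plan")
}

#' Run a bundle study
#'
#' Executes the plan cell by cell: porosity of every (bundle, method, degree)
#' and directional permeability for the planned directions, then assembles
#' the porosity table (rows = bundle/method, columns = press-fit degree), the
#' undeformed permeability (K0) table, and the normalized permeability
#' sweeps.  Per-cell errors are collected and the run continues.  The run is
#' fully deterministic: fixed iteration order and no randomness.
#'
#' @param plan A [study_plan()].
#' @param permeability Set `FALSE` to run the porosity part only.
#' @return An object of class `study_report`: tibbles `results`,
#'   `porosity_table`, `K0_table`, `normalized`, `errors`.
#' @export
run_study <- function(plan, permeability = TRUE) {
  stopifnot(inherits(plan, "study_plan"))
  por_rows <- list(); perm_rows <- list(); errors <- list()
  note_error <- function(bundle, stage, msg) {
    errors[[length(errors) + 1]] <<- tibble::tibble(
      bundle_id = bundle, stage = stage, message = conditionMessage(msg))
  }
  for (bundle in plan$bundles) {
    ps <- tryCatch(bundle_preset(bundle), error = function(e) {
      note_error(bundle, "preset", e); NULL })
    if (is.null(ps)) next
    for (method in plan$methods) {
      for (degree in plan$degrees) {
        cell <- tryCatch(preset_cell(bundle, degree, method),
                         error = function(e) { note_error(bundle, "geometry", e); NULL })
        if (is.null(cell)) next
        spacing_por <- cell$spec$outer_diameter / plan$resolution_porosity
        eps <- tryCatch(
          measure_porosity(voxelize(cell, spacing_por, store_gap = FALSE))$porosity,
          error = function(e) { note_error(bundle, "porosity", e); NA_real_ })
        por_rows[[length(por_rows) + 1]] <- tibble::tibble(
          bundle_id = bundle, method = method, press_fit_degree = degree,
          porosity = eps)
        if (!permeability) next
        for (dir in plan$directions[[bundle]]) {
          res <- tryCatch(
            directional_permeability(cell, dir,
                                     resolution = plan$resolution_flow,
                                     min_gap = plan$min_gap),
            error = function(e) { note_error(bundle, paste0("flow_", dir), e); NULL })
          if (!is.null(res)) {
            row <- tidy.permeability_result(res)
            row$method <- method
            perm_rows[[length(perm_rows) + 1]] <- row
          }
        }
      }
    }
  }
  porosity <- dplyr::bind_rows(por_rows)
  porosity_table <- if (nrow(porosity) > 0)
    tidyr::pivot_wider(porosity,
                       names_from = "press_fit_degree",
                       names_prefix = "pf_",
                       values_from = "porosity")
    else porosity
  results <- dplyr::bind_rows(perm_rows)
  K0_table <- if (nrow(results) > 0) {
    k0 <- results[results$press_fit_degree == 0,
                  c("bundle_id", "direction", "porosity", "K")]
    k0[order(k0$bundle_id, k0$direction), ]
  } else results
  normalized <- if (nrow(results) > 0) normalize_permeability(results) else results
  structure(list(results = results, porosity = porosity,
                 porosity_table = porosity_table, K0_table = K0_table,
                 normalized = normalized,
                 errors = if (length(errors)) dplyr::bind_rows(errors)
                          else tibble::tibble(bundle_id = character(),
                                              stage = character(),
                                              message = character()),
                 plan = plan),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n\nPorosity (rows = bundle/method, columns = press-fit degree):\n")
  print(x$porosity_table, n = Inf)
  if (nrow(x$K0_table) > 0) {
    cat("\nUndeformed permeability K0 [m^2]:\n")
    print(x$K0_table, n = Inf)
  }
  if (nrow(x$errors) > 0) {
    cat("\nErrors:\n"); print(x$errors, n = Inf)
  }
  invisible(x)
}

#' Write study tables to CSV
#'
#' Writes `porosity.csv`, `permeability.csv` and `normalized.csv` with fixed
#' numeric formatting, so repeated runs of the same plan produce
#' byte-identical files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study_csv <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) formatC(col, digits = 10, format = "g") else col)
    df
  }
  paths <- c(porosity = file.path(dir, "porosity.csv"),
             permeability = file.path(dir, "permeability.csv"),
             normalized = file.path(dir, "normalized.csv"))
  write.csv(fmt(report$porosity_table), paths["porosity"], row.names = FALSE)
  write.csv(fmt(report$results), paths["permeability"], row.names = FALSE)
  write.csv(fmt(report$normalized), paths["normalized"], row.names = FALSE)
  invisible(paths)
}
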