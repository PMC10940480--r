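#' Darcy permeability from a unit-cell pressure drop
#'
#' `K = mu * (Q / A) * (L / dP)`: the permeability of the porous medium whose
#' repetitive cell passes flow rate `Q` across cross-section `A` over length
#' `L` under pressure drop `dP`.
#'
#' @param Q Volumetric flow rate, m^3/s.
#' @param A Cross-section of the porous medium associated with the cell
#'   (total, not fluid-only), m^2.
#' @param L Cell length along the flow direction, m.
#' @param dP Pressure drop across the cell, Pa (> 0).
#' @param mu Dynamic viscosity, kg/(m s).
#' @return Permeability in m^2.
#' @examples
#' darcy_permeability(Q = 1, A = 1, L = 1, dP = 1, mu = 1e-3)
#' @export
darcy_permeability <- function(Q, A, L, dP, mu = 1e-3) {
  stopifnot(Q > 0, A > 0, L > 0, mu > 0)
  if (dP <= 0)
    stop("singular input: `dP` must be positive", call. = FALSE)
  mu * (Q / A) * (L / dP)
}

#' Directional permeability of a unit cell
#'
#' Full pipeline for one (cell, direction) pair: voxelize, apply the
#' minimum-gap rule, solve the periodic flow problem at the target Reynolds
#' number, and extract K from Darcy's law with `A` and `L` taken from the
#' (press-fit-scaled) nominal box dimensions.
#'
#' @param cell A `unit_cell`.
#' @param direction `"x"`, `"y"` or `"z"`.
#' @param resolution Voxels across the fiber outer diameter (default 32).
#' @param min_gap Minimum fluid gap at contacts in micrometres.
#' @param lateral_bc `"auto"`, `"periodic"` or `"symmetry"`.
#' @param settings A [solver_settings()].
#' @param target_Re Reynolds number of the operating point.
#' @param fluid A [water_properties()] list.
#' @return An object of class `permeability_result` with `K` (m^2),
#'   `porosity`, `press_fit_degree`, `method`, `direction`, `bundle_id`, the
#'   Darcy inputs (`Q`, `A`, `L`, `dP`, `mu`) and solver diagnostics.
#'   `K0` and `K_normalized` are filled by [normalize_permeability()].
#' @examples
#' \donttest{
#' cell <- preset_cell("O_380_50_500")
#' directional_permeability(cell, "z", resolution = 16)
#' }
#' @export
directional_permeability <- function(cell, direction, resolution = 32,
                                     min_gap = 1, lateral_bc = "auto",
                                     settings = solver_settings(),
                                     target_Re = 1,
                                     fluid = water_properties()) {
  stopifnot(inherits(cell, "unit_cell"))
  spacing <- cell$spec$outer_diameter / resolution
  grid <- voxelize(cell, spacing)
  porosity <- measure_porosity(grid)$porosity
  grid <- enforce_min_gap(grid, min_gap)
  prob <- flow_problem(grid, direction, lateral_bc, fluid = fluid,
                       target_Re = target_Re)
  field <- solve_flow(prob, settings)
  K <- darcy_permeability(field$Q, field$A, field$L, field$dP,
                          fluid$viscosity)
  structure(list(
    K = K, K0 = NA_real_, K_normalized = NA_real_,
    porosity = porosity,
    press_fit_degree = cell$press_fit$degree,
    method = cell$press_fit$method,
    direction = c("x", "y", "z")[field$flow_axis],
    bundle_id = attr(cell, "bundle_id") %||% NA_character_,
    resolution = resolution, n_voxels = prod(grid$dims),
    Q = field$Q, A = field$A, L = field$L, dP = field$dP,
    mu = fluid$viscosity,
    superficial_velocity = field$superficial_velocity, Re = field$Re,
    diagnostics = field$diagnostics),
    class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> %s %s-flow: K = %.3g m^2 (porosity %.3f, press-fit %g%% %s)\n",
              if (is.na(x$bundle_id)) "cell" else x$bundle_id, x$direction,
              x$K, x$porosity, 100 * x$press_fit_degree, x$method))
  invisible(x)
}

#' Tidy a permeability result into a one-row tibble
#'
#' @param x A `permeability_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.permeability_result <- function(x, ...) {
  tibble::tibble(bundle_id = x$bundle_id, direction = x$direction,
                 method = x$method, press_fit_degree = x$press_fit_degree,
                 porosity = x$porosity, K = x$K, K0 = x$K0,
                 K_normalized = x$K_normalized, resolution = x$resolution,
                 dP = x$dP, Q = x$Q)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @importFrom tibble as_tibble
#' @export
as_tibble.permeability_result <- function(x, ...) tidy.permeability_result(x)

#' Normalize permeability sweeps by their undeformed value
#'
#' For each (bundle, direction, method) group the permeability is divided by
#' K0, the value at 0% press-fit of the same group; 0% entries normalize to
#' exactly 1.
#'
#' @param results A list of `permeability_result`s or a tibble in the layout
#'   of [tidy.permeability_result()].
#' @return A tibble with `K0` and `K_normalized` filled.
#' @export
normalize_permeability <- function(results) {
  tbl <- if (inherits(results, "data.frame")) tibble::as_tibble(results)
         else dplyr::bind_rows(lapply(results, tidy.permeability_result))
  # the undeformed cell is the common reference for every method
  key_ref <- function(bundle_id, direction) paste(bundle_id, direction)
  ref <- tbl[tbl$press_fit_degree == 0, ]
  if (nrow(ref) == 0)
    stop("incomplete sweep: no 0% press-fit entry to normalize against",
         call. = FALSE)
  k0 <- setNames(ref$K, key_ref(ref$bundle_id, ref$direction))
  keys <- key_ref(tbl$bundle_id, tbl$direction)
  if (any(!keys %in% names(k0)))
    stop("incomplete sweep: missing 0% press-fit entry for ",
         paste(unique(keys[!keys %in% names(k0)]), collapse = ", "),
         call. = FALSE)
  tbl$K0 <- unname(k0[keys])
  tbl$K_normalized <- tbl$K / tbl$K0
  tbl
}
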