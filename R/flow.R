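#' Working fluid properties
#'
#' Water at room temperature: dynamic viscosity 1e-3 kg/(m s), density
#' 998 kg/m^3.  Permeability is a property of the geometry alone, so the
#' fluid only sets the operating point (the Reynolds number), never the
#' extracted K.
#'
#' @param viscosity Dynamic viscosity, kg/(m s).
#' @param density Density, kg/m^3.
#' @return A list with `viscosity` and `density`.
#' @export
water_properties <- function(viscosity = 1e-3, density = 998) {
  stopifnot(viscosity > 0, density > 0)
  list(viscosity = viscosity, density = density)
}

#' Define a periodic unit-cell flow problem
#'
#' @param grid A `voxel_grid`.
#' @param flow_direction `"x"`, `"y"` or `"z"`.
#' @param lateral_bc Boundary condition on the four lateral box faces:
#'   `"periodic"`, `"symmetry"` (free-slip planes, admissible when the box
#'   faces are mirror planes of the microstructure, as in the orthogonal
#'   layout), or `"auto"` (symmetry for orthogonal cells, periodic
#'   otherwise).  The flow direction itself is always periodic.
#' @param fluid A [water_properties()] list.
#' @param target_Re Superficial-velocity Reynolds number to scale the
#'   solution to (default 1, the oxygenator operating point).
#' @param char_length Characteristic length for Re in micrometres; defaults
#'   to the fiber outer diameter when the grid stems from a unit cell.
#' @return An object of class `flow_problem`.
#' @export
flow_problem <- function(grid, flow_direction = "z",
                         lateral_bc = c("auto", "periodic", "symmetry"),
                         fluid = water_properties(), target_Re = 1,
                         char_length = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  lateral_bc <- match.arg(lateral_bc)
  ax <- axis_index(flow_direction)
  is_cell <- !is.null(grid$cell)
  if (lateral_bc == "auto") {
    lateral_bc <- if (is_cell && grid$cell$layout$configuration == "orthogonal")
      "symmetry" else "periodic"
  }
  if (lateral_bc == "symmetry" && is_cell &&
      grid$cell$layout$configuration == "angled")
    stop("the box faces of an angled cell are not mirror planes: ",
         "use lateral_bc = \"periodic\"", call. = FALSE)
  if (is.null(char_length))
    char_length <- if (is_cell) grid$cell$spec$outer_diameter else mean(grid$box)
  structure(list(grid = grid, flow_axis = ax, lateral_bc = lateral_bc,
                 fluid = fluid, target_Re = target_Re,
                 char_length = char_length, driving = "body_force"),
            class = "flow_problem")
}

#' Solver settings
#'
#' @param residual_tolerance Relative residual threshold for continuity and
#'   momentum (default 1e-5).
#' @param max_iterations Maximum outer (pressure) iterations.
#' @param advection `"stokes"` (creeping flow, default: at Re = 1 inertial
#'   corrections are negligible and the pressure-drop/flow-rate relation is
#'   exactly linear) or `"navier_stokes"` (explicit Picard iteration on the
#'   advection term).
#' @param inner_tolerance Relative tolerance of the inner velocity solves
#'   (Schur-complement algorithm only).
#' @param algorithm `"minres"` (preconditioned MINRES on the full
#'   velocity-pressure saddle-point system, default) or `"schur"` (conjugate
#'   gradients on the pressure Schur complement with inner velocity solves).
#'   Both solve the identical discrete system; `"schur"` is kept as an
#'   independent cross-check route.
#' @param picard_iterations,picard_tolerance Control of the advection loop.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(residual_tolerance = 1e-5, max_iterations = 200000,
                            advection = c("stokes", "navier_stokes"),
                            algorithm = c("minres", "schur"),
                            inner_tolerance = 1e-8,
                            picard_iterations = 10, picard_tolerance = 1e-4) {
  advection <- match.arg(advection)
  algorithm <- match.arg(algorithm)
  stopifnot(residual_tolerance > 0)
  structure(list(residual_tolerance = residual_tolerance,
                 max_iterations = as.integer(max_iterations),
                 advection = advection, algorithm = algorithm,
                 inner_tolerance = inner_tolerance,
                 picard_iterations = as.integer(picard_iterations),
                 picard_tolerance = picard_tolerance),
            class = "solver_settings")
}

# dispatch to the chosen algorithm; identical discrete system either way
run_stokes <- function(grid, ax, bc, settings, sx = numeric(0),
                       sy = numeric(0), sz = numeric(0)) {
  if (settings$algorithm == "minres") {
    stokes_solve_minres_cpp(as.integer(grid$solid), as.integer(grid$dims),
                            as.numeric(grid$spacing), ax - 1L, bc,
                            as.numeric(sx), as.numeric(sy), as.numeric(sz),
                            tol = settings$residual_tolerance,
                            max_iterations = settings$max_iterations)
  } else {
    stokes_solve_cpp(as.integer(grid$solid), as.integer(grid$dims),
                     as.numeric(grid$spacing), ax - 1L, bc,
                     as.numeric(sx), as.numeric(sy), as.numeric(sz),
                     tol = settings$residual_tolerance,
                     max_outer = min(settings$max_iterations, 1000L),
                     inner_tol = settings$inner_tolerance)
  }
}

#' Solve steady incompressible flow through a voxelized unit cell
#'
#' Staggered-grid (MAC) finite differences on the voxel lattice, driven by a
#' uniform body force along the flow direction with fully periodic pressure -
#' in the Darcy regime this is equivalent to prescribing the flow rate across
#' a periodic face pair with zero outlet pressure.  No-slip is imposed at
#' solid voxel faces.  The linear Stokes system is solved iteratively for
#' velocity and pressure (preconditioned MINRES on the saddle-point system by
#' default, or conjugate gradients on the pressure Schur complement) until
#' the normalized continuity and momentum residuals both fall below
#' `residual_tolerance`; the normalizations are documented in the solver
#' source.
#'
#' The force magnitude is scaled after the (linear) solve so that the
#' superficial velocity matches `target_Re`.
#'
#' @param problem A [flow_problem()].
#' @param settings A [solver_settings()].
#' @return An object of class `flow_field`: face-centred `velocity` arrays
#'   `u`, `v`, `w` (m/s), periodic-part `pressure` (Pa), `dP` (Pa) across the
#'   cell, `Q` (m^3/s), `superficial_velocity` (m/s), `Re`, and solver
#'   diagnostics.
#' @export
solve_flow <- function(problem, settings = solver_settings()) {
  stopifnot(inherits(problem, "flow_problem"), inherits(settings, "solver_settings"))
  grid <- problem$grid
  ax <- problem$flow_axis
  if (!check_percolation(grid, ax))
    stop("no-flow: the fluid phase does not percolate along the flow direction",
         call. = FALSE)
  # Symmetry (free-slip mirror) planes are admissible only where the box face
  # is a mirror plane of the microstructure.  With the layer registration
  # used here (fiber axes on the x = 0 and y = 0 faces, layer centre planes
  # at z = d/2 and 3d/2) the lateral X and Y faces are mirror planes but the
  # Z faces are not, so a symmetric lateral Z face is never used.
  bc <- rep(0L, 3)
  if (problem$lateral_bc == "symmetry") { bc[1] <- 1L; bc[2] <- 1L }
  bc[ax] <- 0L
  if (settings$advection == "navier_stokes" && any(bc == 1L))
    stop("advection = \"navier_stokes\" requires periodic lateral boundaries",
         call. = FALSE)
  sol <- run_stokes(grid, ax, bc, settings)
  if (!sol$converged)
    stop(sprintf(paste0("flow solver did not converge within %d outer iterations ",
                        "(continuity residual %.3g, momentum residual %.3g)"),
                 settings$max_iterations, sol$res_continuity, sol$res_momentum),
         call. = FALSE)
  if (settings$advection == "navier_stokes")
    sol <- picard_navier_stokes(sol, problem, settings)
  finalize_flow_field(sol, problem, settings)
}

# Scale the unit-force solution (micrometre units, unit viscosity) to
# physical units at the target Reynolds number.
finalize_flow_field <- function(sol, problem, settings) {
  grid <- problem$grid
  ax <- problem$flow_axis
  dims <- grid$dims
  N <- prod(dims)
  comp <- list(sol$u, sol$v, sol$w)[[ax]]
  u_sup_solve <- sum(comp) / N                     # um-units superficial velocity
  if (u_sup_solve <= 0)
    stop("no-flow: zero net flux along the flow direction", call. = FALSE)
  K_um2 <- u_sup_solve                             # K = mu * u_sup / f with mu = f = 1
  mu <- problem$fluid$viscosity
  rho <- problem$fluid$density
  d_m <- problem$char_length * 1e-6
  u_t <- problem$target_Re * mu / (rho * d_m)      # physical superficial velocity
  vel_scale <- u_t / u_sup_solve                   # 0 when nothing drives the flow
  f_phys <- u_t * mu / (K_um2 * .UM2_TO_M2)        # body force, Pa/m
  L_m <- grid$box[ax] * 1e-6
  A_m2 <- prod(grid$box[-ax]) * 1e-12
  structure(list(
    velocity = list(u = array(sol$u * vel_scale, dims),
                    v = array(sol$v * vel_scale, dims),
                    w = array(sol$w * vel_scale, dims)),
    pressure = array(sol$p * f_phys * 1e-6, dims),
    dP = f_phys * L_m,
    Q = u_t * A_m2,
    superficial_velocity = u_t,
    Re = reynolds_number(u_t, problem$char_length, problem$fluid),
    K_um2 = K_um2,
    A = A_m2, L = L_m,
    flow_axis = ax, lateral_bc = problem$lateral_bc,
    grid = grid, fluid = problem$fluid, settings = settings,
    diagnostics = list(outer_iterations = sol$outer_iterations,
                       inner_iterations = sol$inner_iterations,
                       res_continuity = sol$res_continuity,
                       res_momentum = sol$res_momentum,
                       max_div = sol$max_div)),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(paste0("<flow_field> axis %s, dP = %.4g Pa, Q = %.4g m^3/s, ",
                     "Re = %.3g\n  residuals: continuity %.2e, momentum %.2e\n"),
              c("x", "y", "z")[x$flow_axis], x$dP, x$Q, x$Re,
              x$diagnostics$res_continuity, x$diagnostics$res_momentum))
  invisible(x)
}

# Picard iteration on the explicit advection term.  Works in solver units
# (micrometre lengths, unit viscosity) with an effective density chosen so
# the solution's Reynolds number equals the target; the advective source is
# re-evaluated from the latest field until the pressure drop stabilizes.
picard_navier_stokes <- function(sol, problem, settings) {
  grid <- problem$grid
  ax <- problem$flow_axis
  dims <- grid$dims
  N <- prod(dims)
  h <- grid$spacing
  d_um <- problem$char_length
  bc <- c(0L, 0L, 0L)
  dP_prev <- NA_real_
  for (it in seq_len(settings$picard_iterations)) {
    comp <- list(sol$u, sol$v, sol$w)[[ax]]
    u_sup <- sum(comp) / N
    rho_eff <- problem$target_Re / (u_sup * d_um)
    adv <- advection_source(array(sol$u, dims), array(sol$v, dims),
                            array(sol$w, dims), h, rho_eff)
    sol <- run_stokes(grid, ax, bc, settings, adv$sx, adv$sy, adv$sz)
    dP_now <- 1 / (sum(list(sol$u, sol$v, sol$w)[[ax]]) / N)
    if (!is.na(dP_prev) &&
        abs(dP_now - dP_prev) / abs(dP_prev) < settings$picard_tolerance) break
    dP_prev <- dP_now
  }
  sol
}

# -rho (u . grad) u on the staggered faces, central differences, periodic.
advection_source <- function(u, v, w, h, rho) {
  sh <- function(a, ax, by) {
    # circular shift: value at index i+by along axis ax
    idx <- lapply(dim(a), seq_len)
    n <- dim(a)[ax]
    idx[[ax]] <- ((idx[[ax]] - 1 + by) %% n) + 1
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  ddc <- function(a, ax) (sh(a, ax, 1) - sh(a, ax, -1)) / (2 * h[ax])
  sx <- -rho * (u * ddc(u, 1) +
                ((v + sh(v, 1, -1) + sh(v, 2, 1) + sh(sh(v, 1, -1), 2, 1)) / 4) * ddc(u, 2) +
                ((w + sh(w, 1, -1) + sh(w, 3, 1) + sh(sh(w, 1, -1), 3, 1)) / 4) * ddc(u, 3))
  sy <- -rho * (((u + sh(u, 2, -1) + sh(u, 1, 1) + sh(sh(u, 2, -1), 1, 1)) / 4) * ddc(v, 1) +
                v * ddc(v, 2) +
                ((w + sh(w, 2, -1) + sh(w, 3, 1) + sh(sh(w, 2, -1), 3, 1)) / 4) * ddc(v, 3))
  sz <- -rho * (((u + sh(u, 3, -1) + sh(u, 1, 1) + sh(sh(u, 3, -1), 1, 1)) / 4) * ddc(w, 1) +
                ((v + sh(v, 3, -1) + sh(v, 2, 1) + sh(sh(v, 3, -1), 2, 1)) / 4) * ddc(w, 2) +
                w * ddc(w, 3))
  list(sx = sx, sy = sy, sz = sz)
}

#' Superficial-velocity Reynolds number
#'
#' `Re = rho * u * d / mu` with the fiber outer diameter as characteristic
#' length and the superficial (volume-flux per total cross-section) velocity.
#'
#' @param u_superficial Superficial velocity, m/s.
#' @param spec A [fiber_spec()] providing the characteristic length.
#' @param fluid A [water_properties()] list.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds(2.64e-3, fiber_spec(380, 50), water_properties())
#' @export
reynolds <- function(u_superficial, spec, fluid = water_properties()) {
  stopifnot(inherits(spec, "fiber_spec"))
  reynolds_number(u_superficial, spec$outer_diameter, fluid)
}

reynolds_number <- function(u, char_length_um, fluid) {
  fluid$density * u * (char_length_um * 1e-6) / fluid$viscosity
}

#' Volumetric flux through each cross-section along the flow axis
#'
#' Mass-conservation diagnostic: the plane-integrated flow rate should be
#' identical on every cross-section (to solver tolerance).
#'
#' @param field A `flow_field`.
#' @return Numeric vector of Q (m^3/s) per slice.
#' @export
slice_flow_rates <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  ax <- field$flow_axis
  comp <- field$velocity[[ax]]
  h <- field$grid$spacing
  area_vox <- prod(h[-ax]) * 1e-12
  apply(comp, ax, sum) * area_vox
}

#' Grid-sensitivity study of the pressure drop
#'
#' Re-solves the same flow problem at a sequence of voxel spacings and
#' reports the pressure drop per level together with its relative difference
#' from the finest level.  Following the usual mesh-independence procedure,
#' the optimal level is the coarsest one whose pressure drop differs from the
#' finest by less than 1%.
#'
#' @param cell A `unit_cell`.
#' @param direction Flow direction.
#' @param spacings Voxel spacings in micrometres (at least 2 levels).
#' @param lateral_bc,settings,min_gap,target_Re Passed to the flow stages.
#' @return A tibble with one row per level (sorted coarse to fine), columns
#'   `spacing`, `nx`, `ny`, `nz`, `dP`, `K`, `rel_diff_vs_finest`,
#'   `meets_1pct`; the chosen spacing is in attribute `optimal_spacing`.
#' @export
grid_convergence <- function(cell, direction = "z", spacings,
                             lateral_bc = "auto",
                             settings = solver_settings(), min_gap = 1,
                             target_Re = 1) {
  stopifnot(inherits(cell, "unit_cell"), length(spacings) >= 2)
  spacings <- sort(as.numeric(spacings), decreasing = TRUE)
  rows <- lapply(spacings, function(s) {
    grid <- enforce_min_gap(voxelize(cell, s), min_gap)
    prob <- flow_problem(grid, direction, lateral_bc, target_Re = target_Re)
    fld <- solve_flow(prob, settings)
    tibble::tibble(spacing = s, nx = grid$dims[1], ny = grid$dims[2],
                   nz = grid$dims[3], dP = fld$dP,
                   K = fld$K_um2 * .UM2_TO_M2)
  })
  out <- dplyr::bind_rows(rows)
  dP_fine <- out$dP[nrow(out)]
  out$rel_diff_vs_finest <- abs(out$dP - dP_fine) / dP_fine
  out$meets_1pct <- out$rel_diff_vs_finest < 0.01
  attr(out, "optimal_spacing") <- out$spacing[which(out$meets_1pct)[1]]
  out
}
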