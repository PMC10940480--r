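#' Voxelize a unit cell
#'
#' Discretizes the cell on a regular grid: a voxel is solid iff its centre
#' lies inside any (deformed) fiber outer surface, with periodic wrap.  The
#' per-axis voxel count is `round(L / spacing)`, so the effective spacing can
#' differ from the nominal by up to half a voxel per axis (the grid always
#' reproduces the cell box exactly); the three effective spacings are carried
#' in the result and used by the flow solver.
#'
#' Alongside the phase, the local fiber-to-fiber gap (the sum of the two
#' layer families' surface distances) is stored for [enforce_min_gap()].
#'
#' @param cell A `unit_cell`.
#' @param spacing Nominal isotropic voxel edge in micrometres; must be at most
#'   `outer_diameter / 20`.
#' @param store_gap Keep the gap field (doubles memory); default `TRUE`.
#' @return An object of class `voxel_grid`: `dims`, `spacing` (3-vector of
#'   effective spacings), `origin`, `box`, `solid` (logical array), optionally
#'   `gap`.
#' @examples
#' cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
#' grid <- voxelize(cell, spacing = 380 / 24)
#' grid$dims
#' @export
voxelize <- function(cell, spacing, store_gap = TRUE) {
  stopifnot(inherits(cell, "unit_cell"), is.numeric(spacing), spacing > 0)
  d <- cell$spec$outer_diameter
  if (spacing > d / 10)
    stop("resolution too coarse: spacing must be at most outer_diameter/10 = ",
         signif(d / 10, 4), " um", call. = FALSE)
  box <- unname(cell$box)
  dims <- pmax(1L, as.integer(round(box / spacing)))
  h <- box / dims
  xc <- (seq_len(dims[1]) - 0.5) * h[1]
  yc <- (seq_len(dims[2]) - 0.5) * h[2]
  solid <- array(FALSE, dim = dims)
  gap <- if (store_gap) array(0, dim = dims) else NULL
  xy_x <- rep(xc, times = dims[2])
  xy_y <- rep(yc, each = dims[1])
  nxy <- dims[1] * dims[2]
  # chunk over z to bound peak memory on fine grids
  chunk <- max(1L, as.integer(2e6 %/% nxy))
  k <- 1L
  while (k <= dims[3]) {
    kk <- k:min(dims[3], k + chunk - 1L)
    zc <- (kk - 0.5) * h[3]
    px <- rep(xy_x, times = length(kk))
    py <- rep(xy_y, times = length(kk))
    pz <- rep(zc, each = nxy)
    pg <- cell_phase_and_gap(cell, px, py, pz)
    solid[, , kk] <- pg$solid
    if (store_gap) gap[, , kk] <- pg$gap
    k <- k + chunk
  }
  structure(list(dims = dims, spacing = h, nominal_spacing = spacing,
                 origin = c(0, 0, 0), box = box, solid = solid, gap = gap,
                 cell = cell, min_gap = NULL),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing ~%.3g um, porosity %.4f\n",
              x$dims[1], x$dims[2], x$dims[3], mean(x$spacing),
              1 - mean(x$solid)))
  invisible(x)
}

#' Enforce a minimum fluid gap at fiber contacts
#'
#' Fiber layers touch (or interpenetrate) where they cross, leaving
#' infinitesimally thin fluid slivers around the contact line that a flow
#' mesh cannot resolve.  Following the usual treatment, the contact area is
#' slightly extended: any fluid voxel through which the fiber-to-fiber gap
#' (sum of the distances to the two layer families' surfaces) is thinner than
#' `min_gap` is converted to solid, so every remaining fluid passage between
#' crossing fibers is at least `min_gap` thick.
#'
#' @param grid A `voxel_grid` from [voxelize()] with the gap field stored.
#' @param min_gap Minimum fluid passage thickness in micrometres (default 1).
#' @return The modified `voxel_grid`; the porosity change is recorded in
#'   attribute `min_gap_porosity_change`.
#' @export
enforce_min_gap <- function(grid, min_gap = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (any(min_gap >= grid$box))
    stop("degenerate minimum gap: min_gap must be smaller than the cell box",
         call. = FALSE)
  if (is.null(grid$gap)) return(grid)   # nothing known about contacts
  before <- mean(!grid$solid)
  convert <- (!grid$solid) & (grid$gap < min_gap)
  grid$solid[convert] <- TRUE
  grid$min_gap <- min_gap
  attr(grid, "min_gap_porosity_change") <- before - mean(!grid$solid)
  grid
}

#' Measure porosity of a voxel grid
#'
#' @param grid A `voxel_grid`.
#' @return An object of class `porosity_result` with fields `porosity`,
#'   `fluid_volume` and `box_volume` (um^3), and `method = "voxel_count"`.
#' @examples
#' cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
#' measure_porosity(voxelize(cell, 380 / 32))
#' @export
measure_porosity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  vvox <- prod(grid$spacing)
  nfluid <- sum(!grid$solid)
  box_volume <- prod(grid$box)
  structure(list(porosity = nfluid / prod(grid$dims),
                 fluid_volume = nfluid * vvox,
                 box_volume = box_volume,
                 method = "voxel_count"),
            class = "porosity_result")
}

#' Monte-Carlo porosity of a unit cell
#'
#' Independent membership-sampling estimate of the fluid fraction, used as an
#' oracle for the voxel count.
#'
#' @param cell A `unit_cell`.
#' @param n Number of uniform sample points.
#' @return A `porosity_result` with `method = "monte_carlo"`.
#' @export
porosity_monte_carlo <- function(cell, n = 1e6) {
  stopifnot(inherits(cell, "unit_cell"))
  pts <- cbind(runif(n, 0, cell$box[1]),
               runif(n, 0, cell$box[2]),
               runif(n, 0, cell$box[3]))
  eps <- mean(!cell_is_solid(cell, pts))
  structure(list(porosity = eps,
                 fluid_volume = eps * prod(cell$box),
                 box_volume = prod(cell$box),
                 method = "monte_carlo"),
            class = "porosity_result")
}

#' @export
print.porosity_result <- function(x, ...) {
  cat(sprintf("<porosity_result> porosity %.4f (%s)\n", x$porosity, x$method))
  invisible(x)
}

#' Check that the fluid phase percolates along an axis
#'
#' `TRUE` iff a 6-connected fluid path crosses the periodic cell in the given
#' axis (with periodic wrap in the transverse directions).  Guards the flow
#' solver against sealed geometries.
#'
#' @param grid A `voxel_grid`.
#' @param direction `"x"`, `"y"` or `"z"` (or 1:3).
#' @return Logical scalar.
#' @export
check_percolation <- function(grid, direction = "z") {
  stopifnot(inherits(grid, "voxel_grid"))
  ax <- axis_index(direction)
  percolates_cpp(as.integer(grid$solid), as.integer(grid$dims), ax - 1L)
}

axis_index <- function(direction) {
  if (is.numeric(direction)) {
    ax <- as.integer(direction)
  } else {
    ax <- match(tolower(direction), c("x", "y", "z"))
  }
  if (is.na(ax) || ax < 1 || ax > 3)
    stop("`direction` must be one of \"x\", \"y\", \"z\"", call. = FALSE)
  ax
}
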