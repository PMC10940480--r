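#' Fiber cross-section specification
#'
#' Describes one hollow-fiber type by its outer diameter and wall thickness.
#' The fiber lumen (the gas side of the membrane) is treated as solid for all
#' porosity and flow purposes: blood only ever occupies the space between
#' fibers.
#'
#' @param outer_diameter Outer diameter of the fiber in micrometres.
#' @param wall_thickness Wall thickness in micrometres; must be positive and
#'   less than half the outer diameter (the lumen must stay open).
#' @return An object of class `fiber_spec`.
#' @examples
#' fiber_spec(380, 50)
#' @export
fiber_spec <- function(outer_diameter, wall_thickness) {
  stopifnot(is.numeric(outer_diameter), length(outer_diameter) == 1,
            is.numeric(wall_thickness), length(wall_thickness) == 1)
  if (outer_diameter <= 0)
    stop("`outer_diameter` must be positive", call. = FALSE)
  if (wall_thickness <= 0 || wall_thickness >= outer_diameter / 2)
    stop("`wall_thickness` must lie in (0, outer_diameter/2)", call. = FALSE)
  structure(list(outer_diameter = outer_diameter,
                 wall_thickness = wall_thickness),
            class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("<fiber_spec> d = %g um, wall = %g um\n",
              x$outer_diameter, x$wall_thickness))
  invisible(x)
}

#' Bundle layer layout
#'
#' A bundle is a stack of mats of parallel fibers whose orientation alternates
#' between layers.  In the `orthogonal` layout successive layers run along X
#' and Y; in the `angled` layout they run at plus/minus `layer_angle` degrees
#' from the Y (axial) axis.  `pitch` is the centre-to-centre spacing of
#' parallel fibers within a layer, measured perpendicular to their axes.
#'
#' @param configuration `"orthogonal"` or `"angled"`.
#' @param pitch In-layer fiber spacing in micrometres; must exceed the fiber
#'   outer diameter for the layout to be physical.
#' @param layer_angle Angle (degrees) between the fibers and the Y axis for the
#'   angled layout; ignored (and stored as 90) for the orthogonal layout.
#' @return An object of class `bundle_layout`.
#' @examples
#' bundle_layout("orthogonal", pitch = 500)
#' bundle_layout("angled", pitch = 500, layer_angle = 20)
#' @export
bundle_layout <- function(configuration = c("orthogonal", "angled"),
                          pitch, layer_angle = 20) {
  configuration <- match.arg(configuration)
  stopifnot(is.numeric(pitch), length(pitch) == 1, pitch > 0)
  if (configuration == "angled") {
    stopifnot(is.numeric(layer_angle), length(layer_angle) == 1)
    if (layer_angle <= 0 || layer_angle >= 90)
      stop("degenerate layout: `layer_angle` must lie strictly between 0 and 90 degrees; ",
           "use configuration = \"orthogonal\" for 0/90 layups", call. = FALSE)
  } else {
    layer_angle <- 90
  }
  structure(list(configuration = configuration, pitch = pitch,
                 layer_angle = layer_angle),
            class = "bundle_layout")
}

#' @export
print.bundle_layout <- function(x, ...) {
  cat(sprintf("<bundle_layout> %s, pitch = %g um, layer angle = %g deg\n",
              x$configuration, x$pitch, x$layer_angle))
  invisible(x)
}

#' Press-fit descriptor
#'
#' Press-fitting is the compression of the bundle into its rigid housing
#' during device assembly.  It is modelled as a uniform compression of the
#' layer stack along Z (the stacking direction): the layer centre-plane
#' spacing becomes `d * (1 - degree)`.  Two deformation models are available:
#' `"interpenetrated"` moves the fiber layers rigidly and lets fiber
#' cross-sections overlap at contacts, and `"flattened"` additionally replaces
#' the circular cross-section near each contact by an area-preserving ellipse
#' so that no interpenetration remains.
#'
#' @param degree Relative Z-compression of the bundle, a fraction in
#'   \[0, 0.2\].
#' @param method `"none"`, `"interpenetrated"` or `"flattened"`.
#' @return An object of class `press_fit`.
#' @examples
#' press_fit(0.15, "interpenetrated")
#' @export
press_fit <- function(degree = 0,
                      method = c("none", "interpenetrated", "flattened")) {
  method <- match.arg(method)
  stopifnot(is.numeric(degree), length(degree) == 1)
  if (degree < 0 || degree > 0.2)
    stop("press-fit `degree` must lie in [0, 0.2]", call. = FALSE)
  if (method == "none" && degree != 0)
    stop("method \"none\" requires degree 0", call. = FALSE)
  structure(list(degree = degree, method = method), class = "press_fit")
}

#' @export
print.press_fit <- function(x, ...) {
  cat(sprintf("<press_fit> %g%% (%s)\n", 100 * x$degree, x$method))
  invisible(x)
}

# Fiber families -------------------------------------------------------------

# A "family" is one set of parallel fibers (one layer orientation).  All
# layers with the same orientation have identical in-plane line positions, so
# the whole periodic structure is two families, one per layer parity, with
# layer planes alternating along Z with period Lz = 2 d (1 - degree).
#
# For a family with horizontal unit direction t and in-plane normal n
# (n perpendicular to t, both with zero Z component), base line through the
# in-plane origin, the distance of a point to the nearest fiber axis is
#   sqrt(fold(x.n, pitch)^2 + fold(z - z0, Lz)^2)
# where fold(s, p) = s - p * round(s / p).  Contacts with the other family
# occur along each line at axial coordinate
#   xi_c = pitch * (m' - m * (n.n')) / (t.n')
# for the m-th line of this family against the m'-th line of the other: a
# regular spacing pitch / |t.n'| with a per-line phase.
make_families <- function(spec, layout, pf) {
  d <- spec$outer_diameter
  p <- layout$pitch
  degree <- if (pf$method == "none") 0 else pf$degree
  scale_z <- 1 - degree
  if (layout$configuration == "orthogonal") {
    t1 <- c(1, 0, 0); n1 <- c(0, 1, 0)   # layer along X
    t2 <- c(0, 1, 0); n2 <- c(1, 0, 0)   # layer along Y
  } else {
    a <- layout$layer_angle * pi / 180
    t1 <- c(sin(a),  cos(a), 0); n1 <- c(cos(a), -sin(a), 0)
    t2 <- c(-sin(a), cos(a), 0); n2 <- c(cos(a),  sin(a), 0)
  }
  # Contacts of family i with family j lie along each line of i at axial
  # coordinate xi_c = p (m' - m (n_i.n_j)) / (t_i.n_j): spacing p / |t_i.n_j|
  # with a per-line phase whose sign follows t_i.n_j.
  fam <- function(t, n, t_other_n, n_n, z0) {
    list(t = t, n = n, z0 = z0 * scale_z, r = d / 2, pitch = p,
         contact_period = p / abs(t_other_n),
         contact_phase_coef = -n_n / t_other_n)
  }
  list(fam(t1, n1, sum(t1 * n2), sum(n1 * n2), d / 2),
       fam(t2, n2, sum(t2 * n1), sum(n2 * n1), 3 * d / 2))
}

#' Build the undeformed periodic repetitive unit of a fiber bundle
#'
#' Constructs the smallest rectangular periodic cell of the idealized bundle:
#' two touching fiber layers (one per orientation) stacked along Z with period
#' `2 * outer_diameter`.  For the orthogonal layout the in-plane box is
#' `pitch x pitch`; for the angled layout it is
#' `pitch / cos(alpha) x pitch / sin(alpha)`, the smallest rectangle that makes
#' both fiber families periodic.  Layer centre planes sit at `d/2` and `3 d/2`
#' so that adjacent layers touch.
#'
#' @param spec A [fiber_spec()].
#' @param layout A [bundle_layout()].
#' @return An object of class `unit_cell` with fields `box` (Lx, Ly, Lz in
#'   micrometres), `spec`, `layout`, `press_fit` and the per-layer fiber
#'   families.
#' @examples
#' cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
#' cell$box
#' @export
build_unit_cell <- function(spec, layout) {
  stopifnot(inherits(spec, "fiber_spec"), inherits(layout, "bundle_layout"))
  d <- spec$outer_diameter
  p <- layout$pitch
  if (p <= d)
    stop("fibers overlap within a layer: pitch (", p,
         " um) must exceed the fiber outer diameter (", d, " um)", call. = FALSE)
  if (layout$configuration == "orthogonal") {
    box <- c(p, p, 2 * d)
  } else {
    a <- layout$layer_angle * pi / 180
    box <- c(p / cos(a), p / sin(a), 2 * d)
  }
  pf <- press_fit(0, "none")
  structure(list(box = setNames(box, c("Lx", "Ly", "Lz")),
                 spec = spec, layout = layout, press_fit = pf,
                 families = make_families(spec, layout, pf)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %s, box %.4g x %.4g x %.4g um, press-fit %g%% (%s)\n",
              x$layout$configuration, x$box[1], x$box[2], x$box[3],
              100 * x$press_fit$degree, x$press_fit$method))
  invisible(x)
}

#' Analytic porosity of the undeformed bundle
#'
#' The fluid volume fraction of the undeformed repetitive unit is
#' `1 - pi * d / (4 * pitch)`, counting the fiber lumen as solid.  It is
#' independent of the layer configuration: each layer contributes solid volume
#' `pi (d/2)^2` per unit axis length at line density `1 / pitch` over a slab of
#' height `d`.
#'
#' @param spec A [fiber_spec()].
#' @param layout A [bundle_layout()].
#' @return The porosity as a fraction in (0, 1).
#' @examples
#' analytic_porosity(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
#' @export
analytic_porosity <- function(spec, layout) {
  stopifnot(inherits(spec, "fiber_spec"), inherits(layout, "bundle_layout"))
  1 - pi * spec$outer_diameter / (4 * layout$pitch)
}

#' Apply rigid interpenetrated press-fit to a unit cell
#'
#' Compresses the layer stack along Z by the press-fit degree: the box height
#' becomes `Lz * (1 - degree)` and the layer centre planes move rigidly to a
#' spacing of `d * (1 - degree)`.  Fiber cross-sections are unchanged, so
#' fibers of adjacent layers interpenetrate at contacts; the in-plane box is
#' unchanged (the housing constrains the stack only along Z).
#'
#' @param cell A [build_unit_cell()] result (undeformed).
#' @param pf A [press_fit()] with `method = "interpenetrated"` (or degree 0).
#' @return A deformed `unit_cell`.
#' @examples
#' cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
#' apply_press_fit(cell, press_fit(0.15, "interpenetrated"))
#' @export
apply_press_fit <- function(cell, pf) {
  stopifnot(inherits(cell, "unit_cell"), inherits(pf, "press_fit"))
  if (pf$degree < 0 || pf$degree >= 1)
    stop("invalid press-fit degree: must lie in [0, 1)", call. = FALSE)
  if (pf$degree == 0) return(cell)
  if (pf$method != "interpenetrated")
    stop("apply_press_fit() implements the interpenetrated-fibers model; ",
         "use apply_flattened_contact() for method \"flattened\"", call. = FALSE)
  deform_cell(cell, pf)
}

#' Apply press-fit with flattened (elliptical) fiber contacts
#'
#' Same rigid layer motion as [apply_press_fit()], but near every fiber-fiber
#' contact the circular cross-section is replaced by an area-preserving
#' ellipse with minor semi-axis `b = (d/2) (1 - degree)` along Z and major
#' semi-axis `a = (d/2)^2 / b` in the layer plane, blended smoothly back to
#' the circle over an axial length of one diameter.  This removes all
#' interpenetration and mimics the lateral widening of a compressed,
#' nearly-incompressible fiber wall; it is a parametric approximation of the
#' contact deformation, not a structural solution.
#'
#' @param cell A [build_unit_cell()] result (undeformed).
#' @param pf A [press_fit()] with `method = "flattened"` (or degree 0).
#' @return A deformed `unit_cell`.
#' @examples
#' cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
#' apply_flattened_contact(cell, press_fit(0.15, "flattened"))
#' @export
apply_flattened_contact <- function(cell, pf) {
  stopifnot(inherits(cell, "unit_cell"), inherits(pf, "press_fit"))
  if (pf$degree < 0 || pf$degree >= 1)
    stop("invalid press-fit degree: must lie in [0, 1)", call. = FALSE)
  if (pf$degree == 0) return(cell)
  if (pf$method != "flattened")
    stop("apply_flattened_contact() requires a press_fit with method \"flattened\"",
         call. = FALSE)
  d <- cell$spec$outer_diameter
  t <- cell$spec$wall_thickness
  if (pf$degree >= 1 - 2 * t / d)
    stop("lumen collapse: flattening with degree >= 1 - 2*wall/d = ",
         signif(1 - 2 * t / d, 3), " would invert the fiber wall", call. = FALSE)
  deform_cell(cell, pf)
}

deform_cell <- function(cell, pf) {
  out <- cell
  out$press_fit <- pf
  out$box["Lz"] <- 2 * cell$spec$outer_diameter * (1 - pf$degree)
  out$families <- make_families(cell$spec, cell$layout, pf)
  out
}

# Membership -----------------------------------------------------------------

fold_to_nearest <- function(s, period) s - period * round(s / period)

# Per-family signed distance to the (possibly flattened) fiber surface at
# points (x, y, z), periodic across the cell.  Negative inside solid.
family_surface_distance <- function(fam, cell, x, y, z) {
  degree <- if (cell$press_fit$method == "flattened") cell$press_fit$degree else 0
  s  <- x * fam$n[1] + y * fam$n[2]
  ds <- fold_to_nearest(s, fam$pitch)
  dz <- fold_to_nearest(z - fam$z0, cell$box[["Lz"]])
  r  <- fam$r
  if (degree == 0) {
    return(sqrt(ds * ds + dz * dz) - r)
  }
  # flattened: blend circle -> area-preserving ellipse near each contact
  d  <- 2 * r
  m  <- round(s / fam$pitch)
  xi <- x * fam$t[1] + y * fam$t[2]
  uax <- fold_to_nearest(xi - fam$contact_phase_coef * m * fam$pitch,
                         fam$contact_period)
  lam <- 0.5 * (1 + cos(pi * pmin(abs(uax) / d, 1)))
  b <- r * (1 - lam * degree)
  a <- r * r / b
  q <- (ds / a)^2 + (dz / b)^2
  sq <- sqrt(q)
  grad <- 2 * sqrt(ds^2 / a^4 + dz^2 / b^4)
  dist <- ifelse(grad > 0, 2 * sq * (sq - 1) / grad, -b)
  dist
}

#' Solid-phase indicator of a unit cell
#'
#' Tests whether points lie inside any (deformed) fiber outer surface, with
#' periodic wrap across the cell box.  The fiber lumen counts as solid.
#'
#' @param cell A `unit_cell`.
#' @param points An `n x 3` matrix (or 3-vector) of coordinates in
#'   micrometres.
#' @return A logical vector: `TRUE` where the point is solid.
#' @examples
#' cell <- build_unit_cell(fiber_spec(380, 50), bundle_layout("orthogonal", 500))
#' cell_is_solid(cell, c(250, 0, 190))   # on the X-layer fiber axis
#' @export
cell_is_solid <- function(cell, points) {
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else points
  sol <- rep(FALSE, nrow(pts))
  for (fam in cell$families) {
    sol <- sol | (family_surface_distance(fam, cell, pts[, 1], pts[, 2], pts[, 3]) <= 0)
  }
  sol
}

# Solid indicator plus the local fiber-to-fiber gap (sum of the two family
# surface distances), used by the minimum-gap rule.  Vector inputs.
cell_phase_and_gap <- function(cell, x, y, z) {
  d1 <- family_surface_distance(cell$families[[1]], cell, x, y, z)
  d2 <- family_surface_distance(cell$families[[2]], cell, x, y, z)
  list(solid = (d1 <= 0) | (d2 <= 0), gap = d1 + d2)
}

# Fiber instances ------------------------------------------------------------

#' Enumerate fiber axis segments of a unit cell
#'
#' Lists the fiber instances whose axes intersect the cell box, for export and
#' visualization.  Each instance records an axis point, unit direction, outer
#' radius, and a deformation descriptor.
#'
#' @param cell A `unit_cell`.
#' @return A list of fiber instances.
#' @export
cell_fibers <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  box <- cell$box
  out <- list()
  for (fam in cell$families) {
    # range of line indices m whose in-plane offset m * pitch intersects the box
    corners_s <- c(0, box[1] * fam$n[1], box[2] * fam$n[2],
                   box[1] * fam$n[1] + box[2] * fam$n[2])
    m_range <- floor(min(corners_s) / fam$pitch - 1):ceiling(max(corners_s) / fam$pitch + 1)
    for (m in m_range) {
      base <- c(m * fam$pitch * fam$n[1], m * fam$pitch * fam$n[2], fam$z0)
      seg <- clip_line_to_slab(base, fam$t, box, margin = fam$r)
      if (is.null(seg)) next
      deformation <- switch(cell$press_fit$method,
        none = "none",
        interpenetrated = list(type = "interpenetration",
                               overlap_depth = cell$spec$outer_diameter * cell$press_fit$degree),
        flattened = list(type = "ellipse",
                         b = fam$r * (1 - cell$press_fit$degree),
                         a = fam$r^2 / (fam$r * (1 - cell$press_fit$degree)),
                         blend_length = cell$spec$outer_diameter))
      out[[length(out) + 1]] <- list(
        axis_point = base + seg[1] * fam$t,
        axis_direction = fam$t,
        outer_radius = fam$r,
        t_range = c(0, seg[2] - seg[1]),
        deformation = deformation)
    }
  }
  out
}

# Intersect the line base + t*dir with the box [0,Lx]x[0,Ly] expanded by
# `margin` in-plane; returns c(tmin, tmax) or NULL.
clip_line_to_slab <- function(base, dir, box, margin = 0) {
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:2) {
    lo <- -margin; hi <- box[ax] + margin
    if (abs(dir[ax]) < 1e-12) {
      if (base[ax] < lo || base[ax] > hi) return(NULL)
    } else {
      t1 <- (lo - base[ax]) / dir[ax]; t2 <- (hi - base[ax]) / dir[ax]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (!is.finite(tmin) || !is.finite(tmax)) {
    # line parallel to both in-plane axes cannot happen (dir is horizontal unit)
    tmin <- 0; tmax <- max(box[1:2])
  }
  if (tmax <= tmin) return(NULL)
  c(tmin, tmax)
}
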