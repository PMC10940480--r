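#' Export a unit cell as a JSON descriptor
#'
#' Writes the box dimensions, fiber spec, layout, press-fit state and the
#' fiber instances (axis point, direction, radius, deformation) so the
#' geometry can be reproduced elsewhere.
#'
#' @param cell A `unit_cell`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cell_json <- function(cell, path) {
  stopifnot(inherits(cell, "unit_cell"))
  obj <- list(
    box_um = as.list(cell$box),
    fiber_spec = unclass(cell$spec),
    layout = unclass(cell$layout),
    press_fit = unclass(cell$press_fit),
    fibers = lapply(cell_fibers(cell), function(fb) {
      list(axis_point = fb$axis_point, axis_direction = fb$axis_direction,
           outer_radius = fb$outer_radius, t_range = fb$t_range,
           deformation = fb$deformation)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export fiber surfaces as an ASCII STL
#'
#' Triangulates the outer surface of every fiber segment crossing the cell as
#' a circular tube (press-fit contact flattening is carried in the JSON
#' descriptor, not in the STL, which is intended for visualization).
#'
#' @param cell A `unit_cell`.
#' @param path Output file.
#' @param sides Number of facets around the circumference.
#' @param axial_step Axial facet length in micrometres.
#' @return Invisibly, `path`.
#' @export
write_cell_stl <- function(cell, path, sides = 24, axial_step = 50) {
  stopifnot(inherits(cell, "unit_cell"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid unit_cell", con)
  up <- c(0, 0, 1)
  for (fb in cell_fibers(cell)) {
    t <- fb$axis_direction
    e1 <- cross3(t, up); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(t, e1)
    len <- diff(fb$t_range)
    nseg <- max(1L, ceiling(len / axial_step))
    tt <- seq(fb$t_range[1], fb$t_range[2], length.out = nseg + 1)
    th <- seq(0, 2 * pi, length.out = sides + 1)
    ring <- function(tpos) {
      ctr <- fb$axis_point + tpos * t
      sapply(seq_len(sides + 1), function(q)
        ctr + fb$outer_radius * (cos(th[q]) * e1 + sin(th[q]) * e2))
    }
    r_prev <- ring(tt[1])
    for (s in seq_len(nseg)) {
      r_next <- ring(tt[s + 1])
      for (q in seq_len(sides)) {
        write_stl_tri(con, r_prev[, q], r_prev[, q + 1], r_next[, q])
        write_stl_tri(con, r_prev[, q + 1], r_next[, q + 1], r_next[, q])
      }
      r_prev <- r_next
    }
  }
  writeLines("endsolid unit_cell", con)
  invisible(path)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

write_stl_tri <- function(con, p1, p2, p3) {
  nrm <- cross3(p2 - p1, p3 - p1)
  nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
  cat(sprintf("facet normal %g %g %g\n outer loop\n", nrm[1], nrm[2], nrm[3]),
      sprintf("  vertex %g %g %g\n", p1[1], p1[2], p1[3]),
      sprintf("  vertex %g %g %g\n", p2[1], p2[2], p2[3]),
      sprintf("  vertex %g %g %g\n", p3[1], p3[2], p3[3]),
      " endloop\nendfacet\n", file = con, sep = "")
}

#' Export a voxel grid as legacy ASCII VTK
#'
#' STRUCTURED_POINTS with the phase (0 fluid, 1 solid) as CELL_DATA.
#'
#' @param grid A `voxel_grid`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_grid_vtk <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dims
  writeLines(c("# vtk DataFile Version 3.0", "fiberperm voxel grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
               sprintf("SPACING %g %g %g", grid$spacing[1], grid$spacing[2], grid$spacing[3]),
               sprintf("CELL_DATA %d", prod(d)),
               "SCALARS phase int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(grid$solid), collapse = "\n"), con)
  invisible(path)
}

#' Export a flow field as legacy ASCII VTK
#'
#' Cell-centred velocity vectors (averaged from the staggered faces) and the
#' periodic pressure part.
#'
#' @param field A `flow_field`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_flow_vtk <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  grid <- field$grid
  d <- grid$dims
  cc <- cell_centred_velocity(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fiberperm flow field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
               sprintf("SPACING %g %g %g", grid$spacing[1], grid$spacing[2], grid$spacing[3]),
               sprintf("CELL_DATA %d", prod(d)),
               "VECTORS velocity double"), con)
  writeLines(paste(cc$u, cc$v, cc$w, collapse = "\n"), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.numeric(field$pressure), collapse = "\n"), con)
  invisible(path)
}

# average staggered face velocities to cell centres (periodic wrap)
cell_centred_velocity <- function(field) {
  shift_up <- function(a, ax) {
    idx <- lapply(dim(a), seq_len)
    n <- dim(a)[ax]
    idx[[ax]] <- c(seq_len(n)[-1], 1L)
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  u <- field$velocity$u; v <- field$velocity$v; w <- field$velocity$w
  list(u = as.numeric((u + shift_up(u, 1)) / 2),
       v = as.numeric((v + shift_up(v, 2)) / 2),
       w = as.numeric((w + shift_up(w, 3)) / 2))
}
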