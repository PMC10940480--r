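#' Packaged bundle presets
#'
#' The six bundle geometries studied by the package: two reference bundles
#' (orthogonal and angled layup, fiber outer diameter 380 um, wall 50 um,
#' pitch 500 um, porosity 0.40), two pitch variants (450 and 550 um, porosity
#' 0.34 and 0.46) and two fiber-size variants at matched porosity 0.40
#' (200/25/263 and 300/25/395 um).  Preset names encode
#' `<O|A>_<diameter>_<wall>_<pitch>`.
#'
#' @return A tibble with one row per preset.
#' @examples
#' bundle_presets()
#' @export
bundle_presets <- function() {
  tibble::tibble(
    bundle_id      = c("O_380_50_500", "A_380_50_500", "O_380_50_450",
                       "O_380_50_550", "O_200_25_263", "O_300_25_395"),
    configuration  = c("orthogonal", "angled", "orthogonal",
                       "orthogonal", "orthogonal", "orthogonal"),
    outer_diameter = c(380, 380, 380, 380, 200, 300),
    wall_thickness = c(50, 50, 50, 50, 25, 25),
    pitch          = c(500, 500, 450, 550, 263, 395),
    layer_angle    = c(90, 20, 90, 90, 90, 90),
    reference      = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Look up one bundle preset
#'
#' @param name Preset name, e.g. `"O_380_50_500"`.
#' @return A list with elements `spec` ([fiber_spec()]), `layout`
#'   ([bundle_layout()]) and `bundle_id`.
#' @examples
#' bundle_preset("A_380_50_500")
#' @export
bundle_preset <- function(name) {
  tbl <- bundle_presets()
  row <- tbl[tbl$bundle_id == name, ]
  if (nrow(row) != 1)
    stop("unknown bundle preset \"", name, "\"; available: ",
         paste(tbl$bundle_id, collapse = ", "), call. = FALSE)
  list(bundle_id = name,
       spec = fiber_spec(row$outer_diameter, row$wall_thickness),
       layout = bundle_layout(row$configuration, row$pitch,
                              if (row$configuration == "angled") row$layer_angle else 20))
}

#' Build the unit cell of a named preset
#'
#' Convenience wrapper: [bundle_preset()] followed by [build_unit_cell()] and,
#' if requested, a press-fit deformation.  The returned cell carries the
#' preset name as attribute `bundle_id`.
#'
#' @param name Preset name.
#' @param degree Press-fit degree (fraction).
#' @param method Press-fit method (`"interpenetrated"` or `"flattened"`);
#'   ignored when `degree` is 0.
#' @return A `unit_cell`.
#' @examples
#' preset_cell("O_380_50_500", degree = 0.15, method = "interpenetrated")
#' @export
preset_cell <- function(name, degree = 0, method = "interpenetrated") {
  ps <- bundle_preset(name)
  cell <- build_unit_cell(ps$spec, ps$layout)
  if (degree > 0) {
    pf <- press_fit(degree, method)
    cell <- if (method == "flattened") apply_flattened_contact(cell, pf)
            else apply_press_fit(cell, pf)
  }
  attr(cell, "bundle_id") <- name
  cell
}

#' Read a bundle configuration file
#'
#' A plain declarative YAML file naming the fiber spec, layout and press-fit,
#' either via a `preset` key or explicit fields:
#' \preformatted{
#' preset: O_380_50_500      # or outer_diameter/wall_thickness/pitch/...
#' press_fit:
#'   degree: 0.10
#'   method: interpenetrated
#' }
#'
#' @param path Path to the YAML file.
#' @return A `unit_cell`.
#' @export
read_bundle_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    ps <- bundle_preset(cfg$preset)
    spec <- ps$spec; layout <- ps$layout; id <- ps$bundle_id
  } else {
    spec <- fiber_spec(cfg$outer_diameter, cfg$wall_thickness)
    layout <- bundle_layout(cfg$configuration %||% "orthogonal", cfg$pitch,
                            cfg$layer_angle %||% 20)
    id <- NULL
  }
  cell <- build_unit_cell(spec, layout)
  if (!is.null(cfg$press_fit) && (cfg$press_fit$degree %||% 0) > 0) {
    pf <- press_fit(cfg$press_fit$degree, cfg$press_fit$method)
    cell <- if (pf$method == "flattened") apply_flattened_contact(cell, pf)
            else apply_press_fit(cell, pf)
  }
  if (!is.null(id)) attr(cell, "bundle_id") <- id
  cell
}

`%||%` <- function(a, b) if (is.null(a)) b else a
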