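#' Plot a cross-sectional slice of a voxel grid
#'
#' @param grid A `voxel_grid`.
#' @param axis Slicing axis (`"x"`, `"y"` or `"z"`).
#' @param index Slice index; defaults to the mid-plane.
#' @return A ggplot object (solid phase in dark, fluid in light).
#' @export
plot_slice <- function(grid, axis = "y", index = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  ax <- axis_index(axis)
  if (is.null(index)) index <- ceiling(grid$dims[ax] / 2)
  sl <- slice_array(grid$solid, ax, index)
  other <- setdiff(1:3, ax)
  h <- grid$spacing
  df <- expand.grid(a = (seq_len(dim(sl)[1]) - 0.5) * h[other[1]],
                    b = (seq_len(dim(sl)[2]) - 0.5) * h[other[2]])
  df$phase <- factor(ifelse(as.vector(sl), "solid", "fluid"),
                     levels = c("fluid", "solid"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["a"]], y = .data[["b"]],
                                   fill = .data[["phase"]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(fluid = "grey92", solid = "grey25")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(c("x", "y", "z")[other[1]], " [um]"),
                  y = paste0(c("x", "y", "z")[other[2]], " [um]"),
                  fill = NULL)
}

#' Plot the velocity magnitude on a slice of a flow field
#'
#' @param field A `flow_field`.
#' @param axis Slicing axis.
#' @param index Slice index; defaults to the mid-plane.
#' @return A ggplot object.
#' @export
plot_velocity_slice <- function(field, axis = "y", index = NULL) {
  stopifnot(inherits(field, "flow_field"))
  ax <- axis_index(axis)
  grid <- field$grid
  if (is.null(index)) index <- ceiling(grid$dims[ax] / 2)
  cc <- cell_centred_velocity(field)
  vmag <- array(sqrt(cc$u^2 + cc$v^2 + cc$w^2), grid$dims)
  sl <- slice_array(vmag, ax, index)
  other <- setdiff(1:3, ax)
  h <- grid$spacing
  df <- expand.grid(a = (seq_len(dim(sl)[1]) - 0.5) * h[other[1]],
                    b = (seq_len(dim(sl)[2]) - 0.5) * h[other[2]])
  df$v <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["a"]], y = .data[["b"]],
                                   fill = .data[["v"]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(c("x", "y", "z")[other[1]], " [um]"),
                  y = paste0(c("x", "y", "z")[other[2]], " [um]"),
                  fill = "|u| [m/s]")
}

slice_array <- function(a, ax, index) {
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  idx[[ax]] <- index
  do.call(`[`, c(list(a), idx, list(drop = TRUE)))
}

#' Plot normalized permeability against press-fit degree
#'
#' One line per (bundle, direction, method), mirroring the usual presentation
#' of press-fit sweeps.
#'
#' @param object A `study_report` (or a normalized tibble from
#'   [normalize_permeability()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  tbl <- if (inherits(object, "study_report")) object$normalized else object
  stopifnot(nrow(tbl) > 0)
  tbl$series <- paste(tbl$bundle_id, tbl$direction, tbl$method)
  ggplot2::ggplot(tbl, ggplot2::aes(x = 100 * .data[["press_fit_degree"]],
                                    y = .data[["K_normalized"]],
                                    colour = .data[["series"]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "press-fit degree [%]", y = "K / K0", colour = NULL) +
    ggplot2::ylim(0, NA)
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
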