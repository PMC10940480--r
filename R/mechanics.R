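#' Neo-Hookean material model of the fiber wall
#'
#' Two-parameter hyperelastic model with strain-energy density
#' `U = C10 (I1_bar - 3) + (1/D1) (J_el - 1)^2`, where `I1_bar` is the first
#' deviatoric strain invariant and `J_el` the elastic volume ratio.  The
#' packaged default, [oxyphan_pp_material()], carries the constants calibrated
#' against transverse compression of commercial polypropylene oxygenator
#' fibers.
#'
#' @param C10 Shear-like modulus parameter, MPa (> 0).
#' @param D1 Compressibility parameter, 1/MPa (> 0).
#' @return An object of class `neo_hookean`.
#' @examples
#' neo_hookean(17.308, 0.027)
#' @export
neo_hookean <- function(C10, D1) {
  stopifnot(is.numeric(C10), length(C10) == 1,
            is.numeric(D1), length(D1) == 1)
  if (C10 <= 0 || D1 <= 0)
    stop("`C10` and `D1` must be positive", call. = FALSE)
  structure(list(C10 = C10, D1 = D1), class = "neo_hookean")
}

#' @export
print.neo_hookean <- function(x, ...) {
  cat(sprintf("<neo_hookean> C10 = %g MPa, D1 = %g 1/MPa\n", x$C10, x$D1))
  invisible(x)
}

#' Calibrated polypropylene fiber material
#'
#' The Neo-Hookean constants calibrated for OXYPHAN-type polypropylene hollow
#' fibers (outer diameter 380 um, wall 50 um) under transverse compression:
#' `C10 = 17.308` MPa, `D1 = 0.027` 1/MPa.
#'
#' @return A `neo_hookean` material.
#' @export
oxyphan_pp_material <- function() neo_hookean(17.308, 0.027)

#' Neo-Hookean strain-energy density
#'
#' @param mat A [neo_hookean()] material.
#' @param I1_bar First deviatoric strain invariant (>= 3).
#' @param J_el Elastic volume ratio (> 0).
#' @return Strain-energy density in MPa.
#' @examples
#' strain_energy(oxyphan_pp_material(), I1_bar = 3.1, J_el = 1)
#' @export
strain_energy <- function(mat, I1_bar, J_el = 1) {
  stopifnot(inherits(mat, "neo_hookean"))
  if (any(I1_bar < 3))
    stop("invalid invariant: `I1_bar` must be >= 3", call. = FALSE)
  if (any(J_el <= 0))
    stop("`J_el` must be positive", call. = FALSE)
  mat$C10 * (I1_bar - 3) + (1 / mat$D1) * (J_el - 1)^2
}

#' Small-strain moduli implied by a Neo-Hookean material
#'
#' Standard limits of the potential at the reference state: initial shear
#' modulus `mu0 = 2 C10`, initial bulk modulus `K = 2 / D1`, and the isotropic
#' Poisson ratio `nu = (3K - 2 mu0) / (2 (3K + mu0))`.
#'
#' @param mat A [neo_hookean()] material.
#' @return A list with `shear_modulus` (MPa), `bulk_modulus` (MPa),
#'   `poisson_ratio`.
#' @examples
#' derived_moduli(oxyphan_pp_material())
#' @export
derived_moduli <- function(mat) {
  stopifnot(inherits(mat, "neo_hookean"))
  mu0 <- 2 * mat$C10
  K <- 2 / mat$D1
  nu <- (3 * K - 2 * mu0) / (2 * (3 * K + mu0))
  list(shear_modulus = mu0, bulk_modulus = K, poisson_ratio = nu)
}
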