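# Independent oracles used across the suite.

# Exact porosity of an interpenetrated-press-fit cell (orthogonal layout):
# two perpendicular cylinder families minus the crossing overlap volume,
# obtained by 1D quadrature of the crossing-lens cross-section.
porosity_interpenetrated_exact <- function(d, p, degree) {
  r <- d / 2
  cdist <- d * (1 - degree)           # layer centre-plane spacing
  Lz <- 2 * d * (1 - degree)
  overlap <- if (cdist < 2 * r) {
    integrand <- function(z)
      4 * sqrt(pmax(r^2 - z^2, 0)) * sqrt(pmax(r^2 - (z - cdist)^2, 0))
    stats::integrate(integrand, cdist - r, r, rel.tol = 1e-10)$value
  } else 0
  solid <- 2 * pi * r^2 * p - 2 * overlap
  1 - solid / (p^2 * Lz)
}

# Sangani-Acrivos dilute-limit expansion for transverse creeping flow
# through a square array of cylinders; accurate to well under 1% at c = 0.05.
sangani_acrivos_transverse_K <- function(R, c) {
  S <- 0.5 * log(1 / c) - 0.738 + c - 0.887 * c^2 + 2.038 * c^3
  R^2 * S / (4 * c) * 1e-12
}

# published reference values for the study bundles, used by the acceptance suite
published_K0 <- c(orth_z = 4.44e-10, orth_x = 3.54e-10,
              angl_x = 1.33e-10, angl_y = 6.35e-10, angl_z = 4.45e-10)
published_porosity_0 <- c(O_380_50_500 = 0.40, A_380_50_500 = 0.40,
                      O_380_50_450 = 0.34, O_380_50_550 = 0.46,
                      O_200_25_263 = 0.40, O_300_25_395 = 0.40)
published_interp_rows <- list(
  O_380_50_500 = c(`0` = 0.40, `0.05` = 0.38, `0.1` = 0.35, `0.15` = 0.32),
  A_380_50_500 = c(`0` = 0.40, `0.05` = 0.37, `0.1` = 0.35, `0.15` = 0.32))
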