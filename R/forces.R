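#' Hertzian force magnitude between two soft disks
#'
#' Elastic repulsion between deformable cells in contact:
#' \deqn{F = \frac{h^{3/2}}{\tfrac{3}{2}\,\frac{1-\nu^2}{E}\,
#'   \sqrt{1/R_i + 1/R_j}}}
#' with overlap `h`, common elastic modulus `E` (MPa) and Poisson ratio
#' `nu`. Vectorized over `h`.
#'
#' @param h overlap(s), um; must be non-negative.
#' @param R_i,R_j radii of the two cells, um.
#' @param E elastic modulus, MPa.
#' @param nu Poisson ratio.
#' @return force magnitude(s) in model units (MPa um^2 scale).
#' @export
hertz_force_magnitude <- function(h, R_i, R_j, E = 1e-3, nu = 0.5) {
  if (any(h < 0)) stop("overlap h must be non-negative")
  h^1.5 / (1.5 * (1 - nu^2) / E * sqrt(1 / R_i + 1 / R_j))
}

#' Total pairwise forces on all cells
#'
#' Sums the Hertzian repulsion over all contacting pairs (h_ij > 0) using
#' minimum-image distances; the force on cell i from j acts along the unit
#' vector from j's centre to i's centre. Pairwise antisymmetry makes the
#' net force exactly zero.
#'
#' @param pop a [cell_population()].
#' @param params a [sim_params()] (supplies E and nu).
#' @return N x 2 matrix of force components.
#' @export
total_forces <- function(pop, params) {
  forces_stress_cpp(pop$positions, pop$radii, pop$box_length,
                    params$elastic_modulus_E, params$poisson_nu)$forces
}

#' Off-diagonal virial stress of a configuration
#'
#' \deqn{P_{\mu\nu} = \frac{1}{A} \sum_{i<j} r_{ij,\mu} f_{ij,\nu}}
#' with minimum-image separations and A = L^2. No kinetic term enters: the
#' model is overdamped and athermal, so the stress is purely interaction
#' (virial) stress. For central pairwise forces P_xy = P_yx exactly.
#'
#' @inheritParams total_forces
#' @return list with components `pxy` and `pyx`.
#' @export
virial_stress <- function(pop, params) {
  r <- forces_stress_cpp(pop$positions, pop$radii, pop$box_length,
                         params$elastic_modulus_E, params$poisson_nu)
  list(pxy = r$pxy, pyx = r$pyx)
}
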