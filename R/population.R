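#' Create a cell population
#'
#' A `cell_population` is the instantaneous simulation state: N disk radii
#' and centre positions in a periodic square box of side `box_length`.
#' Positions are wrapped into the primary image `[0, L)^2`.
#'
#' @param positions N x 2 matrix of centre coordinates, um.
#' @param radii length-N vector of radii, um.
#' @param box_length box side L, um; must exceed twice the largest radius.
#' @return an object of class `cell_population`.
#' @export
cell_population <- function(positions, radii, box_length) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("positions must be an N x 2 matrix")
  if (nrow(positions) != length(radii))
    stop("positions and radii disagree on N")
  if (any(radii <= 0)) stop("radii must be positive")
  if (box_length < 2 * max(radii))
    stop("box_length must be at least twice the largest radius")
  positions <- positions %% box_length
  structure(list(positions = positions, radii = as.numeric(radii),
                 box_length = box_length),
            class = "cell_population")
}

#' Box side length that realizes a target packing fraction
#'
#' The packing (area) fraction is phi = sum(pi R_i^2) / L^2, so
#' `L = sqrt(sum(pi * radii^2) / phi)`.
#'
#' @param radii cell radii, um.
#' @param phi target packing fraction in (0, 1).
#' @return box side, um.
#' @export
box_length_for_phi <- function(radii, phi) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0, 1)")
  sqrt(sum(pi * radii^2) / phi)
}

#' Packing fraction of a population
#'
#' @param pop a [cell_population()].
#' @return sum(pi R_i^2) / L^2.
#' @export
packing_fraction <- function(pop) {
  sum(pi * pop$radii^2) / pop$box_length^2
}

#' Pair overlap between two cells
#'
#' h_ij = max(0, R_i + R_j - d_ij) with d_ij the minimum-image distance;
#' the basic measure of interpenetration of soft cells.
#'
#' @param pop a [cell_population()].
#' @param i,j distinct cell indices.
#' @return overlap in um (0 when not in contact).
#' @export
pair_overlap <- function(pop, i, j) {
  if (i == j) stop("i and j must differ")
  L <- pop$box_length
  d <- pop$positions[i, ] - pop$positions[j, ]
  d <- d - L * round(d / L)
  max(0, pop$radii[i] + pop$radii[j] - sqrt(sum(d^2)))
}

#' Random initial placement of cells at a target packing fraction
#'
#' Positions are uniform in the box; severe overlaps are expected and are
#' removed by the zero-noise relaxation stage of [run_simulation()].
#'
#' @param radii cell radii, um.
#' @param target_phi packing fraction; fixes the box via
#'   [box_length_for_phi()].
#' @param box_length optional explicit box side (overrides `target_phi`).
#' @return a [cell_population()].
#' @export
random_population <- function(radii, target_phi = NULL, box_length = NULL) {
  if (is.null(box_length)) {
    if (is.null(target_phi)) stop("give target_phi or box_length")
    box_length <- box_length_for_phi(radii, target_phi)
  }
  n <- length(radii)
  pos <- cbind(runif(n, 0, box_length), runif(n, 0, box_length))
  cell_population(pos, radii, box_length)
}

#' Square lattice population
#'
#' `n_side^2` equal cells on a square lattice: a zero-force reference
#' configuration used in tests and examples.
#'
#' @param n_side cells per side.
#' @param radius common radius, um.
#' @param target_phi packing fraction fixing the box size.
#' @return a [cell_population()].
#' @export
lattice_population <- function(n_side, radius = 8.5, target_phi = 0.7) {
  n <- n_side^2
  L <- box_length_for_phi(rep(radius, n), target_phi)
  a <- L / n_side
  g <- (seq_len(n_side) - 0.5) * a
  pos <- as.matrix(expand.grid(x = g, y = g))
  cell_population(pos, rep(radius, n), L)
}

#' @export
print.cell_population <- function(x, ...) {
  cat("cell_population:", length(x$radii), "cells, L =",
      signif(x$box_length, 6), "um, phi =",
      signif(packing_fraction(x), 4), "\n")
  cat("  radii: [", signif(min(x$radii), 4), ",", signif(max(x$radii), 4),
      "] um, mean", signif(mean(x$radii), 4), "um\n")
  invisible(x)
}
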