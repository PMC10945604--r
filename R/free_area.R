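#' Periodic Voronoi tessellation of a population
#'
#' Voronoi diagram of the cell centres on the torus, built by half-plane
#' clipping against the 3x3 periodic images (exact on the torus). The
#' per-cell free area is `A_free,i = A_i - pi R_i^2`; it is negative when
#' neighbours interpenetrate enough that the Voronoi cell is smaller than
#' the disk itself. Areas partition the box: `sum(A_i) = L^2`.
#'
#' Optionally a radius-weighted Laguerre (power) tessellation can be used
#' for sensitivity analysis (`laguerre = TRUE`, weights R_i^2).
#'
#' @param pop a [cell_population()].
#' @param laguerre use the power diagram instead of the plain Voronoi?
#' @return object of class `voronoi_result`: data.frame with `cell`,
#'   `radius`, `area`, `a_free`; attributes `box_length`, `phi`.
#' @export
periodic_voronoi <- function(pop, laguerre = FALSE) {
  n <- length(pop$radii)
  if (n < 3) stop("need at least 3 cells")
  w <- if (laguerre) pop$radii^2 else NULL
  areas <- voronoi_areas_cpp(pop$positions, pop$box_length, w)
  out <- data.frame(cell = seq_len(n), radius = pop$radii, area = areas,
                    a_free = areas - pi * pop$radii^2)
  attr(out, "box_length") <- pop$box_length
  attr(out, "phi") <- packing_fraction(pop)
  class(out) <- c("voronoi_result", "data.frame")
  out
}

#' Voronoi results for a set of trajectory frames
#'
#' @param traj a `trajectory`.
#' @param frames frame indices; default a spread of at most `max_frames`
#'   evenly spaced production frames.
#' @param max_frames cap on the number of frames tessellated.
#' @param ... passed to [periodic_voronoi()].
#' @return list of `voronoi_result`, one per frame.
#' @export
voronoi_frames <- function(traj, frames = NULL, max_frames = 50, ...) {
  if (is.null(frames)) {
    FF <- n_frames(traj)
    frames <- unique(round(seq(1, FF, length.out = min(max_frames, FF))))
  }
  lapply(frames, function(f)
    periodic_voronoi(frame_population(traj, f), ...))
}

#' Free-area fraction phi_free
#'
#' Frame-averaged sum of the positive per-cell free areas divided by the
#' box area: only cells whose Voronoi cell exceeds their own disk area
#' contribute. This is the net void space actually available for motion;
#' in the jammed regime it exceeds the naive `1 - phi` because overlapping
#' cells release space to their neighbourhood.
#'
#' @param results a `voronoi_result` or list of them (frames).
#' @return phi_free (dimensionless).
#' @export
free_area_fraction <- function(results) {
  if (inherits(results, "voronoi_result")) results <- list(results)
  per_frame <- vapply(results, function(v) {
    L2 <- attr(v, "box_length")^2
    sum(v$a_free[v$a_free > 0]) / L2
  }, 0)
  mean(per_frame)
}

#' Distribution of per-cell free areas
#'
#' Normalized histogram of `A_free` over all cells and frames, including
#' the negative side (interpenetration), with summary statistics.
#'
#' @param results a `voronoi_result` or list of them.
#' @param breaks passed to [hist()]; default Freedman-Diaconis.
#' @return list with `a_free` (bin centres), `p` (density), `mode` (bin
#'   centre of the density maximum), `mean`, `negative_fraction` (share
#'   of cells with A_free < 0).
#' @export
free_area_distribution <- function(results, breaks = "FD") {
  if (inherits(results, "voronoi_result")) results <- list(results)
  af <- unlist(lapply(results, function(v) v$a_free))
  h <- graphics::hist(af, breaks = breaks, plot = FALSE)
  list(a_free = h$mids, p = h$density, mode = h$mids[which.max(h$density)],
       mean = mean(af), negative_fraction = mean(af < 0))
}

#' Mean Voronoi cell area per packing fraction
#'
#' @param trajs list of `trajectory` objects.
#' @param ... passed to [voronoi_frames()].
#' @return data.frame with `phi`, `mean_area`, `sd`, `n` (replicates).
#' @export
mean_voronoi_area_vs_phi <- function(trajs, ...) {
  phi <- vapply(trajs, function(tr) tr$params$target_phi, 0)
  ma <- vapply(trajs, function(tr) {
    mean(vapply(voronoi_frames(tr, ...), function(v) mean(v$area), 0))
  }, 0)
  agg <- split(ma, phi)
  data.frame(phi = as.numeric(names(agg)),
             mean_area = vapply(agg, mean, 0),
             sd = vapply(agg, function(v) if (length(v) > 1) sd(v) else 0, 0),
             n = vapply(agg, length, 0L), row.names = NULL)
}
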