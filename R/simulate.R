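#' Simulation parameters
#'
#' Bundles the mechanical constants, timestep and run lengths of the model.
#' Defaults are the reference parameter set: E = 1e-3 MPa, nu = 0.5,
#' gamma0 = 0.1 kg/(um s), mu = 0.045 (active-noise amplitude), dt = 10 s.
#'
#' The friction on cell i is gamma0 * R_i, so smaller cells are more
#' mobile. The active noise enters the update as `mu * sqrt(dt) * N(0,1)`
#' per coordinate, the discretization consistent with delta-correlated
#' noise (mu therefore carries units um/sqrt(s); its numeric value follows
#' the reference set).
#'
#' @param n_cells number of cells N.
#' @param target_phi packing fraction; fixes the box once radii are drawn.
#' @param elastic_modulus_E elastic modulus, MPa.
#' @param poisson_nu Poisson ratio.
#' @param gamma0 friction prefactor, kg/(um s).
#' @param mu_activity self-propulsion (active noise) amplitude.
#' @param dt timestep, s.
#' @param box_length_L optional explicit box side, um; derived from the
#'   radii and `target_phi` when `NULL`.
#' @param rng_seed integer seed; the full run is reproducible from it.
#' @param n_steps_init zero-noise relaxation steps used to remove the
#'   overlaps of the random initial placement (radii ramped from 50%).
#' @param n_steps_equil equilibration steps (noise on, frames discarded).
#' @param n_steps_prod production steps (frames recorded).
#' @param save_every record a frame every this many production steps.
#' @param stress_every record the off-diagonal stress every this many
#'   production steps (independent of frame saving; stress is a scalar,
#'   so a fine sampling is cheap and resolves the fast initial decay of
#'   its autocorrelation).
#' @param max_step_disp per-step displacement bound, um; exceeding it
#'   signals an unstable timestep. Default: the largest radius.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_cells = 500,
                       target_phi = 0.93,
                       elastic_modulus_E = 1e-3,
                       poisson_nu = 0.5,
                       gamma0 = 0.1,
                       mu_activity = 0.045,
                       dt = 10,
                       box_length_L = NULL,
                       rng_seed = 1L,
                       n_steps_init = 3000,
                       n_steps_equil = 20000,
                       n_steps_prod = 50000,
                       save_every = 100,
                       stress_every = 1,
                       max_step_disp = NULL) {
  stopifnot(n_cells >= 1, dt > 0, elastic_modulus_E > 0, gamma0 > 0,
            mu_activity >= 0, n_steps_init >= 0, n_steps_equil >= 0,
            n_steps_prod >= 0, save_every >= 1)
  if (target_phi <= 0 || target_phi >= 1)
    stop("target_phi must be in (0, 1)")
  p <- list(n_cells = as.integer(n_cells), target_phi = target_phi,
            elastic_modulus_E = elastic_modulus_E, poisson_nu = poisson_nu,
            gamma0 = gamma0, mu_activity = mu_activity, dt = dt,
            box_length_L = box_length_L, rng_seed = as.integer(rng_seed),
            n_steps_init = as.integer(n_steps_init),
            n_steps_equil = as.integer(n_steps_equil),
            n_steps_prod = as.integer(n_steps_prod),
            save_every = as.integer(save_every),
            stress_every = as.integer(max(1, stress_every)),
            max_step_disp = max_step_disp)
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params: N =", x$n_cells, " phi =", x$target_phi,
      " dt =", x$dt, "s  mu =", x$mu_activity, "\n")
  cat("  steps: init", x$n_steps_init, "| equil", x$n_steps_equil,
      "| prod", x$n_steps_prod, "(save every", x$save_every, ")\n")
  invisible(x)
}

#' Advance a population by explicit Euler-Maruyama steps
#'
#' Overdamped update
#' `dr_i = F_i / (gamma0 R_i) * dt + mu * sqrt(dt) * xi_i`
#' with standard bivariate normal `xi_i`, followed by a periodic wrap.
#' Uses R's global RNG stream, so results are deterministic after
#' `set.seed()`. A per-step displacement exceeding `params$max_step_disp`
#' raises an error (unstable `dt`).
#'
#' @param pop a [cell_population()].
#' @param params a [sim_params()].
#' @param n_steps number of steps to take.
#' @return the updated [cell_population()]; unwrapped positions are
#'   carried in attribute `"unwrapped"`.
#' @export
step <- function(pop, params, n_steps = 1) {
  upos <- attr(pop, "unwrapped")
  if (is.null(upos)) upos <- pop$positions
  md <- if (is.null(params$max_step_disp)) max(pop$radii) else params$max_step_disp
  res <- simulate_cpp(pop$positions, pop$radii, pop$box_length,
                      params$elastic_modulus_E, params$poisson_nu,
                      params$gamma0, params$mu_activity, params$dt,
                      as.integer(n_steps), 0L, md)
  # carry unwrapped displacements accumulated in the C++ state
  dr <- res$final_unwrapped - pop$positions
  out <- pop
  out$positions <- res$final_wrapped
  attr(out, "unwrapped") <- upos + dr
  out
}

#' Run a full simulation
#'
#' Pipeline: draw radii from `spec`, fix the box from `target_phi`, place
#' cells at random, remove initial overlaps by a zero-noise relaxation with
#' the radii ramped from 50% to 100%, equilibrate with noise for
#' `n_steps_equil`, then record a frame (wrapped + unwrapped positions and
#' the off-diagonal virial stress) every `save_every` steps for
#' `n_steps_prod` steps. Fully reproducible from `params$rng_seed`.
#'
#' @param params a [sim_params()].
#' @param spec a [radius_spec()]; ignored when `radii` is given.
#' @param radii optional explicit radii (bypasses sampling).
#' @param positions optional initial positions (bypasses random placement
#'   and the relaxation stage).
#' @return an object of class `trajectory`: list with `times` (s),
#'   `pos_wrapped` and `pos_unwrapped` (N x 2 x frames arrays),
#'   `stress_xy` (per-frame off-diagonal stress), `radii`, `box_length`,
#'   `params`.
#' @export
run_simulation <- function(params, spec = radius_spec(), radii = NULL,
                           positions = NULL) {
  set.seed(params$rng_seed)
  if (is.null(radii)) radii <- sample_radii(spec, params$n_cells)
  L <- params$box_length_L
  if (is.null(L)) L <- box_length_for_phi(radii, params$target_phi)
  if (L < 2 * max(radii))
    stop("box too small: L must be at least twice the largest radius")
  md <- if (is.null(params$max_step_disp)) max(radii) else params$max_step_disp

  if (is.null(positions)) {
    pos <- cbind(runif(length(radii), 0, L), runif(length(radii), 0, L))
    if (params$n_steps_init > 0)
      pos <- relax_cpp(pos, radii, L, params$elastic_modulus_E,
                       params$poisson_nu, params$gamma0, params$dt,
                       params$n_steps_init,
                       as.integer(params$n_steps_init / 2), 0.5,
                       0.25 * min(radii))
  } else {
    pos <- as.matrix(positions) %% L
  }

  if (params$n_steps_equil > 0) {
    eq <- simulate_cpp(pos, radii, L, params$elastic_modulus_E,
                       params$poisson_nu, params$gamma0,
                       params$mu_activity, params$dt,
                       params$n_steps_equil, 0L, md)
    pos <- eq$final_wrapped
  }

  res <- simulate_cpp(pos, radii, L, params$elastic_modulus_E,
                      params$poisson_nu, params$gamma0, params$mu_activity,
                      params$dt, params$n_steps_prod, params$save_every, md,
                      0, params$stress_every)
  structure(list(times = res$times, pos_wrapped = res$pos_wrapped,
                 pos_unwrapped = res$pos_unwrapped,
                 stress_xy = res$stress_xy,
                 stress_dt = params$stress_every * params$dt,
                 radii = radii, box_length = L,
                 params = params),
            class = "trajectory")
}

#' Number of stored frames
#' @param traj a `trajectory`.
#' @return frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame as a population
#' @param traj a `trajectory`.
#' @param frame frame index (1-based).
#' @param wrapped use wrapped (primary-image) coordinates?
#' @return a [cell_population()].
#' @export
frame_population <- function(traj, frame, wrapped = TRUE) {
  a <- if (wrapped) traj$pos_wrapped else traj$pos_unwrapped
  cell_population(a[, , frame] %% traj$box_length, traj$radii,
                  traj$box_length)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$radii), "cells,", n_frames(x), "frames,",
      "t in [", min(x$times), ",", max(x$times), "] s\n")
  cat("  box L =", signif(x$box_length, 6), "um, phi =",
      signif(sum(pi * x$radii^2) / x$box_length^2, 4), "\n")
  invisible(x)
}
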