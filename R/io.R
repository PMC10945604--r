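#' Save / load a trajectory
#'
#' Trajectories are persisted as a single hierarchical serialized container
#' per run (RDS), holding metadata, radii, frame times, wrapped and
#' unwrapped positions and the per-frame stress. Use
#' [write_trajectory_csv()] for a plain-text export.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @return `path`, invisibly (`save_trajectory`); the `trajectory`
#'   (`load_trajectory`).
#' @export
save_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) {
  traj <- readRDS(path)
  if (!inherits(traj, "trajectory")) stop("not a trajectory file")
  traj
}

#' Export a trajectory as tidy CSV
#'
#' One row per cell per frame: `frame, time_s, cell_id, x_um, y_um,
#' radius_um` (wrapped coordinates).
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @param frames frame indices (default all).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  N <- length(traj$radii)
  df <- do.call(rbind, lapply(frames, function(f)
    data.frame(frame = f, time_s = traj$times[f], cell_id = seq_len(N),
               x_um = traj$pos_wrapped[, 1, f],
               y_um = traj$pos_wrapped[, 2, f],
               radius_um = traj$radii)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read simulation settings from a config file
#'
#' Flat key-value YAML whose keys mirror [sim_params()] and
#' [radius_spec()] arguments (`radius_` prefix for the latter, e.g.
#' `radius_kind`, `radius_mean_radius`). Unknown keys are an error.
#'
#' @param path YAML file.
#' @return list with elements `params` ([sim_params()]) and `spec`
#'   ([radius_spec()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  is_rad <- grepl("^radius_", names(cfg))
  rad <- cfg[is_rad]
  names(rad) <- sub("^radius_", "", names(rad))
  sim <- cfg[!is_rad]
  ok_sim <- names(formals(sim_params))
  ok_rad <- names(formals(radius_spec))
  bad <- c(setdiff(names(sim), ok_sim), setdiff(names(rad), ok_rad))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  list(params = do.call(sim_params, sim), spec = do.call(radius_spec, rad))
}

#' Run a sweep of replicate simulations over packing fractions
#'
#' Launches `replicates` independent simulations at each phi with child
#' seeds derived from the master seed by a counter scheme
#' (`seed_i = master_seed + 1000 * i`), and returns the runs together with
#' a manifest recording phi, seed and run index for each trajectory. A
#' failing run is recorded in the manifest (`ok = FALSE`) without aborting
#' the sweep.
#'
#' @param phis packing fractions.
#' @param replicates runs per phi.
#' @param base_params a [sim_params()] template (`target_phi`/`rng_seed`
#'   are overridden per run).
#' @param spec a [radius_spec()].
#' @param master_seed master integer seed.
#' @return list with `runs` (list of `trajectory`) and `manifest`
#'   (data.frame: run, phi, seed, ok, error).
#' @export
sweep_phi <- function(phis, replicates, base_params, spec = radius_spec(),
                      master_seed = 1L) {
  runs <- list()
  man <- data.frame()
  k <- 0L
  for (phi in phis) for (r in seq_len(replicates)) {
    k <- k + 1L
    seed <- (master_seed + 1000L * k) %% .Machine$integer.max
    p <- base_params
    p$target_phi <- phi
    p$rng_seed <- as.integer(seed)
    res <- tryCatch(run_simulation(p, spec), error = function(e) e)
    ok <- !inherits(res, "error")
    man <- rbind(man, data.frame(
      run = k, phi = phi, seed = seed, ok = ok,
      error = if (ok) NA_character_ else conditionMessage(res)))
    if (ok) runs[[k]] <- res
  }
  list(runs = runs[!vapply(runs, is.null, TRUE)], manifest = man)
}
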