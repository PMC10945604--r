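# Small shared simulations, memoised across test files. Desk-scale runs
# (N = 150, short production) used for ordering/monotonicity checks.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(phi, n_cells = 150, n_steps_equil = 30000,
                       n_steps_prod = 50000, save_every = 50, seed = NULL) {
  if (is.null(seed)) seed <- 20000 + round(1000 * phi)
  key <- paste(phi, n_cells, n_steps_equil, n_steps_prod, save_every, seed,
               sep = "_")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  p <- sim_params(n_cells = n_cells, target_phi = phi, n_steps_init = 1500,
                  n_steps_equil = n_steps_equil, n_steps_prod = n_steps_prod,
                  save_every = save_every, rng_seed = seed)
  .run_cache[[key]] <- run_simulation(p)
  .run_cache[[key]]
}
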