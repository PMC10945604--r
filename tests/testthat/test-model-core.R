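test_that("pair_overlap follows the minimum-image definition", {
  pop <- cell_population(rbind(c(10, 10), c(40, 10)), c(8.5, 8.5), 100)
  expect_equal(pair_overlap(pop, 1, 2), 0)

  pop <- make_fixture("pair_h1")  # centres 16 um apart, R = 8.5 each
  expect_equal(pair_overlap(pop, 1, 2), 1)
  expect_equal(pair_overlap(pop, 2, 1), 1)
  expect_error(pair_overlap(pop, 1, 1), "differ")

  # straddling the periodic boundary: wrapped distance 16, raw L - 16
  L <- 100
  popb <- cell_population(rbind(c(2, 50), c(L - 14, 50)), c(8.5, 8.5), L)
  d9 <- image_distance(popb$positions[1, ], popb$positions[2, ], L)
  expect_equal(d9, 16)
  expect_equal(pair_overlap(popb, 1, 2), 8.5 + 8.5 - d9)
})

test_that("Hertz force magnitude follows the h^{3/2} contact law", {
  expect_equal(hertz_force_magnitude(0, 8.5, 8.5), 0)
  f1 <- hertz_force_magnitude(1, 8.5, 8.5)
  expect_equal(hertz_force_magnitude(2, 8.5, 8.5) / f1, 2^1.5)
  # frozen value from a one-off independent evaluation of the contact law
  # at h = 1 um, R_i = R_j = 8.5 um, E = 1e-3 MPa, nu = 0.5
  expect_equal(f1, 1.832491389163e-3, tolerance = 1e-9)
  expect_equal(hertz_force_magnitude(1.3, 4, 12),
               hertz_force_magnitude(1.3, 12, 4))
  expect_error(hertz_force_magnitude(-0.1, 8.5, 8.5), "non-negative")
  h <- seq(0, 3, by = 0.1)
  expect_true(all(diff(hertz_force_magnitude(h, 8.5, 8.5)) > 0))
})

test_that("total forces are pairwise antisymmetric and match the O(N^2) oracle", {
  params <- sim_params(n_cells = 10, target_phi = 0.9)

  # non-overlapping lattice: all forces vanish
  lat <- lattice_population(4, target_phi = 0.5)
  expect_true(all(total_forces(lat, params) == 0))

  # symmetric two-cell overlap: equal and opposite along the centre line
  pop2 <- make_fixture("pair_h1")
  F2 <- total_forces(pop2, params)
  expect_equal(F2[1, ], -F2[2, ])
  expect_equal(F2[1, 2], 0)           # centres share y
  expect_lt(F2[1, 1], 0)              # repulsion pushes cell 1 left

  # random overlapping configurations vs brute force, incl. net force zero
  set.seed(42)
  for (rep in 1:3) {
    radii <- sample_radii(radius_spec(), 30)
    pop <- random_population(radii, target_phi = 0.9)
    F <- total_forces(pop, params)
    expect_equal(F, brute_forces(pop, params), tolerance = 1e-12)
    expect_equal(colSums(F), c(0, 0), tolerance = 1e-12)
  }
})

test_that("forces and stress are invariant under lattice translations", {
  params <- sim_params()
  set.seed(7)
  radii <- sample_radii(radius_spec(), 25)
  pop <- random_population(radii, target_phi = 0.92)
  F0 <- total_forces(pop, params)
  s0 <- virial_stress(pop, params)
  shifted <- cell_population(pop$positions + c(pop$box_length, 2 * pop$box_length),
                             radii, pop$box_length)
  expect_equal(total_forces(shifted, params), F0, tolerance = 1e-9)
  expect_equal(virial_stress(shifted, params)$pxy, s0$pxy, tolerance = 1e-9)
})

test_that("virial stress matches the one-pair closed form and is symmetric", {
  params <- sim_params()
  lat <- lattice_population(3, target_phi = 0.4)
  s <- virial_stress(lat, params)
  expect_equal(s$pxy, 0)
  expect_equal(s$pyx, 0)

  # one tilted overlapping pair: P_xy = r_x f_y / L^2
  L <- 80
  d <- c(12, 9)                       # |d| = 15 < 17 -> h = 2
  pop <- cell_population(rbind(c(30, 30), c(30, 30) + d), c(8.5, 8.5), L)
  h <- 17 - 15
  fm <- hertz_force_magnitude(h, 8.5, 8.5, params$elastic_modulus_E,
                              params$poisson_nu)
  # force on cell 2 points along +d
  expect_equal(virial_stress(pop, params)$pxy,
               d[1] * (fm * d[2] / 15) / L^2, tolerance = 1e-12)

  set.seed(3)
  pop <- random_population(sample_radii(radius_spec(), 40), target_phi = 0.93)
  s <- virial_stress(pop, params)
  expect_equal(s$pxy, s$pyx, tolerance = 1e-14)
})

test_that("step handles drift, mobility ordering and noise-free limits", {
  params <- sim_params(mu_activity = 0, dt = 10)
  lat <- lattice_population(3, target_phi = 0.4)
  expect_equal(step(lat, params)$positions, unname(lat$positions))

  # two overlapping cells of different size separate; smaller moves farther
  pop <- cell_population(rbind(c(40, 50), c(52, 50)), c(5, 10), 100)
  out <- step(pop, params)
  dx <- out$positions - pop$positions
  expect_lt(dx[1, 1], 0)
  expect_gt(dx[2, 1], 0)
  expect_gt(abs(dx[1, 1]), abs(dx[2, 1]))
  expect_equal(abs(dx[1, 1]) / abs(dx[2, 1]), 10 / 5, tolerance = 1e-9)
})

test_that("free cells diffuse with per-component variance mu^2 t", {
  # 10^4 particles, 10^3 steps, no interactions
  n <- 1e4
  params <- sim_params(n_cells = n, target_phi = 0.01, mu_activity = 0.045,
                       dt = 10, max_step_disp = 10)
  radii <- rep(1, n)
  L <- box_length_for_phi(radii, 0.01)
  pop <- cell_population(cbind(runif(n, 0, L), runif(n, 0, L)), radii, L)
  set.seed(123)
  out <- step(pop, params, n_steps = 1000)
  dr <- attr(out, "unwrapped") - pop$positions
  t_tot <- 1000 * params$dt
  v <- c(var(dr[, 1]), var(dr[, 2]))
  expect_equal(v, rep(params$mu_activity^2 * t_tot, 2), tolerance = 0.05)
})

test_that("unstable timesteps are reported as errors", {
  pop <- cell_population(rbind(c(40, 50), c(41, 50)), c(8.5, 8.5), 100)
  params <- sim_params(mu_activity = 0, elastic_modulus_E = 10,
                       max_step_disp = 0.5)
  expect_error(step(pop, params), "displacement exceeded")
})

test_that("packing fraction is exact", {
  pop <- cell_population(matrix(c(1, 1), 1), 1, 2)
  expect_equal(packing_fraction(pop), pi / 4)
  pop2 <- cell_population(matrix(c(1, 1), 1), 1, 4)
  expect_equal(packing_fraction(pop2), pi / 16)
  set.seed(1)
  radii <- sample_radii(radius_spec(), 50)
  pop3 <- random_population(radii, target_phi = 0.93)
  expect_equal(packing_fraction(pop3), 0.93, tolerance = 1e-12)
})

test_that("run_simulation is reproducible and honours zero production", {
  p <- sim_params(n_cells = 20, target_phi = 0.8, n_steps_init = 200,
                  n_steps_equil = 100, n_steps_prod = 0, rng_seed = 4)
  tr <- run_simulation(p)
  expect_equal(n_frames(tr), 1)
  expect_equal(dim(tr$pos_wrapped), c(20, 2, 1))

  p2 <- sim_params(n_cells = 20, target_phi = 0.8, n_steps_init = 200,
                   n_steps_equil = 100, n_steps_prod = 500, save_every = 50,
                   rng_seed = 9)
  tr1 <- run_simulation(p2)
  tr2 <- run_simulation(p2)
  expect_identical(tr1$pos_wrapped, tr2$pos_wrapped)
  expect_identical(tr1$stress_xy, tr2$stress_xy)
  expect_equal(diff(tr1$times), rep(50 * 10, n_frames(tr1) - 1))
})

test_that("noise-free relaxation never increases the total overlap", {
  set.seed(8)
  radii <- sample_radii(radius_spec(), 30)
  pop <- random_population(radii, target_phi = 0.85)
  params <- sim_params(mu_activity = 0, max_step_disp = 20)
  total_h <- function(pp) {
    s <- 0
    for (i in 1:29) for (j in (i + 1):30) s <- s + pair_overlap(pp, i, j)
    s
  }
  hs <- numeric(12)
  cur <- pop
  for (k in 1:12) {
    cur <- step(cur, params, n_steps = 5)
    hs[k] <- total_h(cur)
  }
  expect_true(all(diff(c(total_h(pop), hs)) <= 1e-9))
})

test_that("a moderately packed system relaxes below 1/e within the run", {
  tr <- cached_run(0.70, n_steps_equil = 10000, n_steps_prod = 40000,
                   save_every = 20)
  g <- pair_correlation(tr, bin_width = 0.5,
                        frames = round(seq(1, n_frames(tr), length.out = 40)))
  q <- 2 * pi / first_peak_position(g)
  tau <- relaxation_time(self_intermediate_scattering(tr, q))
  expect_true(attr(tau, "relaxed"))
  expect_lt(tau, 1e5)
})
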