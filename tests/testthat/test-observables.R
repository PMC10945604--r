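make_static_traj <- function(pos, L, frames = 5) {
  N <- nrow(pos)
  upos <- array(rep(pos, frames), c(N, 2, frames))
  structure(list(times = (0:(frames - 1)) * 10, pos_wrapped = upos %% L,
                 pos_unwrapped = upos, stress_xy = numeric(frames),
                 stress_dt = 10, radii = rep(1, N), box_length = L,
                 params = sim_params(n_cells = N, target_phi = 0.5,
                                     n_steps_prod = 0)),
            class = "trajectory")
}

test_that("g(r) is flat for ideal-gas configurations and obeys the sum rule", {
  set.seed(21)
  L <- 100; N <- 400
  pos <- cbind(runif(N, 0, L), runif(N, 0, L))
  tr <- make_static_traj(pos, L, frames = 1)
  tr$radii <- rep(1, N)
  g <- pair_correlation(tr, bin_width = 2)
  mid <- g$r > 10
  expect_lt(max(abs(g$g[mid] - 1)), 0.25)
  expect_lt(abs(mean(g$g[mid]) - 1), 0.05)

  # count-sum rule: rho * int g 2 pi r dr = expected neighbours in range
  rho <- N / L^2
  integral <- sum(g$g * 2 * pi * g$r * 2)
  expect_equal(rho * integral, (N - 1) * pi * (L / 2)^2 / L^2,
               tolerance = 0.05)
})

test_that("two fixed particles occupy a single correctly normalized bin", {
  L <- 60; d <- 13
  tr <- make_static_traj(rbind(c(10, 10), c(10 + d, 10)), L, frames = 7)
  g <- pair_correlation(tr, bin_width = 1)
  occupied <- which(g$g > 0)
  expect_length(occupied, 1)
  expect_equal(g$r[occupied], 13.5)
  # closed form: counts = 2 ordered pairs; g = 2 / (N rho shell)
  shell <- pi * (14^2 - 13^2)
  expect_equal(g$g[occupied], 2 / (2 * (2 / L^2) * shell))
})

test_that("first_peak_position finds spikes and refined maxima", {
  g <- structure(data.frame(r = seq(0.5, 19.5, 1), g = c(rep(0, 9), 5, rep(0, 10))),
                 class = c("radial_distribution", "data.frame"))
  expect_equal(first_peak_position(g, smooth = 0), 9.5)

  r <- seq(0.25, 30, 0.5)
  prof <- exp(-(r - 17.2)^2 / 8)
  g2 <- structure(data.frame(r = r, g = prof),
                  class = c("radial_distribution", "data.frame"))
  expect_lt(abs(first_peak_position(g2) - 17.2), 0.25)

  g3 <- structure(data.frame(r = r, g = r), class = class(g2))
  expect_error(first_peak_position(g3), "no qualifying peak")
})

test_that("Fs equals 1 at t = 0, stays at 1 for frozen cells, and is bounded", {
  L <- 100
  set.seed(5)
  tr <- make_static_traj(cbind(runif(30, 0, L), runif(30, 0, L)), L, 20)
  fs <- self_intermediate_scattering(tr, q = 0.4)
  expect_equal(fs$value[fs$lag == 0], 1)
  expect_true(all(fs$value == 1))

  trg <- gaussian_trajectory(seed = 2)
  fsg <- self_intermediate_scattering(trg, q = 0.4)
  expect_equal(fsg$value[1], 1)
  expect_true(all(abs(fsg$value) <= 1 + 1e-12))
  expect_error(self_intermediate_scattering(trg, q = -1), "positive")
})

test_that("Fs matches the Gaussian-displacement closed form", {
  sigma <- 0.8
  trg <- gaussian_trajectory(N = 128, frames = 800, sigma = sigma, seed = 3)
  q <- 0.45
  fs <- self_intermediate_scattering(trg, q, max_origins = 300)
  sel <- fs$lag > 0 & fs$lag <= 2000
  f_lag <- fs$lag[sel] / 10       # frames elapsed
  expected <- exp(-q^2 * sigma^2 * f_lag / 2)
  expect_lt(max(abs(fs$value[sel] - expected)), 0.03)
})

test_that("Fs uses unwrapped coordinates: free diffusion decays instead of plateauing", {
  trg <- gaussian_trajectory(N = 100, frames = 1500, sigma = 1.2, seed = 4,
                             L = 40)
  q <- 0.1
  fs <- self_intermediate_scattering(trg, q)
  expect_lt(min(fs$value), 0.05)
  # same data analysed on wrapped coordinates plateaus near the uniform
  # minimum-image level (~0.47 for q L = 4) instead of decaying
  trw <- trg
  trw$pos_unwrapped <- trg$pos_wrapped
  fsw <- self_intermediate_scattering(trw, q)
  # wrapped differences are triangular on (-L, L), giving a finite
  # plateau (~0.2 here) instead of full decay
  long <- fsw$lag > 5000
  expect_gt(mean(fsw$value[long]), 0.15)
})

test_that("relaxation_time inverts known decay laws and censors non-crossings", {
  t <- c(0, exp(seq(log(1), log(1e4), length.out = 80)))
  tau0 <- 120
  fs <- structure(data.frame(lag = t, value = exp(-t / tau0)),
                  class = c("correlation_series", "data.frame"))
  expect_equal(as.numeric(relaxation_time(fs)), tau0, tolerance = 0.01)

  # stretched exponential crosses 1/e at tau0 for any beta
  fss <- structure(data.frame(lag = t, value = exp(-(t / tau0)^0.5)),
                   class = class(fs))
  expect_equal(as.numeric(relaxation_time(fss)), tau0, tolerance = 0.01)

  # refinement invariance
  t2 <- c(0, exp(seq(log(1), log(1e4), length.out = 400)))
  fs2 <- structure(data.frame(lag = t2, value = exp(-t2 / tau0)),
                   class = class(fs))
  expect_equal(as.numeric(relaxation_time(fs2)),
               as.numeric(relaxation_time(fs)), tolerance = 0.005)

  flat <- structure(data.frame(lag = t, value = 0.5 + 0.4 * exp(-t / 50)),
                    class = class(fs))
  tau <- relaxation_time(flat)
  expect_true(is.na(tau))
  expect_false(attr(tau, "relaxed"))
})

test_that("per-cell relaxation times are consistent with the global estimator", {
  trg <- gaussian_trajectory(N = 80, frames = 900, sigma = 0.9, seed = 6)
  q <- 0.4
  pc <- per_cell_relaxation_times(trg, q)
  expect_equal(nrow(pc), 80)
  expect_true(all(pc$relaxed))
  # monodisperse free diffusers: narrow spread of tau
  expect_lt(sd(log(pc$tau)), 0.35)
  glob <- relaxation_time(self_intermediate_scattering(trg, q))
  expect_equal(median(pc$tau), as.numeric(glob), tolerance = 0.25)

  # one frozen cell among diffusers is censored, others are not
  trf <- trg
  trf$pos_unwrapped[1, , ] <- trf$pos_unwrapped[1, , 1]
  pcf <- per_cell_relaxation_times(trf, q)
  expect_false(pcf$relaxed[1])
  expect_true(all(pcf$relaxed[-1]))
})

test_that("log-tau histograms recover a generating Gaussian and count censoring", {
  set.seed(12)
  taus <- c(rlnorm(4000, meanlog = 8, sdlog = 0.7), rep(NA, 25))
  h <- log_tau_histogram(taus)
  expect_equal(h$n_censored, 25)
  expect_equal(h$n_used, 4000)
  expect_equal(sum(h$p * diff(h$log_tau)[1]), 1, tolerance = 0.01)
  fit <- fit_gaussian_log_tau(h$log_tau, h$p_scaled)
  expect_true(fit$converged)
  # generating Gaussian: P/Pmax = exp(-(x - 8)^2 / (2 * 0.7^2))
  expect_equal(fit$par[["c"]], 1 / (2 * 0.7^2), tolerance = 0.1)
  expect_equal(fit$par[["log_tau0"]], 8, tolerance = 0.02)
  expect_error(log_tau_histogram(c(1, 2, NA)), "at least 10")
})

test_that("waiting-time Fs collapses for stationary input and orders drifting input", {
  trg <- gaussian_trajectory(N = 90, frames = 1200, sigma = 0.9, seed = 7)
  q <- 0.4
  wt <- waiting_time_fs(trg, q, tau_w = c(0, 1000, 4000), origin_window = 500)
  taus <- vapply(wt, function(s) as.numeric(relaxation_time(s)), 0)
  expect_lt(diff(range(taus)) / mean(taus), 0.2)

  # non-stationary oracle: increments get smaller over time (slowing down)
  set.seed(8)
  N <- 90; FF <- 1200
  upos <- array(0, c(N, 2, FF))
  upos[, , 1] <- cbind(runif(N, 0, 200), runif(N, 0, 200))
  for (f in 2:FF) {
    sig <- 1.4 * exp(-f / 500)
    upos[, , f] <- upos[, , f - 1] + rnorm(2 * N, 0, sig)
  }
  trd <- trg
  trd$pos_unwrapped <- upos
  wtd <- waiting_time_fs(trd, q, tau_w = c(0, 2000, 6000), origin_window = 500)
  tausd <- vapply(wtd, function(s) as.numeric(relaxation_time(s)), 0)
  expect_true(all(diff(tausd) > 0))

  expect_error(waiting_time_fs(trg, q, tau_w = 2e5), "shorter")
})

test_that("overlap distributions handle empty, fixed and simulated cases", {
  lat <- lattice_population(4, target_phi = 0.5)
  trl <- make_static_traj(lat$positions, lat$box_length, 3)
  trl$radii <- lat$radii
  od <- overlap_distribution(trl)
  expect_equal(od$mean_h, 0)
  expect_equal(od$n_pairs, 0L)

  pop <- make_fixture("pair_h1")
  trp <- make_static_traj(pop$positions, pop$box_length, 4)
  trp$radii <- pop$radii
  odp <- overlap_distribution(trp, bin_width = 0.2)
  expect_equal(odp$mean_h, 1)
  expect_equal(odp$n_pairs, 4L)
  expect_equal(odp$h[which.max(odp$p)], 0.9, tolerance = 0.11)
})
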