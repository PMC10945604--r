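#' Small deterministic fixtures for testing and examples
#'
#' Named, fully deterministic configurations and synthetic series used to
#' exercise every analysis path against known answers:
#' \describe{
#'   \item{`pair_h1`}{two 8.5 um cells with overlap exactly 1 um.}
#'   \item{`lattice16`}{4 x 4 square lattice of equal cells, zero forces.}
#'   \item{`random10`}{10 polydisperse cells at random seed-fixed
#'     positions.}
#'   \item{`gauss_traj`}{synthetic trajectory whose per-frame increments
#'     are exact i.i.d. Gaussian displacements (free diffusion), so
#'     Fs(q,t) has the closed form `exp(-q^2 sigma^2 t' / 2)`.}
#'   \item{`acf_stretch_b06`}{stationary Gaussian stress series whose
#'     population autocorrelation is `C exp(-(t/tau)^0.6)` (circulant
#'     embedding), for exercising the Green-Kubo estimator.}
#' }
#'
#' @param name fixture name.
#' @param seed RNG seed for the stochastic fixtures.
#' @param n series/trajectory length for the synthetic fixtures.
#' @return a [cell_population()], `trajectory`, or list as documented.
#' @export
make_fixture <- function(name, seed = 42L, n = 2048L) {
  switch(name,
    pair_h1 = {
      L <- 100
      # d = R1 + R2 - 1 = 16 -> h = 1
      cell_population(rbind(c(40, 50), c(56, 50)), c(8.5, 8.5), L)
    },
    lattice16 = lattice_population(4, radius = 8.5, target_phi = 0.7),
    random10 = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      radii <- sample_radii(radius_spec(), 10)
      random_population(radii, target_phi = 0.5)
    },
    gauss_traj = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      N <- 64L
      FF <- as.integer(n)
      sigma <- 0.8   # per-frame per-component displacement sd, um
      L <- 200
      pos0 <- cbind(runif(N, 0, L), runif(N, 0, L))
      inc <- array(rnorm(N * 2 * (FF - 1), 0, sigma), c(N, 2, FF - 1))
      upos <- array(0, c(N, 2, FF))
      upos[, , 1] <- pos0
      for (f in 2:FF) upos[, , f] <- upos[, , f - 1] + inc[, , f - 1]
      structure(list(times = (0:(FF - 1)) * 10,
                     pos_wrapped = upos %% L, pos_unwrapped = upos,
                     stress_xy = numeric(FF),
                     radii = rep(8.5, N), box_length = L,
                     params = sim_params(n_cells = N, target_phi = 0.5,
                                         n_steps_prod = 0),
                     sigma = sigma),
                class = "trajectory")
    },
    acf_stretch_b06 = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      stretch_gaussian_series(n = as.integer(n), C = 1, tau = 300,
                              beta = 0.6, dt = 10)
    },
    stop("unknown fixture name: ", name))
}

#' Stationary Gaussian series with a stretched-exponential ACF
#'
#' Generates a zero-mean Gaussian process whose population autocovariance
#' is `C exp(-(|t|/tau)^beta)` by circulant embedding of the covariance
#' on a ring (eigenvalues clipped at zero; for these parameters the
#' clipped mass is negligible).
#'
#' @param n series length.
#' @param C variance at lag 0.
#' @param tau,beta stretched-exponential parameters.
#' @param dt sample spacing, s.
#' @return list with `t`, `x`, and the generating `C`, `tau`, `beta`,
#'   `dt`.
#' @export
stretch_gaussian_series <- function(n, C = 1, tau = 300, beta = 0.6,
                                    dt = 10) {
  m <- 2 * n
  lag <- c(0:(m / 2), (m / 2 - 1):1) * dt
  cv <- C * exp(-(lag / tau)^beta)
  ev <- Re(fft(cv))
  ev[ev < 0] <- 0
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  x <- Re(fft(sqrt(ev) * z)) / sqrt(m)
  list(t = (0:(n - 1)) * dt, x = x[1:n], C = C, tau = tau, beta = beta,
       dt = dt)
}
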