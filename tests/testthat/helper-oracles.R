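# Independent brute-force oracles used to cross-check the fast paths.

# all-pairs minimum-image Hertzian forces, pure R
brute_forces <- function(pop, params) {
  N <- length(pop$radii)
  L <- pop$box_length
  F <- matrix(0, N, 2)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    d <- pop$positions[i, ] - pop$positions[j, ]
    d <- d - L * round(d / L)
    dd <- sqrt(sum(d^2))
    h <- pop$radii[i] + pop$radii[j] - dd
    if (h > 0) {
      fm <- hertz_force_magnitude(h, pop$radii[i], pop$radii[j],
                                  params$elastic_modulus_E,
                                  params$poisson_nu)
      f <- fm * d / dd
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
  }
  F
}

# minimum-image distance via explicit search over the 9 periodic images
image_distance <- function(p1, p2, L) {
  best <- Inf
  for (gx in -1:1) for (gy in -1:1) {
    v <- p2 + c(gx, gy) * L - p1
    best <- min(best, sqrt(sum(v^2)))
  }
  best
}

# per-point periodic Voronoi area by half-plane intersection against all
# 9N - 1 images (no pruning): independent geometric construction
voronoi_area_oracle <- function(pos, L, i) {
  poly <- list(c(-L / 2, -L / 2), c(L / 2, -L / 2),
               c(L / 2, L / 2), c(-L / 2, L / 2))
  for (j in seq_len(nrow(pos))) for (gx in -1:1) for (gy in -1:1) {
    if (j == i && gx == 0 && gy == 0) next
    v <- c(pos[j, 1] + gx * L - pos[i, 1], pos[j, 2] + gy * L - pos[i, 2])
    d <- sqrt(sum(v^2)); u <- v / d; cc <- d / 2
    out <- list(); n <- length(poly)
    if (n == 0) break
    for (k in seq_len(n)) {
      a <- poly[[k]]; b <- poly[[k %% n + 1]]
      da <- sum(a * u) - cc; db <- sum(b * u) - cc
      if (da <= 0) out[[length(out) + 1]] <- a
      if ((da < 0 && db > 0) || (da > 0 && db < 0))
        out[[length(out) + 1]] <- a + da / (da - db) * (b - a)
    }
    poly <- out
  }
  if (length(poly) < 3) return(0)
  m <- do.call(rbind, poly); n <- nrow(m)
  abs(sum(m[, 1] * m[c(2:n, 1), 2] - m[c(2:n, 1), 1] * m[, 2])) / 2
}

# synthetic trajectory with prescribed i.i.d. Gaussian frame increments
gaussian_trajectory <- function(N = 64, frames = 512, sigma = 0.8,
                                dt_frame = 10, L = 200, seed = 1) {
  set.seed(seed)
  upos <- array(0, c(N, 2, frames))
  upos[, , 1] <- cbind(runif(N, 0, L), runif(N, 0, L))
  for (f in 2:frames)
    upos[, , f] <- upos[, , f - 1] + rnorm(2 * N, 0, sigma)
  structure(list(times = (0:(frames - 1)) * dt_frame,
                 pos_wrapped = upos %% L, pos_unwrapped = upos,
                 stress_xy = numeric(frames), stress_dt = dt_frame,
                 radii = rep(8.5, N), box_length = L,
                 params = sim_params(n_cells = N, target_phi = 0.5,
                                     n_steps_prod = 0)),
            class = "trajectory")
}
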