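#' Stress autocorrelation function
#'
#' Time-origin-averaged autocorrelation of the off-diagonal virial stress,
#' summed over the (mu, nu) off-diagonal components. Since P_xy = P_yx for
#' central pairwise forces, the sum is exactly twice the xy term:
#' `C(t) = 2 <P_xy(t) P_xy(0)>`. All available origins enter (computed via
#' FFT). The normalized form C(t)/C(0) is returned alongside.
#'
#' @param traj a `trajectory` (per-frame stress stored), or a numeric
#'   vector of P_xy samples via `stress`.
#' @param stress optional explicit stress series (overrides `traj`).
#' @param dt frame spacing in seconds (required with `stress`).
#' @return object of class `correlation_series`: data.frame with `lag`
#'   (s), `value` (summed ACF), `normalized`, `n_origins`.
#' @export
stress_autocorrelation <- function(traj = NULL, stress = NULL, dt = NULL) {
  if (is.null(stress)) {
    stress <- traj$stress_xy
    dt <- if (!is.null(traj$stress_dt)) traj$stress_dt else
      diff(traj$times[1:2])
  }
  n <- length(stress)
  if (n < 2) stop("need at least 2 stress samples")
  # raw (non-centred) autocovariance over all origins, via zero-padded FFT
  m <- nextn(2 * n)
  f <- fft(c(stress, rep(0, m - n)))
  cnt <- n:1  # origins contributing to each lag
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[1:n] / m / cnt
  val <- 2 * ac
  out <- data.frame(lag = (0:(n - 1)) * dt, value = val,
                    normalized = val / val[1], n_origins = cnt)
  class(out) <- c("correlation_series", "data.frame")
  out
}

#' Cubic spline smoothing of the short-time ACF
#'
#' Interpolates the short-time part of the stress ACF with a cubic
#' interpolating spline (continuous value, first and second derivative at
#' the knots; Forsythe-Malcolm-Moler end conditions, which reproduce cubic
#' polynomials exactly) and resamples it on an evenly spaced grid.
#'
#' @param acf a `correlation_series`.
#' @param t_end end of the short-time window, s.
#' @param dt_grid resampling spacing, s (default 10).
#' @return data.frame with `lag`, `value` on the uniform grid.
#' @export
smooth_short_time <- function(acf, t_end, dt_grid = 10) {
  sel <- acf$lag <= t_end
  t <- acf$lag[sel]; y <- acf$value[sel]
  if (any(diff(t) <= 0)) stop("lag times must be strictly increasing")
  if (length(t) < 4) stop("need at least 4 points before t_end")
  grid <- seq(0, t_end, by = dt_grid)
  s <- spline(t, y, xout = grid, method = "fmm")
  data.frame(lag = s$x, value = s$y)
}

#' Stretched-exponential fit of the long-time ACF decay
#'
#' Fits `C_s * exp(-(t / tau_eta)^beta)` to the ACF at lags >= `t_start`
#' by nonlinear least squares, with beta constrained to (0, 2].
#'
#' @param acf a `correlation_series`.
#' @param t_start start of the long-time window, s.
#' @return a `fit_result` (see [fit_stretched_exponential()]) with
#'   parameters `Cs`, `tau`, `beta`.
#' @export
fit_long_time <- function(acf, t_start) {
  sel <- acf$lag >= t_start
  fit_stretched_exponential(acf$lag[sel], acf$value[sel])
}

# analytic tail of the stretched exponential from T to infinity:
# int_T^inf C exp(-(t/tau)^b) dt = C tau / b * Gamma(1/b, (T/tau)^b)
stretch_tail <- function(Cs, tau, beta, T) {
  x <- (T / tau)^beta
  Cs * tau / beta * gamma(1 / beta) * stats::pgamma(x, 1 / beta,
                                                    lower.tail = FALSE)
}

# default splice point: flattest point (smallest log-slope) of the
# smoothed normalized ACF inside the band norm in [lo, hi] -- i.e. the
# plateau between the fast initial decay and the noisy long-time tail
auto_splice <- function(acf, lo = 0.03, hi = 0.5, min_tail = 12) {
  y <- acf$normalized
  t <- acf$lag
  n <- length(y)
  w <- max(3, min(31, round(n / 100)))
  if (w %% 2 == 0) w <- w + 1
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  cand <- which(ys < hi & ys > lo)
  cand <- cand[cand > 1 & cand <= n - min_tail]
  # stay within the physical decay: drop candidates past the first time
  # the smoothed ACF reaches the noise floor
  first_lo <- which(ys < lo)[1]
  if (!is.na(first_lo)) cand <- cand[cand < first_lo]
  if (length(cand) < 3) {
    k <- which(ys < hi)[1]
    return(t[max(2, min(if (is.na(k)) 2 else k, n - min_tail))])
  }
  dlog <- abs(diff(log(pmax(ys, 1e-12)))) / diff(t)
  t[cand[which.min(dlog[pmin(cand, n - 1)])]]
}

#' Green-Kubo effective viscosity from a spliced ACF
#'
#' The effective shear viscosity is the time integral of the summed
#' off-diagonal stress autocorrelation. The noisy ACF is replaced by a
#' two-part smooth representation before integrating: a natural cubic
#' spline of the short-time decay on `[0, t1]` and the stretched
#' exponential fit `C_s exp(-(t/tau_eta)^beta)` beyond the splice point
#' `t1`. The integral is a trapezoidal sum on an evenly spaced grid plus
#' the closed-form tail of the stretched exponential
#' (`C tau Gamma(1/beta, (T/tau)^beta) / beta`), so truncation error is
#' analytically zero beyond the last grid point.
#'
#' @param acf a `correlation_series` from [stress_autocorrelation()].
#' @param t1 splice time, s, or `"auto"` (flattest point of the
#'   normalized log-ACF).
#' @param dt_grid integration grid spacing, s.
#' @param t_max end of the numerical grid, s; default 8 stretched times.
#' @param continuity_tol allowed relative mismatch of the two segments at
#'   `t1`.
#' @return list of class `viscosity_estimate`: `eta` (the integral),
#'   `t1`, `fit` (stretched-exponential `fit_result`), `spliced`
#'   (data.frame of the combined smooth ACF), `tail` (analytic tail
#'   contribution).
#' @export
green_kubo_viscosity <- function(acf, t1 = "auto", dt_grid = 10,
                                 t_max = NULL, continuity_tol = 0.25) {
  if (identical(t1, "auto")) t1 <- auto_splice(acf)
  fit <- fit_long_time(acf, t1)
  if (!fit$converged) stop("long-time stretched-exponential fit failed")
  p <- fit$par
  if (!all(is.finite(p)) || p[["tau"]] <= 0)
    stop("degenerate long-time fit (non-finite parameters)")
  short <- smooth_short_time(acf, t1, dt_grid)
  f_t1 <- p[["Cs"]] * exp(-(t1 / p[["tau"]])^p[["beta"]])
  s_t1 <- short$value[nrow(short)]
  scale0 <- abs(acf$value[1])
  if (abs(f_t1 - s_t1) > continuity_tol * scale0)
    stop(sprintf(
      "spliced ACF discontinuous at t1 = %g: spline %.4g vs fit %.4g",
      t1, s_t1, f_t1))
  if (is.null(t_max))
    t_max <- max(t1 + dt_grid,
                 min(8 * p[["tau"]], 50 * max(acf$lag)))
  tl <- seq(short$lag[nrow(short)], t_max, by = dt_grid)
  long <- data.frame(lag = tl,
                     value = p[["Cs"]] * exp(-(tl / p[["tau"]])^p[["beta"]]))
  spliced <- rbind(short[-nrow(short), ], long)
  eta_num <- sum(diff(spliced$lag) *
                 (head(spliced$value, -1) + tail(spliced$value, -1)) / 2)
  tail_an <- stretch_tail(p[["Cs"]], p[["tau"]], p[["beta"]], t_max)
  if (!is.finite(eta_num + tail_an))
    stop("Green-Kubo integral did not converge (degenerate tail fit)")
  structure(list(eta = eta_num + tail_an, t1 = t1, fit = fit,
                 spliced = spliced, tail = tail_an),
            class = "viscosity_estimate")
}

#' @export
print.viscosity_estimate <- function(x, ...) {
  p <- x$fit$par
  cat("Green-Kubo effective viscosity:", signif(x$eta, 5), "\n")
  cat("  splice t1 =", signif(x$t1, 4), "s; stretched exp: Cs =",
      signif(p[["Cs"]], 4), " tau =", signif(p[["tau"]], 4), "s  beta =",
      signif(p[["beta"]], 3), "\n")
  invisible(x)
}

#' Effective viscosity of a trajectory
#'
#' Convenience wrapper: stress ACF then spliced Green-Kubo integral.
#'
#' @param traj a `trajectory`.
#' @param ... passed to [green_kubo_viscosity()].
#' @return a `viscosity_estimate`.
#' @export
effective_viscosity <- function(traj, ...) {
  green_kubo_viscosity(stress_autocorrelation(traj), ...)
}

#' Replicate-averaged viscosity per packing fraction
#'
#' The ensemble average in the stress autocorrelation runs over time
#' origins *and* independent trajectories, so by default the per-replicate
#' ACFs at each phi are averaged first and a single spliced Green-Kubo
#' integral is taken of the pooled ACF (`method = "pooled"`); the quoted
#' spread is the standard deviation of the per-replicate integrals (which
#' are individually noisier). `method = "per_run"` instead averages the
#' per-replicate integrals directly. Replicates at one phi must share the
#' model parameters.
#'
#' @param trajs list of `trajectory` objects (replicates across phi).
#' @param method `"pooled"` (default) or `"per_run"`.
#' @param ... passed to [green_kubo_viscosity()].
#' @return data.frame with `phi`, `eta`, `sd`, `n` sorted by phi.
#' @export
viscosity_vs_phi <- function(trajs, method = c("pooled", "per_run"), ...) {
  method <- match.arg(method)
  phi <- vapply(trajs, function(tr) tr$params$target_phi, 0)
  out <- data.frame()
  for (ph in sort(unique(phi))) {
    grp <- trajs[phi == ph]
    key <- vapply(grp, function(tr)
      paste(tr$params$n_cells, tr$params$dt, tr$params$mu_activity,
            tr$params$elastic_modulus_E, tr$params$stress_every), "")
    if (length(unique(key)) > 1)
      stop("mixed simulation parameters among replicates at phi = ", ph)
    acfs <- lapply(grp, stress_autocorrelation)
    per_run <- vapply(acfs, function(a)
      tryCatch(green_kubo_viscosity(a, ...)$eta, error = function(e)
        NA_real_), 0)
    if (method == "pooled") {
      nmin <- min(vapply(acfs, nrow, 0L))
      vm <- rowMeans(vapply(acfs, function(a) a$value[1:nmin],
                            numeric(nmin)))
      pooled <- data.frame(lag = acfs[[1]]$lag[1:nmin], value = vm,
                           normalized = vm / vm[1],
                           n_origins = acfs[[1]]$n_origins[1:nmin])
      class(pooled) <- c("correlation_series", "data.frame")
      eta <- tryCatch(green_kubo_viscosity(pooled, ...)$eta,
                      error = function(e) mean(per_run, na.rm = TRUE))
    } else {
      eta <- mean(per_run, na.rm = TRUE)
    }
    out <- rbind(out, data.frame(
      phi = ph, eta = eta,
      sd = if (sum(is.finite(per_run)) > 1) sd(per_run, na.rm = TRUE) else 0,
      n = length(grp)))
  }
  out
}
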