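#' Pair correlation function g(r)
#'
#' Shell- and density-normalized histogram of all minimum-image pair
#' distances, averaged over frames:
#' `g(r) = <counts in [r, r+dr)> / (N rho * shell area)`, rho = N / L^2.
#' All cells enter regardless of radius.
#'
#' @param traj a `trajectory`.
#' @param bin_width histogram bin, um.
#' @param r_max upper distance limit, um; at most L/2 (default).
#' @param frames frame indices to average over (default: all).
#' @return object of class `radial_distribution`: data.frame with columns
#'   `r` (bin centres) and `g`, plus attributes `bin_width`, `n_frames`.
#' @export
pair_correlation <- function(traj, bin_width = 0.5, r_max = NULL,
                             frames = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  L <- traj$box_length
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2) stop("r_max must not exceed L/2")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  N <- length(traj$radii)
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  for (f in frames)
    counts <- counts + gr_counts_cpp(traj$pos_wrapped[, , f], L,
                                     bin_width, r_max)
  edges <- seq(0, nb * bin_width, by = bin_width)
  shell <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2)
  rho <- N / L^2
  g <- counts / (length(frames) * N * rho * shell)
  out <- data.frame(r = edges[-(nb + 1)] + bin_width / 2, g = g)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("radial_distribution", "data.frame")
  out
}

#' Position of the first peak of g(r)
#'
#' First interior local maximum whose height exceeds the configurable
#' prominence threshold (a fraction of the g-range above the minimum),
#' refined to sub-bin precision by a parabola through the three bins
#' around the maximum.
#'
#' @param g a `radial_distribution` from [pair_correlation()].
#' @param prominence minimum height above `min(g)` as a fraction of
#'   `diff(range(g))`.
#' @param smooth half-width (in bins) of a centred moving average applied
#'   before peak detection; `0` disables it.
#' @return peak position r_max, um.
#' @export
first_peak_position <- function(g, prominence = 0.05, smooth = 1) {
  y <- g$g; r <- g$r
  n <- length(y)
  if (n < 3) stop("too few bins")
  ys <- y
  if (smooth > 0) {
    # centered moving average to suppress single-bin noise bumps
    k <- 2 * smooth + 1
    ys <- stats::filter(y, rep(1 / k, k), sides = 2)
    ys[is.na(ys)] <- y[is.na(ys)]
    ys <- as.numeric(ys)
  }
  thr <- min(ys) + prominence * diff(range(ys))
  for (k in 2:(n - 1)) {
    if (ys[k] >= ys[k - 1] && ys[k] > ys[k + 1] && ys[k] > thr) {
      d <- (ys[k - 1] - 2 * ys[k] + ys[k + 1])
      off <- if (d < 0) 0.5 * (ys[k - 1] - ys[k + 1]) / d else 0
      return(r[k] + off * (r[2] - r[1]))
    }
  }
  stop("no qualifying peak in g(r)")
}

# log-spaced unique integer lags up to max_lag (always includes 0 and 1)
log_lags <- function(max_lag, n_lags) {
  if (max_lag < 1) return(0L)
  unique(c(0L, as.integer(round(exp(seq(0, log(max_lag),
                                        length.out = n_lags))))))
}

# core Fs accumulator: returns per-cell x per-lag matrix or global vector
fs_accumulate <- function(upos, times, q, lags, origins_per_lag,
                          per_cell = FALSE, origin_min = 1L,
                          origin_max = Inf) {
  N <- dim(upos)[1]
  FF <- dim(upos)[3]
  vals <- if (per_cell) matrix(NA_real_, N, length(lags)) else
    numeric(length(lags))
  n_orig <- integer(length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    if (lag == 0) {
      vals[k] <- 1
      if (per_cell) vals[, k] <- 1
      n_orig[k] <- FF
      next
    }
    o_max <- min(FF - lag, origin_max)
    if (o_max < origin_min) {
      n_orig[k] <- 0L
      if (per_cell) vals[, k] <- NA_real_ else vals[k] <- NA_real_
      next
    }
    origins <- unique(round(seq(origin_min, o_max,
                                length.out = min(origins_per_lag,
                                                 o_max - origin_min + 1))))
    acc <- if (per_cell) numeric(N) else 0
    for (o in origins) {
      dx <- upos[, 1, o + lag] - upos[, 1, o]
      dy <- upos[, 2, o + lag] - upos[, 2, o]
      j0 <- besselJ(q * sqrt(dx * dx + dy * dy), 0)
      if (per_cell) acc <- acc + j0 else acc <- acc + mean(j0)
    }
    if (per_cell) vals[, k] <- acc / length(origins) else
      vals[k] <- acc / length(origins)
    n_orig[k] <- length(origins)
  }
  list(vals = vals, n_origins = n_orig)
}

#' Self-intermediate scattering function Fs(q, t)
#'
#' Isotropic estimator
#' `Fs(q, t) = < J0(q |r_j(t0 + t) - r_j(t0)|) >_{j, t0}`,
#' the exact average of `cos(q . dr)` over all directions of the
#' wavevector in 2D. Displacements use unwrapped coordinates (wrapped ones
#' would artificially plateau). Lags are log-spaced in frame units with up
#' to `max_origins` time origins per lag. `Fs(q, 0) = 1` exactly.
#'
#' @param traj a `trajectory`.
#' @param q wavevector magnitude, 1/um; conventionally `2*pi / r_max` with
#'   r_max the first peak of g(r).
#' @param n_lags number of log-spaced lags.
#' @param max_origins cap on time origins per lag.
#' @return object of class `correlation_series`: data.frame with columns
#'   `lag` (s), `value`, `n_origins`.
#' @export
self_intermediate_scattering <- function(traj, q, n_lags = 60,
                                         max_origins = 200) {
  if (q <= 0) stop("q must be positive")
  lags <- log_lags(n_frames(traj) - 1, n_lags)
  res <- fs_accumulate(traj$pos_unwrapped, traj$times, q, lags, max_origins)
  dtf <- if (n_frames(traj) > 1) diff(traj$times[1:2]) else traj$params$dt
  out <- data.frame(lag = lags * dtf, value = res$vals,
                    n_origins = res$n_origins)
  out <- out[out$n_origins > 0, ]
  class(out) <- c("correlation_series", "data.frame")
  out
}

#' Alpha-relaxation time from a correlation series
#'
#' First crossing of 1/e, located by interpolation between the bracketing
#' lags (linear in log-time when both lags are positive). A crossing only
#' counts when the following sampled lag is also below 1/e, which guards
#' against single-lag noise dips in weakly averaged series. Series that
#' never reach 1/e within the window are censored: the return value is
#' `NA_real_` with attribute `relaxed = FALSE`.
#'
#' @param fs a `correlation_series` (e.g. from
#'   [self_intermediate_scattering()]).
#' @return tau_alpha in seconds, or `NA_real_` (unrelaxed).
#' @export
relaxation_time <- function(fs) {
  t <- fs$lag; y <- fs$value
  target <- exp(-1)
  below <- which(y < target)
  # noise guard: require the next sampled lag to stay below 1/e as well
  below <- below[below == length(y) | (below + 1) %in% below]
  if (!length(below)) {
    return(structure(NA_real_, relaxed = FALSE))
  }
  k <- below[1]
  if (k == 1) return(structure(t[1], relaxed = TRUE))
  t1 <- t[k - 1]; t2 <- t[k]; y1 <- y[k - 1]; y2 <- y[k]
  tau <- if (t1 > 0) {
    exp(log(t1) + (y1 - target) / (y1 - y2) * (log(t2) - log(t1)))
  } else {
    t1 + (y1 - target) / (y1 - y2) * (t2 - t1)
  }
  structure(tau, relaxed = TRUE)
}

#' Per-cell alpha-relaxation times
#'
#' Single-particle Fs for each cell (averaged over time origins only),
#' each reduced to its 1/e crossing. Cells that do not relax within the
#' window are censored (`NA`).
#'
#' @inheritParams self_intermediate_scattering
#' @return data.frame with columns `radius`, `tau`, `relaxed`.
#' @export
per_cell_relaxation_times <- function(traj, q, n_lags = 60,
                                      max_origins = 200) {
  if (q <= 0) stop("q must be positive")
  lags <- log_lags(n_frames(traj) - 1, n_lags)
  res <- fs_accumulate(traj$pos_unwrapped, traj$times, q, lags, max_origins,
                       per_cell = TRUE)
  dtf <- if (n_frames(traj) > 1) diff(traj$times[1:2]) else traj$params$dt
  keep <- res$n_origins > 0
  taus <- apply(res$vals[, keep, drop = FALSE], 1, function(v) {
    s <- data.frame(lag = lags[keep] * dtf, value = v)
    class(s) <- c("correlation_series", "data.frame")
    relaxation_time(s)
  })
  data.frame(radius = traj$radii, tau = as.numeric(taus),
             relaxed = !is.na(as.numeric(taus)))
}

#' Histogram of log relaxation times with scaled master curve
#'
#' Builds the normalized histogram of `ln(tau_alpha)` over the finite
#' (relaxed) values and its scaled form P / Pmax against `ln(tau)` centred
#' on the peak, the form on which a Gaussian master curve is expected
#' below the saturation packing fraction. Censored (unrelaxed) values are
#' excluded but counted.
#'
#' @param taus vector of relaxation times (NA = censored).
#' @param breaks passed to [hist()]; default Freedman-Diaconis.
#' @return list with `log_tau` (bin centres), `p` (density), `p_scaled`,
#'   `centered` (bin centres minus peak position), `n_censored`, `n_used`.
#' @export
log_tau_histogram <- function(taus, breaks = "FD") {
  lt <- log(taus[is.finite(taus) & taus > 0])
  if (length(lt) < 10) stop("need at least 10 finite relaxation times")
  h <- graphics::hist(lt, breaks = breaks, plot = FALSE)
  imax <- which.max(h$density)
  list(log_tau = h$mids, p = h$density,
       p_scaled = h$density / max(h$density),
       centered = h$mids - h$mids[imax],
       n_censored = sum(is.na(taus)), n_used = length(lt))
}

#' Waiting-time-resolved Fs(q, t) (aging probe)
#'
#' Recomputes Fs with time origins restricted to a window starting at each
#' waiting time tau_w. For a stationary (non-aging) system the curves
#' collapse; systematic ordering with tau_w indicates aging.
#'
#' @inheritParams self_intermediate_scattering
#' @param tau_w vector of waiting times, s (measured from the first frame).
#' @param origin_window length of the origin window after each tau_w, s;
#'   default one frame (single origin per waiting time uses `0`).
#' @return named list of `correlation_series`, one per waiting time.
#' @export
waiting_time_fs <- function(traj, q, tau_w, origin_window = 0,
                            n_lags = 60, max_origins = 50) {
  if (q <= 0) stop("q must be positive")
  t0 <- traj$times[1]
  dtf <- diff(traj$times[1:2])
  FF <- n_frames(traj)
  out <- list()
  for (w in tau_w) {
    f_lo <- 1L + as.integer(round((w) / dtf))
    f_hi <- 1L + as.integer(round((w + origin_window) / dtf))
    if (f_hi >= FF)
      stop("trajectory shorter than waiting time plus decay window")
    lags <- log_lags(FF - f_hi, n_lags)
    res <- fs_accumulate(traj$pos_unwrapped, traj$times, q, lags,
                         max_origins, origin_min = f_lo, origin_max = f_hi)
    keep <- res$n_origins > 0
    s <- data.frame(lag = lags[keep] * dtf, value = res$vals[keep],
                    n_origins = res$n_origins[keep])
    class(s) <- c("correlation_series", "data.frame")
    out[[as.character(w)]] <- s
  }
  out
}

#' Cell-cell overlap statistics over a trajectory
#'
#' Pools the positive overlaps h_ij of all contacting pairs over the
#' selected frames into a normalized histogram P(h), and returns the mean
#' overlap `<h> = int h P(h) dh` (the sample mean).
#'
#' @param traj a `trajectory`.
#' @param frames frame indices (default: all).
#' @param bin_width histogram bin, um; default Freedman-Diaconis.
#' @return list with `h` (bin centres), `p` (density), `mean_h`,
#'   `n_pairs`.
#' @export
overlap_distribution <- function(traj, frames = NULL, bin_width = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  hs <- unlist(lapply(frames, function(f)
    overlaps_cpp(traj$pos_wrapped[, , f], traj$radii, traj$box_length)))
  if (!length(hs))
    return(list(h = numeric(0), p = numeric(0), mean_h = 0, n_pairs = 0L))
  br <- if (is.null(bin_width)) "FD" else
    seq(0, max(hs) + bin_width, by = bin_width)
  h <- graphics::hist(hs, breaks = br, plot = FALSE)
  list(h = h$mids, p = h$density, mean_h = mean(hs), n_pairs = length(hs))
}
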