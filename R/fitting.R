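new_fit_result <- function(model, par, se = NULL, residual_norm = NA_real_,
                           converged = FALSE, window = NULL, extra = list()) {
  structure(c(list(model = model, par = par, se = se,
                   residual_norm = residual_norm, converged = converged,
                   window = window), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$model,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(signif(x$par, 5))
  if (!is.null(x$se)) { cat("  se:\n"); print(signif(x$se, 3)) }
  cat("  residual norm:", signif(x$residual_norm, 4), "\n")
  invisible(x)
}

#' Vogel-Fulcher-Tammann fit
#'
#' Fits `y = y0 * exp(D / (phi0/phi - 1))` to viscosities or relaxation
#' times as a function of packing fraction. The fit is performed in log
#' space, where the model is linear in `(ln y0, D)` at fixed `phi0`; a 1D
#' search over `phi0` (golden-section via [optimize()]) minimizes the
#' residual sum of squares. Points above the saturation packing fraction
#' `phi_s` are excluded by default, since the VFT regime ends there.
#'
#' @param phi packing fractions.
#' @param y positive values (viscosity or relaxation time).
#' @param weights optional weights on the log-space residuals (e.g.
#'   inverse variances from replicate spreads).
#' @param phi_s fit-window upper bound; points with `phi > phi_s` are
#'   dropped. Default 0.90.
#' @param phi0_max upper search bound for phi0.
#' @return a `fit_result` with parameters `y0`, `D`, `phi0`. The flag
#'   `boundary` marks a phi0 estimate at the search boundary.
#' @export
fit_vft <- function(phi, y, weights = NULL, phi_s = 0.90, phi0_max = 1.1) {
  keep <- phi <= phi_s & is.finite(y) & y > 0
  phi <- phi[keep]; ly <- log(y[keep])
  w <- if (is.null(weights)) rep(1, length(phi)) else weights[keep]
  if (length(phi) < 4) stop("need at least 4 points in the fit window")
  lo <- max(phi) + 0.005
  sse <- function(p0) {
    x <- 1 / (p0 / phi - 1)
    f <- lm(ly ~ x, weights = w)
    sum(w * f$residuals^2)
  }
  opt <- optimize(sse, c(lo, phi0_max))
  p0 <- opt$minimum
  x <- 1 / (p0 / phi - 1)
  f <- lm(ly ~ x, weights = w)
  cf <- coef(f)
  par <- c(y0 = exp(cf[[1]]), D = cf[[2]], phi0 = p0)
  se <- sqrt(diag(stats::vcov(f)))
  boundary <- (p0 - lo < 1e-4) || (phi0_max - p0 < 1e-4)
  under <- length(phi) < 4
  new_fit_result("vft", par,
                 se = c(log_y0 = se[[1]], D = se[[2]], phi0 = NA),
                 residual_norm = sqrt(opt$objective),
                 converged = TRUE, window = range(phi),
                 extra = list(boundary = boundary,
                              underdetermined = under))
}

#' Evaluate a VFT fit
#'
#' @param fit a `fit_result` from [fit_vft()].
#' @param phi packing fractions, all strictly below the fitted phi0 (the
#'   model diverges there).
#' @return fitted values.
#' @export
predict_vft <- function(fit, phi) {
  p <- fit$par
  if (any(phi >= p[["phi0"]]))
    stop("VFT curve diverges at phi0; cannot evaluate at phi >= phi0")
  p[["y0"]] * exp(p[["D"]] / (p[["phi0"]] / phi - 1))
}

#' Stretched-exponential (KWW) fit
#'
#' Fits `Cs * exp(-(t/tau)^beta)` by Levenberg-Marquardt nonlinear least
#' squares with `beta` constrained to (0, 2].
#'
#' @param t times, s.
#' @param y values.
#' @param window optional `c(tmin, tmax)` restricting the fit.
#' @param start optional named start values `Cs`, `tau`, `beta`.
#' @return a `fit_result` with parameters `Cs`, `tau`, `beta`.
#' @export
fit_stretched_exponential <- function(t, y, window = NULL, start = NULL) {
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  keep <- is.finite(y) & t >= 0
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4) stop("need at least 4 points")
  if (is.null(start)) {
    C0 <- max(y)
    pos <- y > 0.01 * C0
    tau0 <- if (any(y < C0 * exp(-1))) t[which(y < C0 * exp(-1))[1]] else
      max(t[pos]) / 2
    start <- list(Cs = C0, tau = max(tau0, 1e-9), beta = 0.7)
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Cs * exp(-(t / tau)^beta), data = df,
                      start = start,
                      lower = c(Cs = -Inf, tau = 1e-12, beta = 1e-3),
                      upper = c(Cs = Inf, tau = Inf, beta = 2),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new_fit_result("stretched_exponential",
                          par = c(Cs = NA, tau = NA, beta = NA),
                          converged = FALSE,
                          extra = list(message = conditionMessage(fit))))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  new_fit_result("stretched_exponential", cf, se = se,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 converged = TRUE, window = range(t))
}

#' Gaussian master-curve fit of the log relaxation-time histogram
#'
#' In the glassy regime the scaled histogram of log relaxation times is
#' expected to follow `P/Pmax = exp(-c (ln tau - ln tau0)^2)`. The fit is
#' nonlinear least squares on the scaled histogram; the residual norm
#' doubles as the goodness-of-fit statistic used to contrast packing
#' fractions below and above saturation.
#'
#' @param log_tau bin centres (ln tau).
#' @param p_scaled histogram values scaled by their maximum.
#' @return a `fit_result` with parameters `c`, `log_tau0` and extra
#'   `gof` (mean squared residual).
#' @export
fit_gaussian_log_tau <- function(log_tau, p_scaled) {
  keep <- is.finite(p_scaled) & is.finite(log_tau)
  x <- log_tau[keep]; p <- p_scaled[keep]
  if (length(x) < 5) stop("need at least 5 bins")
  if (max(p) <= 0) stop("degenerate histogram")
  m0 <- x[which.max(p)]
  c0 <- 1 / max(1e-6, stats::weighted.mean((x - m0)^2, p))
  df <- data.frame(x = x, p = p)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ exp(-cc * (x - m)^2), data = df,
                      start = list(cc = c0 / 2, m = m0),
                      lower = c(cc = 1e-9, m = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new_fit_result("gaussian_log_tau", par = c(c = NA, log_tau0 = NA),
                          converged = FALSE,
                          extra = list(message = conditionMessage(fit))))
  cf <- coef(fit)
  rn <- sqrt(sum(stats::residuals(fit)^2))
  new_fit_result("gaussian_log_tau",
                 c(c = cf[["cc"]], log_tau0 = cf[["m"]]),
                 residual_norm = rn, converged = TRUE,
                 window = range(x),
                 extra = list(gof = mean(stats::residuals(fit)^2)))
}

#' Estimate the saturation packing fraction phi_S
#'
#' Smallest phi beyond which successive values of a monotone quantity
#' (viscosity or relaxation time) are statistically indistinguishable:
#' the first phi_k such that all later successive ratios differ from 1 by
#' less than `n_sigma` combined relative spreads.
#'
#' @param phi packing fractions (sorted or not).
#' @param y values per phi.
#' @param spread per-phi standard deviations (same length); zeros allowed.
#' @param n_sigma tolerance multiplier.
#' @param rel_floor minimum relative tolerance when spreads are tiny.
#' @return estimated phi_S (possibly `NA` when no plateau is reached).
#' @export
estimate_phi_s <- function(phi, y, spread = NULL, n_sigma = 2,
                           rel_floor = 0.1) {
  o <- order(phi)
  phi <- phi[o]; y <- y[o]
  spread <- if (is.null(spread)) rep(0, length(y)) else spread[o]
  rel <- pmax(sqrt((spread / y)^2 + c(0, (spread / y)[-length(y)]^2)),
              rel_floor)
  flat <- abs(diff(y) / head(y, -1)) < n_sigma * head(rel, -1)
  # first index from which all later steps are flat
  for (k in seq_along(flat)) if (all(flat[k:length(flat)])) return(phi[k])
  NA_real_
}
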