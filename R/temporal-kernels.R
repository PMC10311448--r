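#' Temporal receptive-field specification
#'
#' Parameterises a temporal smoothing/derivative kernel: either the
#' time-causal limit kernel \eqn{\psi(t; \tau, c)} (`causal = TRUE`), realised
#' as a finite cascade of `K` first-order integrators with geometrically
#' distributed time constants, or the non-causal temporal Gaussian
#' (`causal = FALSE`). Temporal derivatives of order `n` are scale-normalised
#' by \eqn{\tau^{n/2}}.
#'
#' @param tau Temporal scale (time squared, > 0).
#' @param c Distribution parameter (> 1); ratio between successive temporal
#'   scale levels. Default `sqrt(2)`.
#' @param K Number of cascade stages (>= 1). Default 12, leaving a variance
#'   deficit of `c^(-2K)` (about 2.4e-4 for the default `c`).
#' @param n Temporal derivative order, 0..3.
#' @param causal Use the time-causal limit kernel (default) or the Gaussian.
#' @return Object of class `temporal_rf_spec`.
#' @export
temporal_rf_spec <- function(tau = 1, c = sqrt(2), K = 12L, n = 0L,
                             causal = TRUE) {
  stopifnot(tau > 0, K >= 1)
  if (c <= 1) stop("distribution parameter c must exceed 1")
  n <- as.integer(n)
  if (n < 0L || n > 3L) stop("temporal derivative order n must be in 0..3")
  structure(list(tau = tau, c = c, K = as.integer(K), n = n, causal = causal),
            class = "temporal_rf_spec")
}

#' Time constants of the limit-kernel integrator cascade
#'
#' The limit kernel's Fourier transform is an infinite product of first-order
#' low-pass factors; stage `k` contributes the time constant
#' \eqn{\mu_k = c^{-k} \sqrt{c^2 - 1} \sqrt{\tau}}. The squared time
#' constants form a geometric series summing to \eqn{\tau}, so the first `K`
#' stages carry temporal variance \eqn{\tau (1 - c^{-2K})}.
#'
#' @param tau Temporal scale (> 0).
#' @param c Distribution parameter (> 1).
#' @param K Number of stages.
#' @return Strictly decreasing positive vector `mu[1..K]`.
#' @examples
#' limit_kernel_time_constants(1, sqrt(2), 3)  # 0.7071, 0.5, 0.3536
#' @export
limit_kernel_time_constants <- function(tau, c, K) {
  stopifnot(tau > 0, K >= 1)
  if (c <= 1) stop("distribution parameter c must exceed 1")
  c^(-(1:K)) * sqrt(c^2 - 1) * sqrt(tau)
}

# One first-order integrator stage dy/dt = (x - y) / mu, discretised
# ramp-invariantly (exact for piecewise-linear input): pole at exp(-dt/mu)
# with input weights chosen so the continuous solution is reproduced for
# linear input segments. Unit DC gain, nonnegative impulse response for any
# dt, and - unlike the plain exponential (zero-order-hold) update - no
# half-sample group-delay bias, which would otherwise accumulate to
# K * dt / 2 over the cascade and break temporal-scaling covariance.
integrator_stage <- function(x, mu, dt) {
  r <- dt / mu
  a <- exp(-r)
  b1 <- 1 - (1 - a) / r
  b0 <- (1 - a) / r - a
  xin <- b1 * x + b0 * c(0, x[-length(x)])
  stats::filter(xin, a, method = "recursive")
}

#' Sampled time-causal limit kernel
#'
#' Applies the `K`-stage cascade of first-order temporal integrators to a
#' discrete impulse, yielding the sampled limit kernel on `[0, T]`. The
#' kernel is nonnegative, exactly zero for `t < 0` (not represented), and
#' has unit DC gain; its temporal variance is `tau * (1 - c^(-2K))`.
#'
#' @param spec A [temporal_rf_spec()] with `causal = TRUE`, `n = 0`.
#' @param dt Sampling step; must resolve the fastest stage (`dt <= mu_K`;
#'   a warning is issued above `mu_K / 4`).
#' @param T Horizon; should cover the kernel mean plus `8 sqrt(tau)`.
#' @return Numeric vector of kernel values at `t = 0, dt, 2 dt, ...`, with
#'   attributes `t`, `dt`, `mu`.
#' @export
limit_kernel_discrete <- function(spec, dt, T = NULL) {
  stopifnot(inherits(spec, "temporal_rf_spec"), spec$causal)
  mu <- limit_kernel_time_constants(spec$tau, spec$c, spec$K)
  if (dt > mu[1L] / 2)
    stop("dt too coarse to resolve the integrator cascade (dt > mu_1/2)")
  if (dt > mu[spec$K] / 4)
    warning("dt above mu_K/4; fastest stages only marginally resolved ",
            "(their variance contribution is underestimated)")
  mean_t <- sum(mu)
  if (is.null(T)) T <- mean_t + 8 * sqrt(spec$tau)
  nt <- as.integer(ceiling(T / dt)) + 1L
  h <- numeric(nt)
  h[1L] <- 1 / dt  # unit-mass discrete impulse at t = 0
  for (k in seq_len(spec$K)) h <- integrator_stage(h, mu[k], dt)
  h <- as.numeric(h)
  if (sum(h) * dt < 1 - 1e-3)
    warning("horizon T too short; truncated kernel mass below 0.999")
  structure(h, t = seq(0, by = dt, length.out = nt), dt = dt, mu = mu)
}

#' Temporal Gaussian kernel value
#'
#' The non-causal 1-D temporal Gaussian
#' \eqn{h(t; \tau) = \exp(-t^2 / 2\tau) / \sqrt{2 \pi \tau}}; even in `t`,
#' with temporal variance `tau`.
#'
#' @param t Time point(s).
#' @param tau Temporal scale (time squared, > 0).
#' @return Density value(s).
#' @export
temporal_gaussian_value <- function(t, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  exp(-t^2 / (2 * tau)) / sqrt(2 * pi * tau)
}

# Central differences of order n on a sampled signal (forward/backward at
# the support edges), spacing dt.
finite_difference <- function(h, dt, n) {
  for (i in seq_len(n)) {
    nh <- length(h)
    d <- numeric(nh)
    d[2:(nh - 1)] <- (h[3:nh] - h[1:(nh - 2)]) / (2 * dt)
    d[1L] <- (h[2L] - h[1L]) / dt
    d[nh] <- (h[nh] - h[nh - 1L]) / dt
    h <- d
  }
  h
}

#' Sampled temporal receptive-field kernel
#'
#' For derivative order `n = 0`, the smoothing kernel itself (limit kernel or
#' sampled temporal Gaussian); for `n >= 1`, the scale-normalised temporal
#' derivative \eqn{\tau^{n/2} \partial_t^n h}, computed by central finite
#' differences on the sampled smoothed impulse. Derivative kernels sum to
#' (approximately) zero.
#'
#' @inheritParams limit_kernel_discrete
#' @param spec A [temporal_rf_spec()].
#' @return Numeric vector with attributes `t`, `dt` (and `mu` if causal).
#' @export
temporal_rf_kernel <- function(spec, dt, T = NULL) {
  stopifnot(inherits(spec, "temporal_rf_spec"))
  if (spec$causal) {
    h0 <- limit_kernel_discrete(
      temporal_rf_spec(spec$tau, spec$c, spec$K, 0L, TRUE), dt, T)
    tt <- attr(h0, "t")
    h <- as.numeric(h0)
  } else {
    if (is.null(T)) T <- 8 * sqrt(spec$tau)
    tt <- seq(-T, T, by = dt)
    h <- temporal_gaussian_value(tt, spec$tau)
  }
  if (spec$n > 0L) h <- spec$tau^(spec$n / 2) * finite_difference(h, dt, spec$n)
  structure(h, t = tt, dt = dt,
            mu = if (spec$causal) limit_kernel_time_constants(spec$tau, spec$c, spec$K))
}

# Discrete moments of a sampled kernel on grid t (weights h * dt)
kernel_temporal_moments <- function(h, t, dt) {
  m0 <- sum(h) * dt
  m1 <- sum(t * h) * dt / m0
  m2 <- sum((t - m1)^2 * h) * dt / m0
  list(mass = m0, mean = m1, variance = m2)
}
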