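#' Spatio-temporal receptive-field specification
#'
#' Parameterises a velocity-adapted spatio-temporal receptive field
#' \eqn{s^{m/2} \tau^{n/2} \partial_{\phi_d}^m \bar\partial_t^n
#' (g(x - v t; s\Sigma)\, h(t; \tau))}: the spatial kernel travels along the
#' motion trajectory `x = v t` and temporal differentiation uses the
#' transport (velocity-adapted) derivative
#' \eqn{\bar\partial_t = v_1 \partial_{x_1} + v_2 \partial_{x_2} + \partial_t}.
#'
#' @param s Spatial scale (> 0).
#' @param Sigma A `spatial_covariance` or 2x2 SPD matrix.
#' @param tau Temporal scale (> 0).
#' @param c Distribution parameter of the limit kernel (> 1).
#' @param K Integrator stages.
#' @param v Image velocity, length-2 vector in pixels/frame.
#' @param m Spatial derivative order (0..4).
#' @param n Temporal derivative order (0..2).
#' @param phi_d Spatial derivative direction; default across the elongated
#'   axis as in [spatial_rf_spec()].
#' @param causal Time-causal limit kernel (default) or temporal Gaussian.
#' @return Object of class `st_rf_spec`.
#' @export
st_rf_spec <- function(s = 1, Sigma = covariance_from_eigen(1, 1),
                       tau = 1, c = sqrt(2), K = 12L, v = c(0, 0),
                       m = 0L, n = 0L, phi_d = NULL, causal = TRUE) {
  sp <- spatial_rf_spec(s, Sigma, m, phi_d)
  tp <- temporal_rf_spec(tau, c, K, 0L, causal)
  stopifnot(length(v) == 2L, all(is.finite(v)))
  n <- as.integer(n)
  if (n < 0L || n > 2L) stop("temporal derivative order n must be in 0..2")
  structure(list(s = s, Sigma = sp$Sigma, tau = tau, c = c, K = tp$K,
                 v = as.numeric(v), m = sp$m, n = n, phi_d = sp$phi_d,
                 causal = causal),
            class = "st_rf_spec")
}

# Frame count covering the causal kernel's mean plus eight times its
# slowest decay constant (tail mass ~ 3e-4); odd symmetric span for the
# non-causal Gaussian.
auto_nt <- function(tau, c, K, causal = TRUE) {
  if (causal) {
    mu <- limit_kernel_time_constants(tau, c, K)
    as.integer(ceiling(sum(mu) + 8 * mu[1L])) + 1L
  } else {
    h <- as.integer(ceiling(5 * sqrt(tau)))
    2L * h + 1L
  }
}

# Temporal factor of an ST kernel on an oversampled grid, plus frame-rate
# binning. Fine samples are distributed onto the four neighbouring frames
# with Keys cubic weights, so discrete temporal convolution with the binned
# kernel acts as continuous temporal convolution with the cubically
# interpolated signal - the same interpolation model the warps use, and
# third-order accurate in the frame spacing (box binning would only be
# zero-order and dominates diagram residuals otherwise).
st_temporal_fine <- function(spec, nt, oversample) {
  dt <- 1 / oversample
  tspec <- temporal_rf_spec(spec$tau, spec$c, spec$K, spec$n, spec$causal)
  h <- suppressWarnings(temporal_rf_kernel(tspec, dt, T = nt + 0.5))
  tt <- attr(h, "t")
  if (spec$causal) {
    offset <- 1L
    lo <- 0L
  } else {
    if (nt %% 2L == 0L) stop("non-causal kernels need an odd frame count")
    offset <- (nt - 1L) %/% 2L + 1L
    lo <- -(offset - 1L)
  }
  j0 <- as.integer(floor(tt))
  frac <- tt - j0
  s0 <- j0 + offset          # slice of floor(t); s0 + 1 gets weight frac
  keep <- (j0 >= lo - 1L) & (j0 <= lo + nt - 1L)
  list(h = as.numeric(h)[keep], t = tt[keep], s0 = s0[keep],
       frac = frac[keep], dt = dt, nt = nt)
}

# Keys-binned frame weights of the fine temporal kernel. Taps that fall
# outside the slice range (before the causal edge or past the horizon) are
# folded onto the boundary slice, preserving the partition of unity - a
# dropped tap would otherwise bias the DC weight of every kernel by ~1e-3
# near the causal onset.
temporal_weights <- function(fine, nt) {
  w <- numeric(nt)
  for (i in seq_along(fine$t)) {
    ww <- fine$h[i] * fine$dt
    for (d in -1:2) {
      j <- min(max(fine$s0[i] + d, 1L), nt)
      w[j] <- w[j] + ww * keys_w(d - fine$frac[i])
    }
  }
  w
}

# frame time (in frames) represented by each kernel slice
slice_times <- function(nt, causal) {
  if (causal) seq_len(nt) - 1 else seq_len(nt) - 1 - (nt - 1L) %/% 2L
}

#' Velocity-adapted spatio-temporal receptive-field kernel
#'
#' Builds the discrete 2+1-D kernel indexed `(x1, x2, t)`. At each fine
#' temporal sample the spatial slice is the analytic spatial derivative
#' kernel recentred at `v * t` (the shift enters the Gaussian argument
#' directly, no interpolation); slices are weighted by the temporal kernel
#' and box-integrated down to frame rate. Because the velocity-adapted
#' derivative satisfies
#' \eqn{\bar\partial_t [g(x - v t) h(t)] = g(x - v t)\, h'(t)},
#' temporal differentiation acts on the temporal factor alone (realised by
#' finite differences on the oversampled smoothed impulse), while spatial
#' differentiation is analytic. Scale normalisation is
#' \eqn{s^{m/2} \tau^{n/2}}.
#'
#' For `v = c(0, 0)` the kernel is exactly the outer product of the spatial
#' and temporal kernels (space-time separable).
#'
#' @param spec An [st_rf_spec()].
#' @param grid A [grid_spec()] for the spatial slices; `NULL` sizes it to
#'   cover the truncation radius plus the velocity sweep `|v| * nt`.
#' @param nt Number of temporal frames (frame-time is the unit of `t`).
#' @param oversample Temporal oversampling factor for kernel synthesis
#'   (default 4, i.e. `dt = 0.25` frame).
#' @return 3-D array `[x1, x2, t]` with attributes `mass` and `spec`.
#' @export
st_rf_kernel <- function(spec, grid = NULL, nt = NULL, oversample = 4L) {
  stopifnot(inherits(spec, "st_rf_spec"))
  if (is.null(nt)) nt <- auto_nt(spec$tau, spec$c, spec$K, spec$causal)
  max_std <- sqrt(spec$s * spec$Sigma$lam1)
  fine <- st_temporal_fine(spec, nt, oversample)
  sweep <- max(abs(outer(fine$t, spec$v)))
  if (is.null(grid)) {
    h <- ceiling(5 * max_std + sweep)
    grid <- grid_spec(2L * h + 1L, 2L * h + 1L)
  } else {
    hx <- (grid$nx - 1L) %/% 2L
    if (hx < grid$truncation_radius * max_std + sweep - max_std)
      warning("spatial grid may not contain the velocity-swept kernel support")
  }
  x <- grid_coords(grid)
  S <- spec$s * spec$Sigma$M
  Sinv <- chol2inv(chol(S))
  u <- c(cos(spec$phi_d), sin(spec$phi_d))
  norm_m <- spec$s^(spec$m / 2)
  kern <- array(0, c(grid$nx, grid$ny, nt))
  ht <- temporal_weights(fine, nt)
  if (spec$n >= 1L) ht <- ht - sum(ht) / nt   # vanishing temporal moment
  t_of_slice <- slice_times(nt, spec$causal)
  for (j in seq_len(nt)) {
    if (ht[j] == 0) next
    xs <- x
    xs[, 1L] <- xs[, 1L] - spec$v[1L] * t_of_slice[j]
    xs[, 2L] <- xs[, 2L] - spec$v[2L] * t_of_slice[j]
    slice <- norm_m * directional_gaussian_derivative(xs, S, u, spec$m)
    inside <- rowSums((xs %*% Sinv) * xs) <= grid$truncation_radius^2
    slice[!inside] <- 0
    if (spec$m >= 1L)
      slice[inside] <- slice[inside] - sum(slice[inside]) / sum(inside)
    kern[, , j] <- matrix(slice, grid$nx, grid$ny) * ht[j]
  }
  attr(kern, "mass") <- sum(kern)
  attr(kern, "spec") <- spec
  kern
}

#' Velocity-adapted spatio-temporal LGN kernel
#'
#' Rotationally symmetric over the spatial domain: the spatial Laplacian of
#' an isotropic Gaussian travelling at velocity `v`, times a (velocity-
#' adapted) temporal derivative of the limit kernel,
#' \eqn{\pm s\, \tau^{n/2} (\partial_{x_1 x_1} + \partial_{x_2 x_2})
#' \bar\partial_t^n (g(x - v t; s)\, \psi(t; \tau, c))}.
#' With `v = c(0, 0)` this is the space-time separable LGN model; with
#' `v != 0` its Galilean-covariant velocity-adapted variant.
#'
#' @param s Spatial scale.
#' @param tau,c,K Temporal parameters as in [temporal_rf_spec()].
#' @param n Temporal derivative order (0..2).
#' @param v Velocity 2-vector (pixels/frame).
#' @param grid,nt,oversample As in [st_rf_kernel()].
#' @param sign Leading sign, +1 or -1.
#' @param causal Limit kernel (default) or temporal Gaussian.
#' @return 3-D array `[x1, x2, t]` with attributes `mass` and `spec`.
#' @export
lgn_st_kernel <- function(s, tau = 1, c = sqrt(2), K = 12L, n = 0L,
                          v = c(0, 0), grid = NULL, nt = NULL,
                          oversample = 4L, sign = +1, causal = TRUE) {
  stopifnot(s > 0, sign %in% c(-1, 1), length(v) == 2L)
  if (is.null(nt)) nt <- auto_nt(tau, c, K, causal)
  spec <- list(s = s, tau = tau, c = c, K = as.integer(K), v = as.numeric(v),
               n = as.integer(n), sign = sign, causal = causal,
               model = "lgn_st")
  fine <- st_temporal_fine(list(tau = tau, c = c, K = K, n = n,
                                causal = causal), nt, oversample)
  sweep <- max(abs(outer(fine$t, v)))
  if (is.null(grid)) {
    h <- ceiling(5 * sqrt(s) + sweep)
    grid <- grid_spec(2L * h + 1L, 2L * h + 1L)
  }
  x <- grid_coords(grid)
  kern <- array(0, c(grid$nx, grid$ny, nt))
  # tau^(n/2) normalisation is already applied inside the fine temporal kernel
  ht <- temporal_weights(fine, nt)
  if (n >= 1L) ht <- ht - sum(ht) / nt        # vanishing temporal moment
  t_of_slice <- slice_times(nt, causal)
  for (j in seq_len(nt)) {
    if (ht[j] == 0) next
    d1 <- x[, 1L] - v[1L] * t_of_slice[j]
    d2 <- x[, 2L] - v[2L] * t_of_slice[j]
    r2 <- d1 * d1 + d2 * d2
    g <- exp(-r2 / (2 * s)) / (2 * pi * s)
    slice <- sign * s * (r2 / s^2 - 2 / s) * g
    inside <- r2 <= grid$truncation_radius^2 * s
    slice[!inside] <- 0
    slice[inside] <- slice[inside] - sum(slice[inside]) / sum(inside)
    kern[, , j] <- matrix(slice, grid$nx, grid$ny) * ht[j]
  }
  attr(kern, "mass") <- sum(kern)
  attr(kern, "spec") <- spec
  kern
}

#' Spatio-temporal convolution of a video with a kernel
#'
#' `L(x, t) = sum_{u, r} T(u, r) f(x - u, t - r)` with the kernel's spatial
#' origin at its centre sample and, for causal kernels, temporal support
#' aligned strictly over past and present frames (`r >= 0`). Spatial
#' boundaries reflect; the temporal axis is extended by replication, so the
#' first `dim(kernel)[3] - 1` frames form a start-up region whose values
#' depend on that extension (flagged in the `"invalid_frames"` attribute).
#'
#' @param video 3-D array `[x1, x2, t]`.
#' @param kernel 3-D kernel, odd-sized spatially.
#' @param causal Logical; `TRUE` aligns the kernel's first temporal slice on
#'   the present frame, `FALSE` centres it (odd temporal size required).
#' @param boundary Spatial boundary mode: `"reflect"` (default),
#'   `"replicate"`, `"circular"` (for periodic content), or `"zero"`.
#' @return Response volume, same shape as `video`, with attribute
#'   `invalid_frames` (number of start-up frames).
#' @export
convolve_spatiotemporal <- function(video, kernel, causal = TRUE,
                                    boundary = "reflect") {
  stopifnot(length(dim(video)) == 3L, length(dim(kernel)) == 3L)
  if (any(dim(kernel)[1:2] > dim(video)[1:2]) ||
      dim(kernel)[3L] > dim(video)[3L])
    stop("kernel must fit within the video extent")
  res <- fft_convolve_nd(video, kernel,
                         boundary = c(boundary, boundary, "replicate"),
                         causal_axes = if (causal) 3L else integer(0))
  attr(res, "invalid_frames") <-
    if (causal) dim(kernel)[3L] - 1L else (dim(kernel)[3L] - 1L) %/% 2L
  res
}

#' Frame-binned temporal kernel
#'
#' The temporal factor of a spatio-temporal kernel after box-integration of
#' the oversampled kernel down to frame rate: frame `j` collects fine
#' samples with `t` in `[j - 1/2, j + 1/2)` frames. This is exactly the
#' temporal profile through the spatial centre of a separable (`v = 0`)
#' kernel built by [st_rf_kernel()], divided by its spatial factor.
#'
#' @param tau,c,K,n,causal Temporal parameters as in [temporal_rf_spec()].
#' @param nt Number of frames.
#' @param oversample Oversampling factor (default 4).
#' @return Numeric vector of `nt` frame weights (unit sum for `n = 0` up to
#'   horizon truncation).
#' @export
temporal_frame_kernel <- function(tau, c = sqrt(2), K = 12L, n = 0L,
                                  nt = NULL, oversample = 4L, causal = TRUE) {
  if (is.null(nt)) nt <- auto_nt(tau, c, K, causal)
  fine <- st_temporal_fine(list(tau = tau, c = c, K = as.integer(K),
                                n = as.integer(n), causal = causal),
                           nt, oversample)
  w <- temporal_weights(fine, nt)
  if (n >= 1L) w <- w - sum(w) / nt           # vanishing temporal moment
  w
}
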