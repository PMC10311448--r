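#' Affine Gaussian density value
#'
#' Evaluates the zero-mean affine Gaussian
#' \eqn{g(x; \Sigma) = \exp(-x^T \Sigma^{-1} x / 2) / (2\pi \sqrt{\det \Sigma})},
#' the spatial smoothing kernel underlying the receptive-field models.
#' Mirror symmetric around the origin: `g(x) = g(-x)`.
#'
#' @param x Length-2 numeric vector, or an n x 2 matrix of positions.
#' @param Sigma A `spatial_covariance` or 2x2 SPD matrix.
#' @return Density value(s), units 1/grid-length^2.
#' @examples
#' affine_gaussian_value(c(0, 0), diag(2))  # 1 / (2 * pi)
#' @export
affine_gaussian_value <- function(x, Sigma) {
  Sigma <- eigen_from_covariance(Sigma)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  Sinv <- chol2inv(chol(Sigma$M))
  q <- rowSums((x %*% Sinv) * x)
  v <- exp(-q / 2) / (2 * pi * sqrt(Sigma$lam1 * Sigma$lam2))
  if (length(v) == 1L) v[[1L]] else v
}

# Probabilists' Hermite polynomial He_m(z), m <= 4, by recursion
hermite_he <- function(m, z) {
  if (m == 0L) return(rep_len(1, length(z)))
  h_prev <- rep_len(1, length(z))
  h <- z
  if (m == 1L) return(h)
  for (k in 1L:(m - 1L)) {
    h_next <- z * h - k * h_prev
    h_prev <- h
    h <- h_next
  }
  h
}

# m-th directional derivative of g(x; S) along unit vector u, evaluated at
# rows of x:  d_u^m g = (-1)^m b^{m/2} He_m(a / sqrt(b)) g,
# with a = u' S^{-1} x, b = u' S^{-1} u.
directional_gaussian_derivative <- function(x, S, u, m) {
  Sinv <- chol2inv(chol(S))
  dtS <- S[1L, 1L] * S[2L, 2L] - S[1L, 2L] * S[2L, 1L]
  a <- as.vector(x %*% (Sinv %*% u))
  b <- as.numeric(t(u) %*% Sinv %*% u)
  q <- rowSums((x %*% Sinv) * x)
  g <- exp(-q / 2) / (2 * pi * sqrt(dtS))
  if (m == 0L) return(g)
  (-1)^m * b^(m / 2) * hermite_he(m, a / sqrt(b)) * g
}

# Integer-offset coordinate rows for a kernel grid, centre at (0, 0);
# first array index is x1, second is x2.
grid_coords <- function(grid) {
  hx <- (grid$nx - 1L) %/% 2L
  hy <- (grid$ny - 1L) %/% 2L
  x1 <- rep(seq(-hx, hx), times = grid$ny)
  x2 <- rep(seq(-hy, hy), each = grid$nx)
  cbind(x1, x2)
}

#' Oriented spatial receptive-field kernel (simple-cell model)
#'
#' Samples the scale-normalised directional derivative of an affine Gaussian,
#' \eqn{s^{m/2} (\cos\phi_d \partial_{x_1} + \sin\phi_d \partial_{x_2})^m
#' g(x; s\Sigma)}, at integer offsets from the centre sample. The derivative
#' is taken analytically on the continuous kernel before sampling. Samples
#' beyond `truncation_radius` (Mahalanobis units of \eqn{s\Sigma}) are set to
#' zero; the kernel is not renormalised afterwards - the truncation deficit
#' is reported in the `"mass"` attribute instead.
#'
#' @param spec A [spatial_rf_spec()].
#' @param grid A [grid_spec()], or `NULL` to size the grid automatically.
#' @return Matrix of kernel weights indexed `[x1, x2]`, with attributes
#'   `mass` (sum of weights) and `spec`.
#' @export
spatial_rf_kernel <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "spatial_rf_spec"))
  S <- spec$s * spec$Sigma$M
  max_std <- sqrt(spec$s * spec$Sigma$lam1)
  if (is.null(grid)) grid <- auto_grid(max_std)
  hx <- (grid$nx - 1L) %/% 2L
  if (hx + 1e-9 < grid$truncation_radius * max_std - 1)
    warning(sprintf(
      "grid half-width %d below truncation radius %.1f x std %.2f; truncation error will exceed nominal tolerance",
      hx, grid$truncation_radius, max_std))
  x <- grid_coords(grid)
  u <- c(cos(spec$phi_d), sin(spec$phi_d))
  v <- spec$s^(spec$m / 2) *
    directional_gaussian_derivative(x, S, u, spec$m)
  Sinv <- chol2inv(chol(S))
  maha2 <- rowSums((x %*% Sinv) * x)
  inside <- maha2 <= grid$truncation_radius^2
  v[!inside] <- 0
  if (spec$m >= 1L) {
    # vanishing moment: remove the truncation-flux DC weight over the
    # support so derivative kernels annihilate constants exactly
    v[inside] <- v[inside] - sum(v[inside]) / sum(inside)
  }
  k <- matrix(v, grid$nx, grid$ny)
  attr(k, "mass") <- sum(k)
  attr(k, "spec") <- spec
  k
}

#' Rotationally symmetric spatial LGN kernel (Laplacian of Gaussian)
#'
#' Samples \eqn{\pm s (\partial_{x_1 x_1} + \partial_{x_2 x_2}) g(x; s I)},
#' the centre-surround model of LGN neurons. Exactly invariant under 90-degree
#' grid rotations; integrates to (approximately) zero.
#'
#' @param s Spatial scale (> 0).
#' @param grid A [grid_spec()] or `NULL` for automatic sizing.
#' @param sign `+1` (on-centre: negative central lobe of the Laplacian is
#'   flipped by the leading sign as printed) or `-1`.
#' @return Matrix of kernel weights indexed `[x1, x2]` with `mass` attribute.
#' @export
lgn_spatial_kernel <- function(s, grid = NULL, sign = +1) {
  stopifnot(s > 0, sign %in% c(-1, 1))
  if (is.null(grid)) grid <- auto_grid(sqrt(s))
  x <- grid_coords(grid)
  r2 <- rowSums(x * x)
  g <- exp(-r2 / (2 * s)) / (2 * pi * s)
  v <- sign * s * (r2 / s^2 - 2 / s) * g
  inside <- r2 <= (grid$truncation_radius^2 * s)
  v[!inside] <- 0
  v[inside] <- v[inside] - sum(v[inside]) / sum(inside)  # vanishing moment
  k <- matrix(v, grid$nx, grid$ny)
  attr(k, "mass") <- sum(k)
  attr(k, "spec") <- list(s = s, sign = sign, model = "lgn")
  k
}

#' Spatial convolution of an image with a centred kernel
#'
#' Discrete convolution `L(x) = sum_u T(u) f(x - u)` with the kernel centre
#' aligned on each output pixel, computed by FFT with the image extended by
#' the chosen boundary rule. Interior values (further than a kernel
#' half-width from the border) are independent of the boundary mode.
#'
#' @param image 2-D numeric array indexed `[x1, x2]`.
#' @param kernel Odd-sized 2-D kernel, smaller than the image.
#' @param boundary One of `"reflect"` (default), `"replicate"`, `"zero"`.
#' @return Response map, same shape as `image`.
#' @export
convolve_spatial <- function(image, kernel,
                             boundary = c("reflect", "replicate", "zero")) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(image), is.matrix(kernel))
  if (any(dim(kernel) > dim(image)))
    stop("kernel must not be larger than the image")
  if (any(dim(kernel) %% 2L == 0L)) stop("kernel must be odd-sized")
  fft_convolve_nd(image, kernel, boundary = boundary)
}
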