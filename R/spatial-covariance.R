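#' Spatial covariance matrix for affine Gaussian kernels
#'
#' The 2x2 symmetric positive definite matrix \eqn{\Sigma} that shapes the
#' elliptical support of an affine Gaussian kernel. Parameterised by its
#' eigenvalues `lam1 >= lam2 > 0` (in grid-length squared) and the
#' orientation `phi` of the `lam1` eigenvector, canonicalised to `[0, pi)`.
#'
#' @param lam1 Larger eigenvalue (> 0).
#' @param lam2 Smaller eigenvalue (> 0). If `lam1 < lam2` the two are swapped
#'   and `phi` rotated by `pi/2` so the invariant `lam1 >= lam2` holds.
#' @param phi Orientation of the major (`lam1`) eigenvector, radians.
#' @return An object of class `spatial_covariance` with fields `lam1`,
#'   `lam2`, `phi`, the reconstructed matrix `M`, and `isotropic` flag.
#' @examples
#' covariance_from_eigen(64, 16, 0)$M  # diag(64, 16)
#' @export
covariance_from_eigen <- function(lam1, lam2, phi = 0) {
  stopifnot(is.numeric(lam1), is.numeric(lam2), is.numeric(phi),
            length(lam1) == 1L, length(lam2) == 1L, length(phi) == 1L)
  if (!is.finite(lam1) || !is.finite(lam2) || lam1 <= 0 || lam2 <= 0)
    stop("eigenvalues of a spatial covariance must be positive and finite")
  if (lam1 < lam2) {
    tmp <- lam1; lam1 <- lam2; lam2 <- tmp
    phi <- phi + pi / 2
  }
  phi <- phi %% pi
  R <- rotation2(phi)
  M <- R %*% diag(c(lam1, lam2)) %*% t(R)
  M <- (M + t(M)) / 2  # symmetrise against rounding
  iso <- isTRUE(all.equal(lam1, lam2, tolerance = 1e-12))
  structure(
    list(lam1 = lam1, lam2 = lam2, phi = if (iso) 0 else phi,
         M = M, isotropic = iso),
    class = "spatial_covariance"
  )
}

#' Recover eigenstructure from a 2x2 covariance matrix
#'
#' Inverse of [covariance_from_eigen()]: eigen-decomposes a symmetric
#' positive definite 2x2 matrix into `(lam1, lam2, phi)`. When
#' `lam1 == lam2` the orientation is undefined and set to 0 with the
#' `isotropic` flag raised.
#'
#' @param M A 2x2 symmetric positive definite matrix, or a
#'   `spatial_covariance` object (returned unchanged).
#' @return A `spatial_covariance` object.
#' @export
eigen_from_covariance <- function(M) {
  if (inherits(M, "spatial_covariance")) return(M)
  stopifnot(is.matrix(M), all(dim(M) == c(2L, 2L)))
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M)))
    stop("covariance matrix must be symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("covariance matrix must be positive definite")
  v1 <- e$vectors[, 1L]
  covariance_from_eigen(e$values[1L], e$values[2L], atan2(v1[2L], v1[1L]))
}

#' @export
print.spatial_covariance <- function(x, ...) {
  cat(sprintf("spatial covariance: lam1 = %g, lam2 = %g, phi = %g rad%s\n",
              x$lam1, x$lam2, x$phi,
              if (x$isotropic) " (isotropic, orientation undefined)" else ""))
  invisible(x)
}

#' Eccentricity of a spatial covariance matrix
#'
#' \eqn{\epsilon = \sqrt{\lambda_{min}/\lambda_{max}} \in (0, 1]}: 1 for an
#' isotropic kernel, approaching 0 for a maximally elongated one. Rotation
#' invariant.
#'
#' @param Sigma A `spatial_covariance` or a 2x2 SPD matrix.
#' @return Eccentricity in `(0, 1]`.
#' @examples
#' eccentricity(covariance_from_eigen(64, 16, 0))  # 0.5
#' @export
eccentricity <- function(Sigma) {
  Sigma <- eigen_from_covariance(Sigma)
  sqrt(Sigma$lam2 / Sigma$lam1)
}

# 2x2 rotation matrix
rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Spatial receptive-field specification (simple-cell model)
#'
#' Parameterises an oriented spatial receptive field: a scale-normalised
#' directional derivative of an affine Gaussian kernel,
#' \eqn{s^{m/2} \partial_{\phi_d}^m \, g(x; s\Sigma)}.
#'
#' @param s Spatial scale, dimensionless multiplier on `Sigma` (> 0).
#' @param Sigma A `spatial_covariance` (or 2x2 SPD matrix). Default identity.
#' @param m Spatial derivative order, integer in 0..4.
#' @param phi_d Direction of the directional derivative, radians. Default is
#'   across the elongated axis (the minor eigenvector, `phi + pi/2`),
#'   the convention under which the derivative sweeps over the short axis of
#'   an elongated kernel.
#' @return Object of class `spatial_rf_spec`.
#' @export
spatial_rf_spec <- function(s = 1, Sigma = covariance_from_eigen(1, 1),
                            m = 0L, phi_d = NULL) {
  Sigma <- eigen_from_covariance(Sigma)
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  m <- as.integer(m)
  if (m < 0L || m > 4L) stop("spatial derivative order m must be in 0..4")
  if (is.null(phi_d)) phi_d <- Sigma$phi + pi / 2
  structure(list(s = s, Sigma = Sigma, m = m, phi_d = phi_d),
            class = "spatial_rf_spec")
}

#' @export
print.spatial_rf_spec <- function(x, ...) {
  cat(sprintf("spatial RF: s = %g, m = %d, phi_d = %g rad, ", x$s, x$m, x$phi_d))
  print(x$Sigma)
  invisible(x)
}

#' Kernel sampling grid specification
#'
#' Odd-sized grids so a centre sample exists; `truncation_radius` is the
#' kernel support cut-off in units of the largest kernel standard deviation.
#'
#' @param nx,ny Grid sizes in pixels (odd).
#' @param truncation_radius Support cut-off, default 5 standard deviations.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny = nx, truncation_radius = 5) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx %% 2L == 0L || ny %% 2L == 0L)
    stop("kernel grids must be odd-sized so a centre sample exists")
  stopifnot(truncation_radius > 0)
  structure(list(nx = nx, ny = ny, truncation_radius = truncation_radius),
            class = "grid_spec")
}

# Smallest odd grid covering truncation_radius * max std of the kernel
auto_grid <- function(max_std, truncation_radius = 5) {
  h <- ceiling(truncation_radius * max_std)
  grid_spec(2L * h + 1L, 2L * h + 1L, truncation_radius)
}
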