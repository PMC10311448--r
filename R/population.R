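#' Receptive-field population on a hemisphere
#'
#' Generates the uniform distribution of isotropic receptive-field shapes on
#' a hemisphere mapped to the image plane by orthographic projection: a
#' rotationally symmetric kernel on a tangent plane at slant \eqn{\theta}
#' foreshortens into an anisotropic kernel with eigenvalues
#' \eqn{(\lambda_{max},\ \lambda_{max} \cos^2\theta)} and orientation equal
#' to the azimuth, so the eccentricity is \eqn{\epsilon = \cos\theta}: 1 at
#' the pole (isotropic), approaching 0 at the rim (maximally anisotropic).
#'
#' @param n_azimuth Number of azimuth samples, uniform on `[0, pi)`.
#' @param n_slant Number of slant samples, uniform on `[0, pi/2)` (the rim
#'   itself is excluded since its minor eigenvalue would vanish).
#' @param lam_max Major eigenvalue of every member (> 0).
#' @param s Spatial scale of every member.
#' @param m Derivative order of every member.
#' @return An `rf_population`: list with `members` (list of
#'   [spatial_rf_spec()]), `slant`, `azimuth`, and `provenance`.
#' @export
hemisphere_population <- function(n_azimuth, n_slant, lam_max, s = 1,
                                  m = 1L) {
  stopifnot(n_azimuth >= 1, n_slant >= 1, lam_max > 0)
  slants <- (seq_len(n_slant) - 1L) * (pi / 2) / n_slant
  azimuths <- (seq_len(n_azimuth) - 1L) * pi / n_azimuth
  grid <- expand.grid(azimuth = azimuths, slant = slants)
  members <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid$slant[i]
    spatial_rf_spec(s, covariance_from_eigen(lam_max,
                                             lam_max * cos(th)^2,
                                             grid$azimuth[i]), m)
  })
  structure(list(members = members, slant = grid$slant,
                 azimuth = grid$azimuth,
                 provenance = list(kind = "hemisphere",
                                   n_azimuth = n_azimuth,
                                   n_slant = n_slant, lam_max = lam_max,
                                   s = s, m = m)),
            class = "rf_population")
}

#' Self-similar velocity population
#'
#' Velocity magnitudes form a geometric series
#' `v_base * ratio^k, k = 0..n_levels-1`, mirrored to negative values if
#' `symmetric`, optionally including the space-time separable zero-velocity
#' member. With `v_base = 0.1, ratio = 2, n_levels = 3, symmetric` this
#' reproduces the canonical set `{-0.4, -0.2, -0.1, 0.1, 0.2, 0.4}`.
#'
#' @param v_base Smallest magnitude (> 0).
#' @param ratio Growth ratio (> 1).
#' @param n_levels Number of magnitudes.
#' @param symmetric Mirror to negative velocities.
#' @param include_zero Add the zero-velocity member.
#' @return Sorted numeric vector of velocities (1-D convention).
#' @export
velocity_population <- function(v_base = 0.1, ratio = 2, n_levels = 3L,
                                symmetric = TRUE, include_zero = FALSE) {
  stopifnot(v_base > 0, ratio > 1, n_levels >= 1)
  mags <- v_base * ratio^(seq_len(n_levels) - 1L)
  out <- if (symmetric) c(-rev(mags), mags) else mags
  if (include_zero) out <- c(out[out < 0], 0, out[out > 0])
  sort(out)
}

#' Speed of an image velocity vector
#'
#' `sqrt(v1^2 + v2^2)`; rotation invariant.
#'
#' @param v Length-2 numeric vector (or scalar, taken as 1-D velocity).
#' @return Nonnegative magnitude.
#' @export
v_speed <- function(v) {
  sqrt(sum(v^2))
}

# second moments of the squared kernel along the derivative axis, relative
# to the generating Gaussian eigenvalue: E[xi^2] = r_m * lambda, plus the
# fourth standardised moment used to identify the derivative axis.
# For weight He_m(z)^2 exp(-z^2) (z = xi / sigma):
#   m = 0: r = 1/2, kurtosis 3 (Gaussian)
#   m = 1: r = 3/2, kurtosis (15/4)/(3/2)^2 = 5/3 (bimodal)
#   m = 2: r = 7/6, kurtosis (19/4)/(7/6)^2 ~ 3.49
deriv_axis_moments <- function(m) {
  switch(m + 1L,
         list(r = 1 / 2, kurt = 3),
         list(r = 3 / 2, kurt = (15 / 4) / (3 / 2)^2),
         list(r = 7 / 6, kurt = (19 / 4) / (7 / 6)^2),
         stop("moment inversion implemented for m <= 2"))
}

#' Estimate shape parameters of a sampled receptive-field kernel
#'
#' Second moments of the squared kernel magnitude give the principal axes
#' of its energy distribution; for Gaussian-derivative kernels the mapping
#' from moment scale to the generating eigenvalues of \eqn{s\Sigma} is
#' known per derivative order and inverted analytically, so the generating
#' orientation and eccentricity are recovered. For `m >= 1` the derivative
#' axis is identified by its fourth standardised moment (bimodal along a
#' first-derivative axis, heavy-shouldered for second derivatives, Gaussian
#' elsewhere), which disambiguates near-isotropic kernels whose energy
#' principal axes swap relative to the generating axes.
#'
#' @param kernel Sampled 2-D kernel (matrix indexed `[x1, x2]`).
#' @param m Derivative order the kernel was generated with (0, 1 or 2).
#' @return List with `phi` (orientation of the major generating axis,
#'   radians in `[0, pi)`, `NA` when undefined), `sigma_major`,
#'   `sigma_minor` (generating standard deviations, grid lengths),
#'   `eccentricity` (in `(0, 1]`), `orientation_defined` flag, and
#'   `raw_ratio` (the uncanonicalised minor/major energy ratio).
#' @export
estimate_rf_params <- function(kernel, m = 0L) {
  stopifnot(is.matrix(kernel))
  w <- kernel^2
  tot <- sum(w)
  if (tot <= 0) stop("zero-energy kernel; shape parameters undefined")
  m <- as.integer(m)
  n1 <- nrow(kernel); n2 <- ncol(kernel)
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  x1 <- rep(seq_len(n1) - c1, times = n2)
  x2 <- rep(seq_len(n2) - c2, each = n1)
  ww <- as.vector(w) / tot
  mu1 <- sum(x1 * ww); mu2 <- sum(x2 * ww)
  d1 <- x1 - mu1; d2 <- x2 - mu2
  M <- matrix(c(sum(d1 * d1 * ww), sum(d1 * d2 * ww),
                sum(d1 * d2 * ww), sum(d2 * d2 * ww)), 2L, 2L)
  e <- eigen(M, symmetric = TRUE)
  mom <- deriv_axis_moments(m)
  if (m == 0L) {
    lam <- 2 * e$values            # lambda = 2 * moment for a pure Gaussian
    axis_major <- e$vectors[, 1L]
  } else {
    # project onto both principal axes and compare fourth moments with the
    # Gaussian reference to find the derivative axis
    kurt <- vapply(1:2, function(j) {
      p <- e$vectors[, j]
      z <- d1 * p[1L] + d2 * p[2L]
      sum(z^4 * ww) / sum(z^2 * ww)^2
    }, numeric(1))
    dev <- abs(kurt - 3)
    d_axis <- which.max(dev)       # derivative axis: furthest from Gaussian
    o_axis <- 3L - d_axis
    lam <- numeric(2L)
    lam[d_axis] <- e$values[d_axis] / mom$r
    lam[o_axis] <- 2 * e$values[o_axis]
    axis_major <- e$vectors[, which.max(lam)]
  }
  lam_max <- max(lam); lam_min <- min(lam)
  ecc <- sqrt(lam_min / lam_max)
  defined <- (1 - ecc) > 1e-3
  phi <- if (defined) atan2(axis_major[2L], axis_major[1L]) %% pi else NA_real_
  list(phi = phi,
       sigma_major = sqrt(lam_max), sigma_minor = sqrt(lam_min),
       eccentricity = ecc,
       orientation_defined = defined,
       raw_ratio = sqrt(lam[1L] / lam[2L]))
}

#' Eccentricity of a population member
#'
#' @param member A [spatial_rf_spec()] or [st_rf_spec()].
#' @return `eccentricity(Sigma)` of the member's covariance.
#' @keywords internal
member_eccentricity <- function(member) eccentricity(member$Sigma)

#' Population statistics for the receptive-field shape hypotheses
#'
#' Computes, for every member of a population, the eccentricity
#' \eqn{\epsilon}, the speed `v_speed` (spatio-temporal members), and the
#' scale parameters \eqn{\sigma_{space} = \sqrt{s}},
#' \eqn{\sigma_{time} = \sqrt{\tau}}, then evaluates three mutually
#' constraining verdicts about how the population spans the transformation
#' groups:
#'
#' * H1 - eccentricity variability: the spread of \eqn{\epsilon} exceeds
#'   `eps_spread_threshold` (the population covers more of the affine group
#'   than rotations/uniform scalings alone).
#' * H2 - joint 2-D spanning: the occupied cells of the
#'   \eqn{(\epsilon, v_{speed})} grid extend in both directions (at least
#'   two distinct rows and columns, with some row and column occupied more
#'   than once), and \eqn{\epsilon} is not confined to a narrow band.
#' * H3 - separate expansions: speeds vary while \eqn{\epsilon} stays
#'   within a narrow band (IQR below `eps_narrow_threshold`).
#'
#' H2 and H3 are mutually exclusive by construction.
#'
#' @param pop An `rf_population`, or a list of spec objects.
#' @param eps_breaks,v_breaks Bin edges (or counts) for the occupancy grid.
#' @param eps_spread_threshold Minimum eccentricity range for H1
#'   (default 0.2).
#' @param eps_narrow_threshold Maximum eccentricity IQR for "narrow"
#'   (default 0.05).
#' @return A `hypothesis_report`: list with per-member statistics and the
#'   H1/H2/H3 verdicts (`NA` where not evaluable).
#' @export
hypothesis_report <- function(pop, eps_breaks = 8L, v_breaks = 8L,
                              eps_spread_threshold = 0.2,
                              eps_narrow_threshold = 0.05) {
  members <- if (inherits(pop, "rf_population")) pop$members else pop
  if (length(members) == 0L) stop("empty population")
  eps <- vapply(members, member_eccentricity, numeric(1))
  has_v <- all(vapply(members, function(mb) !is.null(mb$v), logical(1)))
  speeds <- if (has_v) vapply(members, function(mb) v_speed(mb$v), numeric(1))
            else NULL
  sigma_space <- vapply(members, function(mb) sqrt(mb$s), numeric(1))
  sigma_time <- vapply(members, function(mb)
    if (!is.null(mb$tau)) sqrt(mb$tau) else NA_real_, numeric(1))
  degenerate <- length(members) < 2L
  h1 <- if (degenerate) FALSE
        else diff(range(eps)) > eps_spread_threshold
  h2 <- NA; h3 <- NA; occupancy <- NULL
  if (has_v && !degenerate) {
    eps_bin <- cut(eps, breaks = eps_breaks, include.lowest = TRUE)
    v_bin <- cut(speeds, breaks = v_breaks, include.lowest = TRUE)
    occupancy <- table(eps_bin, v_bin)
    occ <- occupancy > 0
    narrow_eps <- stats::IQR(eps) < eps_narrow_threshold
    two_d <- sum(rowSums(occ) > 0) >= 2L && sum(colSums(occ) > 0) >= 2L &&
      any(rowSums(occ) >= 2L) && any(colSums(occ) >= 2L)
    h2 <- two_d && !narrow_eps
    h3 <- (diff(range(speeds)) > 0) && narrow_eps
  } else if (has_v && degenerate) {
    h2 <- FALSE; h3 <- FALSE
  }
  structure(list(eccentricity = eps, v_speed = speeds,
                 sigma_space = sigma_space, sigma_time = sigma_time,
                 occupancy = occupancy,
                 H1 = h1, H2 = h2, H3 = h3,
                 degenerate = degenerate,
                 thresholds = list(eps_spread = eps_spread_threshold,
                                   eps_narrow = eps_narrow_threshold)),
            class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat(sprintf("hypothesis report over %d members%s\n",
              length(x$eccentricity),
              if (x$degenerate) " (degenerate population)" else ""))
  cat(sprintf("  eccentricity: [%.3g, %.3g]\n",
              min(x$eccentricity), max(x$eccentricity)))
  if (!is.null(x$v_speed))
    cat(sprintf("  v_speed: [%.3g, %.3g]\n", min(x$v_speed), max(x$v_speed)))
  cat(sprintf("  H1 (eccentricity variability): %s\n", x$H1))
  cat(sprintf("  H2 (joint 2-D spanning): %s\n", x$H2))
  cat(sprintf("  H3 (separate expansions): %s\n", x$H3))
  invisible(x)
}

#' Factorial spatio-temporal population
#'
#' Convenience generator crossing eccentricities with velocities: one
#' [st_rf_spec()] per (eccentricity, velocity) pair, used to exercise the
#' hypothesis machinery. With a single eccentricity it produces the 1-D
#' population of Hypothesis 3.
#'
#' @param eccentricities Vector of values in `(0, 1]`.
#' @param velocities Vector of 1-D velocities (mapped to `v = c(v, 0)`).
#' @param lam_max Major eigenvalue (eccentricity scales the minor one).
#' @param s,tau Scales shared by all members.
#' @return An `rf_population` of [st_rf_spec()] members.
#' @export
factorial_population <- function(eccentricities, velocities, lam_max = 4,
                                 s = 1, tau = 1) {
  stopifnot(all(eccentricities > 0), all(eccentricities <= 1))
  grid <- expand.grid(eps = eccentricities, v = velocities)
  members <- lapply(seq_len(nrow(grid)), function(i) {
    st_rf_spec(s, covariance_from_eigen(lam_max,
                                        lam_max * grid$eps[i]^2, 0),
               tau, v = c(grid$v[i], 0))
  })
  structure(list(members = members,
                 provenance = list(kind = "factorial",
                                   eccentricities = eccentricities,
                                   velocities = velocities,
                                   lam_max = lam_max, s = s, tau = tau)),
            class = "rf_population")
}

#' Orientation histogram with double-angle identification
#'
#' Receptive-field orientations are defined modulo pi (a derivative kernel
#' and its sign-flipped copy share an orientation), so histogramming uses
#' the double-angle representation `2 * phi mod 2 pi`, identifying opposite
#' directions before binning.
#'
#' @param phis Orientations in radians.
#' @param breaks Number of bins over the double-angle circle.
#' @return Table of counts per double-angle bin.
#' @export
orientation_histogram <- function(phis, breaks = 12L) {
  phis <- phis[is.finite(phis)]
  da <- (2 * phis) %% (2 * pi)
  table(cut(da, breaks = seq(0, 2 * pi, length.out = breaks + 1L),
            include.lowest = TRUE))
}
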