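test_that("covariance matrix eigen parameterisation round-trips", {
  M <- covariance_from_eigen(64, 16, 0)
  expect_equal(M$M, diag(c(64, 16)))
  M2 <- covariance_from_eigen(64, 16, pi / 2)
  expect_equal(M2$M, diag(c(16, 64)))
  expect_equal(covariance_from_eigen(1, 1, 0.7)$M, diag(2))
  # property: reconstruction and decomposition are inverse up to phi mod pi
  set.seed(42)
  for (i in 1:25) {
    lam <- sort(stats::runif(2, 0.5, 20), decreasing = TRUE)
    phi <- stats::runif(1, 0, pi)
    cv <- covariance_from_eigen(lam[1], lam[2], phi)
    back <- eigen_from_covariance(cv$M)
    expect_equal(back$lam1, lam[1], tolerance = 1e-10)
    expect_equal(back$lam2, lam[2], tolerance = 1e-10)
    d <- abs(back$phi - phi) %% pi
    expect_lt(min(d, pi - d), 1e-6)
    expect_equal(det(cv$M), lam[1] * lam[2], tolerance = 1e-10)
  }
  expect_error(covariance_from_eigen(-1, 1), "positive")
  iso <- eigen_from_covariance(diag(c(3, 3)))
  expect_true(iso$isotropic)
  expect_equal(iso$phi, 0)
})

test_that("affine Gaussian values match the closed form", {
  expect_equal(affine_gaussian_value(c(0, 0), diag(2)), 1 / (2 * pi))
  expect_equal(affine_gaussian_value(c(1, 0), diag(2)),
               exp(-0.5) / (2 * pi))
  expect_equal(affine_gaussian_value(c(0, 0), diag(c(64, 16))),
               1 / (2 * pi * 32))
  # mirror symmetry g(x) = g(-x)
  Sg <- covariance_from_eigen(5, 2, 0.4)
  x <- matrix(stats::rnorm(20), ncol = 2)
  expect_equal(affine_gaussian_value(x, Sg), affine_gaussian_value(-x, Sg))
  expect_error(affine_gaussian_value(c(0, 0), diag(c(1, 0))), "positive")
})

test_that("simple-cell kernels have the analytic masses and symmetries", {
  k0 <- spatial_rf_kernel(spatial_rf_spec(s = 1),
                          grid_spec(13, 13, truncation_radius = 6))
  expect_lt(abs(attr(k0, "mass") - 1), 1e-6)
  # first-derivative kernel: zero mass, odd under central reflection
  k1 <- spatial_rf_kernel(spatial_rf_spec(s = 2, m = 1, phi_d = 0))
  expect_lt(abs(sum(k1)), 1e-12)
  flipped <- k1[nrow(k1):1, ncol(k1):1]
  expect_equal(k1, -flipped, ignore_attr = TRUE)
  # second derivative at the centre: -1/(2 pi) for s = 1, Sigma = I
  # centre equals the analytic value up to the vanishing-moment offset
  # (truncation flux spread over the support, ~1e-6)
  k2 <- spatial_rf_kernel(spatial_rf_spec(s = 1, m = 2, phi_d = 0))
  expect_equal(centre_value(k2), -1 / (2 * pi), tolerance = 1e-5)
  # the analytic second derivative itself is exact at the origin
  expect_equal(gaussrf:::directional_gaussian_derivative(
    matrix(0, 1, 2), diag(2), c(1, 0), 2L), -1 / (2 * pi),
    tolerance = 1e-14)
  expect_error(spatial_rf_spec(s = 1, m = 5), "0..4")
  expect_warning(spatial_rf_kernel(spatial_rf_spec(s = 16), grid_spec(9, 9)),
                 "truncation")
})

test_that("LGN kernel is rotation symmetric with Laplacian centre value", {
  for (s in c(1, 2, 4)) {
    k <- lgn_spatial_kernel(s, grid = grid_spec(2L * ceiling(6 * sqrt(s)) + 1L,
                                                truncation_radius = 6))
    rot90 <- t(k)[, rev(seq_len(ncol(k)))]
    expect_identical(k[, ], rot90[, ])         # exact 90-degree symmetry
    # mass: tail-bound limited for adequately resolved kernels; at s = 1 the
    # integer sampling itself contributes at the 1e-6 level
    expect_lt(abs(attr(k, "mass")), if (s >= 2) 1e-6 else 1e-3)
    expect_equal(centre_value(k), -1 / (pi * s), tolerance = 1e-5)
    # oracle: numeric Laplacian of the closed-form Gaussian
    lap <- numeric_laplacian_origin(function(x, y)
      exp(-(x^2 + y^2) / (2 * s)) / (2 * pi * s))
    expect_equal(centre_value(k), s * lap, tolerance = 1e-6)
  }
})

test_that("spatial convolution reproduces impulses, kills constants, and is
           exact on ramps", {
  kern <- spatial_rf_kernel(spatial_rf_spec(s = 4, m = 1, phi_d = 0),
                            grid_spec(21, 21))
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  resp <- convolve_spatial(img, kern)
  expect_equal(resp[11:31, 11:31], kern, ignore_attr = TRUE,
               tolerance = 1e-12)
  const <- matrix(2.5, 41, 41)
  expect_lt(max(abs(convolve_spatial(const, kern)[15:27, 15:27])), 1e-10)
  # scale-normalised first derivative of a ramp a * x1 equals a * sqrt(s)
  x1 <- matrix(rep(seq(-32, 32), 65), 65, 65)
  resp_r <- convolve_spatial(0.5 * x1, kern)
  expect_equal(resp_r[33, 33], 0.5 * sqrt(4), tolerance = 1e-4)
  expect_error(convolve_spatial(matrix(0, 5, 5), kern), "larger")
})

test_that("sampled Gaussians obey the semigroup property", {
  g4 <- spatial_rf_kernel(spatial_rf_spec(s = 4), grid_spec(65, 65))
  g8 <- spatial_rf_kernel(spatial_rf_spec(s = 8), grid_spec(65, 65))
  conv <- convolve_spatial(g4, g4, boundary = "zero")
  expect_lt(relative_l2_test(conv, g8), 1e-3)
  # anisotropic pair
  Sa <- covariance_from_eigen(8, 2, pi / 6)
  Sb <- covariance_from_eigen(4, 3, pi / 3)
  Ssum <- eigen_from_covariance(Sa$M + Sb$M)
  ga <- spatial_rf_kernel(spatial_rf_spec(1, Sa), grid_spec(65, 65))
  gb <- spatial_rf_kernel(spatial_rf_spec(1, Sb), grid_spec(65, 65))
  gsum <- spatial_rf_kernel(spatial_rf_spec(1, Ssum), grid_spec(65, 65))
  expect_lt(relative_l2_test(convolve_spatial(ga, gb, boundary = "zero"),
                             gsum), 1e-3)
})

test_that("kernel construction is rotation equivariant", {
  Sg <- covariance_from_eigen(6, 2, 0)
  spec <- spatial_rf_spec(1, Sg, m = 1, phi_d = pi / 2)
  k <- spatial_rf_kernel(spec, grid_spec(41, 41))
  # 90-degree rotation: exact on the square grid; t(k)[, rev] realises the
  # grid rotation taking the direction (0, 1) to (1, 0)
  R <- rotation2_test(-pi / 2)
  S_rot <- eigen_from_covariance(R %*% Sg$M %*% t(R))
  k_rot_spec <- spatial_rf_kernel(
    spatial_rf_spec(1, S_rot, m = 1, phi_d = pi / 2 - pi / 2),
    grid_spec(41, 41))
  k_rot_grid <- t(k)[, rev(seq_len(41))]
  expect_equal(k_rot_spec[, ], k_rot_grid[, ], tolerance = 1e-12)
})

test_that("finite-difference gradients transform as t(A) grad under warps", {
  img <- test_noise_image(97)
  A <- affine_map(1.5, 0.2, 0, 1)
  warped <- warp_affine(img, A)
  gL <- fd_gradient(img)
  gR <- fd_gradient(warped)
  # left-domain gradient, expressed in the right domain, must equal
  # t(A) %*% (right-domain gradient)
  gL1w <- warp_affine(gL$g1, A)
  gL2w <- warp_affine(gL$g2, A)
  At <- t(A$A)
  pred1 <- At[1, 1] * gR$g1 + At[1, 2] * gR$g2
  pred2 <- At[2, 1] * gR$g1 + At[2, 2] * gR$g2
  crop <- 30:68
  expect_lt(relative_l2_test(pred1[crop, crop], gL1w[crop, crop]), 2e-2)
  expect_lt(relative_l2_test(pred2[crop, crop], gL2w[crop, crop]), 2e-2)
})
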