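test_that("hemisphere population foreshortens isotropic kernels by cos(slant)", {
  pop <- hemisphere_population(n_azimuth = 6, n_slant = 6, lam_max = 16)
  expect_length(pop$members, 36L)
  eps <- vapply(pop$members, function(m) eccentricity(m$Sigma), numeric(1))
  expect_equal(eps, cos(pop$slant), tolerance = 1e-12)
  # pole: isotropic; towards the rim: maximally anisotropic
  expect_equal(max(eps), 1)
  expect_lt(min(eps), cos(pi / 3))
  # orthographic foreshortening at 60 degrees slant gives eccentricity 1/2
  pop2 <- hemisphere_population(1, 3, 16)
  i60 <- which.min(abs(pop2$slant - pi / 3))
  expect_equal(eccentricity(pop2$members[[i60]]$Sigma), cos(pi / 3),
               tolerance = 1e-12)
  # determinism: identical provenance gives bit-identical members
  pop3 <- hemisphere_population(6, 6, 16)
  expect_identical(pop$members, pop3$members)
})

test_that("velocity population reproduces the canonical self-similar set", {
  expect_equal(velocity_population(0.1, 2, 3, symmetric = TRUE),
               c(-0.4, -0.2, -0.1, 0.1, 0.2, 0.4))
  expect_equal(velocity_population(0.1, 2, 3, symmetric = TRUE,
                                   include_zero = TRUE),
               c(-0.4, -0.2, -0.1, 0, 0.1, 0.2, 0.4))
  expect_equal(velocity_population(0.1, 2, 1, symmetric = TRUE),
               c(-0.1, 0.1))
  expect_error(velocity_population(0.1, 0.5, 3), "ratio")
})

test_that("eccentricity and speed are the invariant shape statistics", {
  expect_equal(eccentricity(covariance_from_eigen(1, 1)), 1)
  expect_equal(eccentricity(covariance_from_eigen(64, 16)), 0.5)
  set.seed(11)
  for (i in 1:10) {
    Sg <- covariance_from_eigen(stats::runif(1, 2, 9),
                                stats::runif(1, 0.5, 2),
                                stats::runif(1, 0, pi))
    th <- stats::runif(1, 0, 2 * pi)
    R <- rotation2_test(th)
    expect_equal(eccentricity(R %*% Sg$M %*% t(R)), eccentricity(Sg),
                 tolerance = 1e-10)
    expect_equal(v_speed(as.numeric(R %*% c(1, 2))), v_speed(c(1, 2)),
                 tolerance = 1e-12)
  }
  expect_equal(v_speed(c(0, 0)), 0)
  expect_equal(v_speed(c(3, 4)), 5)
})

test_that("moment analysis recovers the generating orientation and
           eccentricity of derivative kernels", {
  for (eps in c(0.25, 0.5, 1.0)) for (m in 0:2) {
    spec <- spatial_rf_spec(4, covariance_from_eigen(4, 4 * eps^2, pi / 6),
                            m)
    k <- spatial_rf_kernel(spec)
    est <- estimate_rf_params(k, m)
    expect_lt(abs(est$eccentricity - eps) / eps, 0.02)
    if (eps < 1) {
      expect_true(est$orientation_defined)
      d <- abs(est$phi - pi / 6) %% pi
      expect_lt(min(d, pi - d) * 180 / pi, 2)
    } else {
      expect_false(est$orientation_defined)
      expect_true(is.na(est$phi))
    }
  }
  # amplitude rescaling changes nothing
  k <- spatial_rf_kernel(spatial_rf_spec(4, covariance_from_eigen(4, 1, 1),
                                         1L))
  e1 <- estimate_rf_params(k, 1)
  e2 <- estimate_rf_params(17.3 * k, 1)
  expect_equal(e1$phi, e2$phi)
  expect_equal(e1$eccentricity, e2$eccentricity)
  expect_error(estimate_rf_params(matrix(0, 9, 9)), "zero-energy")
})

test_that("hypothesis verdicts separate joint from marginal expansions", {
  # factorial population spans the 2-D (eccentricity, speed) space
  joint <- factorial_population(c(0.25, 0.5, 1.0), c(0.1, 0.2, 0.4))
  rj <- hypothesis_report(joint)
  expect_true(rj$H1)
  expect_true(rj$H2)
  expect_false(rj$H3)
  # fixed eccentricity, varying speed: separate expansions
  sep <- factorial_population(0.5, c(0.1, 0.2, 0.4))
  rs <- hypothesis_report(sep)
  expect_false(rs$H2)
  expect_true(rs$H3)
  # H2 and H3 are never both true
  set.seed(13)
  for (i in 1:8) {
    eps <- stats::runif(sample(1:4, 1), 0.2, 1)
    vs <- stats::runif(sample(1:4, 1), 0.05, 0.5)
    r <- hypothesis_report(factorial_population(eps, vs))
    expect_false(isTRUE(r$H2) && isTRUE(r$H3))
  }
  # degenerate single-member population
  r1 <- hypothesis_report(factorial_population(0.5, 0.1))
  expect_true(r1$degenerate)
  expect_false(r1$H1); expect_false(r1$H2); expect_false(r1$H3)
  # purely spatial population: velocity machinery not evaluated
  rsp <- hypothesis_report(hemisphere_population(4, 4, 16))
  expect_true(is.na(rsp$H2))
  expect_null(rsp$v_speed)
  expect_error(hypothesis_report(list()), "empty")
})

test_that("orientation histogramming uses the double-angle identification", {
  h <- orientation_histogram(c(0.1, 0.1 + pi), breaks = 8)
  expect_equal(sum(h > 0), 1L)  # phi and phi + pi share a bin
  expect_equal(sum(h), 2L)
})
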