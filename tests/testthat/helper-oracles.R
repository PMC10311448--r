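# Independent numerical oracles used across the test files.

# central-difference Laplacian of a closed-form bivariate function at (0, 0)
numeric_laplacian_origin <- function(fun, h = 1e-4) {
  (fun(h, 0) + fun(-h, 0) + fun(0, h) + fun(0, -h) - 4 * fun(0, 0)) / h^2
}

# discrete quadrature moments of a sampled function on grid t
quad_moments <- function(values, t) {
  dt <- t[2] - t[1]
  m0 <- sum(values) * dt
  m1 <- sum(t * values) * dt / m0
  list(mass = m0, mean = m1,
       variance = sum((t - m1)^2 * values) * dt / m0)
}

# subpixel translation between two frames of a circularly shifted pattern,
# from the phase of the cross spectrum at the lowest nonzero frequencies
# (exact for pure circular shifts of band-limited content)
phase_shift_estimate <- function(a, b) {
  n1 <- nrow(a); n2 <- ncol(a)
  C <- stats::fft(a) * Conj(stats::fft(b))
  d1 <- Arg(C[2L, 1L]) * n1 / (2 * pi)
  d2 <- Arg(C[1L, 2L]) * n2 / (2 * pi)
  c(d1, d2)
}

# small deterministic band-limited image for warp/filter experiments
test_noise_image <- function(n = 65L, cutoff = 1 / 6, seed = 0L) {
  make_test_image(fixture_spec("band_limited_noise", size = n,
                               cutoff = cutoff, seed = seed))
}

centre_value <- function(k) k[(nrow(k) + 1L) %/% 2L, (ncol(k) + 1L) %/% 2L]

# independent relative L2 (second argument is the reference)
relative_l2_test <- function(a, b) {
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}

rotation2_test <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# full-size central-difference gradient components (replicated edges)
fd_gradient <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  list(g1 = (x[c(2:n1, n1), ] - x[c(1, 1:(n1 - 1)), ]) / 2,
       g2 = (x[, c(2:n2, n2)] - x[, c(1, 1:(n2 - 1))]) / 2)
}
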