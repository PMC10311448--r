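test_that("zero-velocity kernels are exactly space-time separable", {
  spec <- st_rf_spec(s = 1, tau = 1, v = c(0, 0))
  k <- st_rf_kernel(spec, grid_spec(11, 11), nt = 24L)
  ks <- spatial_rf_kernel(spatial_rf_spec(s = 1), grid_spec(11, 11))
  kt <- temporal_frame_kernel(1, nt = 24L)
  sep <- outer(as.vector(ks), kt)
  dim(sep) <- dim(k)
  expect_lt(max(abs(k - sep)), 1e-12)
  expect_lt(abs(attr(k, "mass") - 1), 2e-3)
})

test_that("Galilean-shearing the separable kernel approximates the
           velocity-adapted kernel", {
  u <- c(0.5, 0)
  nt <- 16L
  g0 <- st_rf_kernel(st_rf_spec(s = 2, tau = 2, v = c(0, 0)),
                     grid_spec(31, 31), nt = nt)
  gv <- st_rf_kernel(st_rf_spec(s = 2, tau = 2, v = u),
                     grid_spec(31, 31), nt = nt)
  # the adapted kernel's slice at frame t is the static slice recentred at
  # v t, which is exactly the Galilean warp of the separable kernel by v
  sheared <- warp_galilean(g0, galilean_map(u[1], u[2]))
  i <- 6:26
  expect_lt(relative_l2_test(sheared[i, i, ], gv[i, i, ]), 1e-2)
})

test_that("spatio-temporal LGN kernels are radially symmetric per slice
           with zero spatial mass and separable temporal profile", {
  k <- lgn_st_kernel(s = 2, tau = 2, v = c(0, 0), nt = 16L)
  for (j in c(1L, 5L, 10L)) {
    sl <- k[, , j]
    expect_identical(sl, t(sl)[, rev(seq_len(ncol(sl)))])  # 90-deg exact
    expect_lt(abs(sum(sl)), 1e-3)
  }
  # temporal profile at the spatial centre tracks the frame-binned kernel
  cc <- (dim(k)[1] + 1L) %/% 2L
  prof <- k[cc, cc, ]
  kt <- temporal_frame_kernel(2, nt = dim(k)[3])
  ratio <- prof[kt > 1e-4] / kt[kt > 1e-4]
  expect_lt(stats::sd(ratio) / abs(mean(ratio)), 1e-6)
  # v != 0 velocity-adapted variant is not separable
  kv <- lgn_st_kernel(s = 2, tau = 2, v = c(0.5, 0),
                      grid = grid_spec(dim(k)[1], dim(k)[2]), nt = 16L)
  expect_gt(max(abs(kv - k)), 1e-4)
})

test_that("spatio-temporal convolution reproduces impulses and kills
           constants", {
  kern <- st_rf_kernel(st_rf_spec(s = 1, tau = 1, v = c(0, 0)),
                       grid_spec(9, 9), nt = 12L)
  vid <- array(0, c(25, 25, 30)); vid[13, 13, 16] <- 1
  resp <- convolve_spatiotemporal(vid, kern)
  expect_equal(resp[9:17, 9:17, 16:27], kern, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(attr(resp, "invalid_frames"), 11L)
  const <- array(3, c(21, 21, 24))
  kd <- st_rf_kernel(st_rf_spec(s = 1, tau = 1, v = c(0, 0), m = 1, n = 1),
                     grid_spec(9, 9), nt = 12L)
  r2 <- convolve_spatiotemporal(const, kd)
  expect_lt(max(abs(r2[8:14, 8:14, 15:24])), 1e-10)
  expect_error(convolve_spatiotemporal(vid, array(0, c(31, 31, 5))), "fit")
})

test_that("matched-velocity filtering of a translating pattern equals
           shifted static filtering", {
  v <- c(1, 0)  # integer: fixture frames are exact circular rolls
  vid <- make_test_video(fixture_spec("translating_pattern", size = 49L,
                                      nt = 40L, v = v, seed = 3))
  kv <- st_rf_kernel(st_rf_spec(s = 2, tau = 2, v = v), nt = 14L)
  # the fixture rolls circularly, so convolve with matching periodic
  # boundaries and the two paths agree everywhere past the start-up frames
  resp <- convolve_spatiotemporal(vid, kv, boundary = "circular")
  # reference: filter the static pattern with the v = 0 kernel, then
  # translate along the motion
  k0 <- st_rf_kernel(st_rf_spec(s = 2, tau = 2, v = c(0, 0)),
                     grid_spec(dim(kv)[1], dim(kv)[2]), nt = 14L)
  static <- array(rep(vid[, , 1], 40L), c(49, 49, 40))
  ref <- convolve_spatiotemporal(static, k0, boundary = "circular")
  shifted <- ref
  for (k in seq_len(40)) {
    t <- k - 1
    i <- ((seq_len(49) - 1 - v[1] * t) %% 49) + 1
    shifted[, , k] <- ref[i, , k]
  }
  expect_lt(relative_l2_test(resp[, , 20:40], shifted[, , 20:40]), 1e-2)
})

test_that("velocity-adapted temporal derivative annihilates patterns
           moving at the kernel velocity", {
  v <- c(1, 0)
  vid <- make_test_video(fixture_spec("translating_pattern", size = 49L,
                                      nt = 40L, v = v, seed = 4))
  kd <- st_rf_kernel(st_rf_spec(s = 2, tau = 2, v = v, n = 1), nt = 14L)
  k0 <- st_rf_kernel(st_rf_spec(s = 2, tau = 2, v = v, n = 0), nt = 14L)
  rd <- convolve_spatiotemporal(vid, kd, boundary = "circular")
  r0 <- convolve_spatiotemporal(vid, k0, boundary = "circular")
  amp0 <- max(abs(r0[, , 20:40]))
  expect_lt(max(abs(rd[, , 20:40])) / amp0, 1e-3)
})
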