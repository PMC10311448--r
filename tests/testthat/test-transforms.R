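test_that("transformation groups compose and invert exactly", {
  set.seed(7)
  for (i in 1:20) {
    A <- affine_map(stats::runif(1, 0.5, 2), stats::runif(1, -0.5, 0.5),
                    stats::runif(1, -0.5, 0.5), stats::runif(1, 0.5, 2))
    B <- affine_map(stats::runif(1, 0.5, 2), stats::runif(1, -0.5, 0.5),
                    stats::runif(1, -0.5, 0.5), stats::runif(1, 0.5, 2))
    expect_equal(transform_compose(A, B)$A, A$A %*% B$A)
    expect_equal(transform_compose(A, transform_inverse(A))$A, diag(2),
                 tolerance = 1e-12)
    u <- galilean_map(stats::rnorm(1), stats::rnorm(1))
    w <- galilean_map(stats::rnorm(1), stats::rnorm(1))
    expect_equal(transform_compose(u, w)$u, u$u + w$u)
    expect_equal(transform_inverse(u)$u, -u$u)
    ts1 <- temporal_scaling_map(sample(-3:3, 1))
    ts2 <- temporal_scaling_map(sample(-3:3, 1))
    expect_equal(transform_compose(ts1, ts2)$S_t, ts1$S_t * ts2$S_t)
  }
  expect_equal(scaling_map(2)$A, 2 * diag(2))
  expect_equal(rotation_map(pi / 3)$A,
               matrix(c(cos(pi / 3), sin(pi / 3),
                        -sin(pi / 3), cos(pi / 3)), 2, 2))
  expect_error(affine_map(1, 1, 1, 1), "invertible")
})

test_that("affine warps are identity-exact, permutation-exact at 90 degrees,
           and scale second moments correctly", {
  img <- test_noise_image(49)
  expect_identical(warp_affine(img, affine_map(1, 0, 0, 1)), img)
  r90 <- warp_affine(img, rotation_map(pi / 2))
  expect_lt(max(abs(warp_affine(r90, rotation_map(-pi / 2)) - img)), 1e-12)
  # centred blob of std 4 maps to std 8 under A = 2I (second-moment check)
  blob <- make_test_image(fixture_spec("gaussian_blob", size = 65, std = 4))
  wb <- warp_affine(blob, scaling_map(2))
  x1 <- matrix(rep(seq(-32, 32), 65), 65, 65)
  v <- sum(x1^2 * wb) / sum(wb)
  expect_lt(abs(sqrt(v) - 8) / 8, 0.01)
  # composition within interpolation tolerance
  A <- affine_map(1.2, 0.1, 0, 1.1)
  B <- affine_map(0.9, 0, 0.2, 1)
  two <- warp_affine(warp_affine(img, B), A)
  one <- warp_affine(img, transform_compose(A, B))
  i <- 13:37
  expect_lt(relative_l2_test(two[i, i], one[i, i]), 2e-2)
  expect_error(warp_affine(img, structure(list(A = matrix(0, 2, 2)),
                                          class = "affine_map")))
})

test_that("Galilean warps shift frames by u t and compose additively", {
  vid <- array(0, c(21, 21, 8)); vid[11, 11, 5] <- 1
  w <- warp_galilean(vid, galilean_map(1, 0), interp = 1)
  expect_equal(which.max(w[, 11, 5]), 11 + 1 * 4)  # impulse at t = 4
  expect_equal(warp_galilean(vid, galilean_map(0, 0)), vid,
               ignore_attr = TRUE)
  vv <- make_test_video(fixture_spec("translating_pattern", size = 33,
                                     nt = 8, v = c(0, 0), seed = 5))
  two <- warp_galilean(warp_galilean(vv, galilean_map(0.3, 0.1)),
                       galilean_map(0.2, -0.1))
  one <- warp_galilean(vv, galilean_map(0.5, 0))
  i <- 9:25
  expect_lt(relative_l2_test(two[i, i, ], one[i, i, ]), 2e-2)
})

test_that("temporal rescaling moves events to S_t * t and round-trips", {
  vid <- array(0, c(5, 5, 17)); vid[3, 3, 5] <- 1  # event at t = 4
  w <- warp_temporal_scale(vid, temporal_scaling_map(2))
  expect_equal(which.max(w[3, 3, ]), 9L)           # now at t = 8
  expect_identical(warp_temporal_scale(vid, temporal_scaling_map(0)), vid)
  vv <- make_test_video(fixture_spec("flashing_blob", size = 17, nt = 33,
                                     event_frame = 16, event_std = 3))
  fwd <- warp_temporal_scale(vv, temporal_scaling_map(1))
  back <- warp_temporal_scale(fwd, temporal_scaling_map(-1))
  # the round trip is only defined where the forward warp kept the content
  # in range: frames up to (nt - 1) / S_t
  expect_lt(relative_l2_test(back[, , 5:22], vv[, , 5:22]), 2e-2)
})

test_that("derivative vectors transform with the transposed map", {
  expect_equal(transform_derivative_vector(c(1, 2), affine_map(1, 0, 0, 1)),
               c(1, 2))
  expect_equal(transform_derivative_vector(c(3, 5), affine_map(2, 0, 0, 1)),
               c(6, 5))
  g <- galilean_map(0.5, -0.2)
  out <- transform_derivative_vector(c(1, 2, 3), g)
  expect_equal(out[1:2], c(1, 2))                      # spatial unchanged
  expect_equal(out[3], 0.5 * 1 + (-0.2) * 2 + 3)        # u . grad + dt
  expect_error(transform_derivative_vector(c(1, 2), g), "3-vectors")
  expect_error(transform_derivative_vector(c(1, 2, 3),
                                           affine_map(1, 0, 0, 1)),
               "2-vectors")
})

test_that("transforms serialise to JSON and back", {
  maps <- list(affine_map(1.5, 0.25, -0.1, 0.9),
               galilean_map(0.5, -1),
               temporal_scaling_map(2, c = sqrt(2)))
  for (mp in maps) {
    js <- transform_to_json(mp)
    back <- transform_from_json(js)
    expect_equal(unclass(back), unclass(mp), tolerance = 1e-12)
  }
  expect_match(as.character(transform_to_json(maps[[2]])),
               '"type":"galilean"')
  expect_error(transform_from_json('{"type":"projective"}'), "unknown")
})
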