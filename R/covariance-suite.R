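#' LGN receptive-field specifications
#'
#' Lightweight specs for the rotationally symmetric (Laplacian-of-Gaussian)
#' models, used by the covariance suite alongside [spatial_rf_spec()] and
#' [st_rf_spec()]. The spatial LGN model is covariant under rotations and
#' uniform scalings but - unlike the affine Gaussian simple-cell model -
#' cannot be made covariant under anisotropic affine maps, because its
#' smoothing kernel is rotationally symmetric. The spatio-temporal model
#' with `v != 0` is the velocity-adapted (Galilean covariant) variant; with
#' `v = 0` it is space-time separable and not Galilean covariant.
#'
#' @param s Spatial scale.
#' @param sign Leading sign, +1 or -1.
#' @param tau,c,K,n,v,causal As in [st_rf_spec()].
#' @return Objects of class `lgn_spatial_spec` / `lgn_st_spec`.
#' @export
lgn_spatial_spec <- function(s = 4, sign = +1) {
  stopifnot(s > 0, sign %in% c(-1, 1))
  structure(list(s = s, sign = sign), class = "lgn_spatial_spec")
}

#' @rdname lgn_spatial_spec
#' @export
lgn_st_spec <- function(s = 4, tau = 4, c = sqrt(2), K = 12L, n = 0L,
                        v = c(0, 0), sign = +1, causal = TRUE) {
  stopifnot(s > 0, tau > 0, c > 1, sign %in% c(-1, 1), length(v) == 2L)
  structure(list(s = s, tau = tau, c = c, K = as.integer(K),
                 n = as.integer(n), v = as.numeric(v), sign = sign,
                 causal = causal),
            class = "lgn_st_spec")
}

is_spatial_spec <- function(spec)
  inherits(spec, c("spatial_rf_spec", "lgn_spatial_spec"))
is_st_spec <- function(spec) inherits(spec, c("st_rf_spec", "lgn_st_spec"))
is_lgn_spec <- function(spec)
  inherits(spec, c("lgn_spatial_spec", "lgn_st_spec"))

# TRUE when A is a similarity (uniform scaling x rotation): t(A) A = lambda I
is_conformal <- function(A, tol = 1e-12) {
  M <- t(A$A) %*% A$A
  abs(M[1, 2]) <= tol * M[1, 1] && abs(M[1, 1] - M[2, 2]) <= tol * M[1, 1]
}

#' Parameter-matching laws for the commutative diagrams
#'
#' Given a left-domain receptive-field spec and a transformation, these
#' return the right-domain spec whose filter output can be matched exactly
#' to the transformed left output (in the continuous theory):
#'
#' * affine `A`: `Sigma_R = A Sigma_L t(A)`; spatio-temporal specs also get
#'   `v_R = A v_L`; `s`, `tau` unchanged.
#' * uniform scaling `S_x`: `s_R = S_x^2 s_L`, `Sigma` unchanged;
#'   spatio-temporal specs also get `v_R = S_x v_L`.
#' * Galilean `u`: `v' = v + u`; everything else unchanged.
#' * temporal scaling `S_t = c^i` (same `c` as the kernel):
#'   `tau' = S_t^2 tau`, `v' = v / S_t`; `s`, `Sigma` unchanged.
#'
#' @param left A receptive-field spec.
#' @param A An [affine_map()].
#' @return A `matched_params` object with fields `left`, `right`,
#'   `transform`.
#' @export
match_affine <- function(left, A) {
  stopifnot(inherits(A, "affine_map"))
  right <-
    if (inherits(left, "spatial_rf_spec")) {
      SR <- eigen_from_covariance(A$A %*% left$Sigma$M %*% t(A$A))
      phi_d <- if (is_conformal(A)) {
        ud <- A$A %*% c(cos(left$phi_d), sin(left$phi_d))
        atan2(ud[2L], ud[1L])
      } else NULL
      spatial_rf_spec(left$s, SR, left$m, phi_d)
    } else if (inherits(left, "st_rf_spec")) {
      SR <- eigen_from_covariance(A$A %*% left$Sigma$M %*% t(A$A))
      phi_d <- if (is_conformal(A)) {
        ud <- A$A %*% c(cos(left$phi_d), sin(left$phi_d))
        atan2(ud[2L], ud[1L])
      } else NULL
      st_rf_spec(left$s, SR, left$tau, left$c, left$K,
                 as.numeric(A$A %*% left$v), left$m, left$n, phi_d,
                 left$causal)
    } else if (is_lgn_spec(left)) {
      if (!is_conformal(A))
        stop("rotationally symmetric LGN kernels admit no affine matching; ",
             "only rotations and uniform scalings are covariant")
      Sx2 <- (t(A$A) %*% A$A)[1, 1]
      if (inherits(left, "lgn_spatial_spec")) {
        lgn_spatial_spec(Sx2 * left$s, left$sign)
      } else {
        lgn_st_spec(Sx2 * left$s, left$tau, left$c, left$K, left$n,
                    as.numeric(A$A %*% left$v), left$sign, left$causal)
      }
    } else stop("unsupported spec for affine matching")
  structure(list(left = left, right = right, transform = A),
            class = "matched_params")
}

#' @rdname match_affine
#' @param S_x Uniform spatial scaling factor (> 0).
#' @export
match_spatial_scaling <- function(left, S_x) {
  stopifnot(is.numeric(S_x), S_x > 0)
  right <-
    if (inherits(left, "spatial_rf_spec")) {
      spatial_rf_spec(S_x^2 * left$s, left$Sigma, left$m, left$phi_d)
    } else if (inherits(left, "st_rf_spec")) {
      st_rf_spec(S_x^2 * left$s, left$Sigma, left$tau, left$c, left$K,
                 S_x * left$v, left$m, left$n, left$phi_d, left$causal)
    } else if (inherits(left, "lgn_spatial_spec")) {
      lgn_spatial_spec(S_x^2 * left$s, left$sign)
    } else if (inherits(left, "lgn_st_spec")) {
      lgn_st_spec(S_x^2 * left$s, left$tau, left$c, left$K, left$n,
                  S_x * left$v, left$sign, left$causal)
    } else stop("unsupported spec for scaling matching")
  structure(list(left = left, right = right, transform = scaling_map(S_x)),
            class = "matched_params")
}

#' @rdname match_affine
#' @param u A [galilean_map()].
#' @export
match_galilean <- function(left, u) {
  stopifnot(inherits(u, "galilean_map"), is_st_spec(left))
  right <- if (inherits(left, "st_rf_spec")) {
    st_rf_spec(left$s, left$Sigma, left$tau, left$c, left$K,
               left$v + u$u, left$m, left$n, left$phi_d, left$causal)
  } else {
    lgn_st_spec(left$s, left$tau, left$c, left$K, left$n,
                left$v + u$u, left$sign, left$causal)
  }
  structure(list(left = left, right = right, transform = u),
            class = "matched_params")
}

#' @rdname match_affine
#' @param ts A [temporal_scaling_map()]; its `c` must equal the kernel's.
#' @export
match_temporal_scaling <- function(left, ts) {
  stopifnot(inherits(ts, "temporal_scaling_map"), is_st_spec(left))
  if (!isTRUE(all.equal(ts$c, left$c)))
    stop("temporal scaling is only a valid matching for S_t = c^i with the ",
         "kernel's own distribution parameter c")
  right <- if (inherits(left, "st_rf_spec")) {
    st_rf_spec(left$s, left$Sigma, ts$S_t^2 * left$tau, left$c, left$K,
               left$v / ts$S_t, left$m, left$n, left$phi_d, left$causal)
  } else {
    lgn_st_spec(left$s, ts$S_t^2 * left$tau, left$c, left$K, left$n,
                left$v / ts$S_t, left$sign, left$causal)
  }
  structure(list(left = left, right = right, transform = ts),
            class = "matched_params")
}

# dispatch: build the kernel for any supported spec
build_spatial_kernel <- function(spec, grid = NULL) {
  if (inherits(spec, "spatial_rf_spec")) spatial_rf_kernel(spec, grid)
  else lgn_spatial_kernel(spec$s, grid, spec$sign)
}

build_st_kernel <- function(spec, grid = NULL, nt = NULL, oversample = 4L) {
  if (inherits(spec, "st_rf_spec"))
    st_rf_kernel(spec, grid, nt, oversample)
  else
    lgn_st_kernel(spec$s, spec$tau, spec$c, spec$K, spec$n, spec$v,
                  grid, nt, oversample, spec$sign, spec$causal)
}

# Relative L2 over the clean region of a Galilean diagram. The warp fill
# contaminates a strip that grows as u * t on the side the content leaves,
# and the velocity-swept kernel's boundary handling contaminates a fixed
# strip of the full (swept) kernel half-width `hw_full` on the side it
# trails; elsewhere the per-slice support radius `hw_s` suffices. The clean
# region is therefore a parallelogram in space-time; frames with an empty
# clean region and the causal start-up frames are excluded.
galilean_masked_l2 <- function(a, b, hw_full, hw_s, u, t_start) {
  d <- dim(a)
  num <- 0; den <- 0
  lohi <- function(uj, t) {
    lo <- max(if (uj > 0) hw_full else hw_s, hw_s + max(0, ceiling(uj * t)))
    hi <- max(if (uj < 0) hw_full else hw_s, hw_s + max(0, ceiling(-uj * t)))
    c(lo, hi)
  }
  for (k in seq.int(t_start + 1L, d[3L])) {
    t <- k - 1
    m1 <- lohi(u[1L], t); m2 <- lohi(u[2L], t)
    if (m1[1] + m1[2] >= d[1L] - 2 || m2[1] + m2[2] >= d[2L] - 2) next
    i1 <- (m1[1] + 1L):(d[1L] - m1[2]); i2 <- (m2[1] + 1L):(d[2L] - m2[2])
    aa <- a[i1, i2, k]; bb <- b[i1, i2, k]
    num <- num + sum((aa - bb)^2)
    den <- den + sum(aa^2)
  }
  if (den == 0) stop("empty or zero-signal clean region; residual undefined")
  sqrt(num / den)
}

# Smallest crop margin such that the preimage of the interior crop square
# under the warp stays at least a kernel half-width away from the image
# border (so both diagram paths are free of boundary and start-up effects).
# The affine image of a square is a parallelogram, so its corners suffice.
affine_crop_margin <- function(A, n, hw) {
  Ainv <- solve(A$A)
  r_lim <- (n - 1) / 2 - hw
  for (mm in seq.int(hw, (n - 5) %/% 2)) {
    r <- (n - 1) / 2 - mm
    corners <- rbind(c(r, r), c(r, -r), c(-r, r), c(-r, -r))
    pre <- corners %*% t(Ainv)
    if (max(abs(pre)) <= r_lim) return(mm)
  }
  stop("interior crop is empty for this image size / kernel / warp")
}

# default matching for a (spec, transform) pair
default_match <- function(left, transform) {
  if (inherits(transform, "affine_map")) {
    if (is_conformal(transform)) {
      Sx2 <- (t(transform$A) %*% transform$A)[1, 1]
      rot <- transform$A / sqrt(Sx2)
      if (isTRUE(all.equal(sqrt(Sx2), 1))) match_affine(left, transform)
      else if (isTRUE(all.equal(rot, diag(2))))
        match_spatial_scaling(left, sqrt(Sx2))
      else {  # rotation * scaling: compose the two laws
        m1 <- match_spatial_scaling(left, sqrt(Sx2))
        m2 <- match_affine(m1$right, affine_map(rot[1, 1], rot[1, 2],
                                                rot[2, 1], rot[2, 2]))
        structure(list(left = left, right = m2$right, transform = transform),
                  class = "matched_params")
      }
    } else match_affine(left, transform)
  } else if (inherits(transform, "galilean_map")) {
    match_galilean(left, transform)
  } else if (inherits(transform, "temporal_scaling_map")) {
    match_temporal_scaling(left, transform)
  } else stop("unsupported transform")
}

#' Commutative-diagram residual: filter-then-warp vs warp-then-filter
#'
#' Computes path A = warp(filter(input, `left_spec`)) and path B =
#' filter(warp(input), matched right spec) and returns their relative L2
#' distance over an interior crop whose margin excludes kernel support,
#' warp displacement, and (for causal kernels) the temporal start-up
#' region. For derivative responses under anisotropic affine maps the two
#' gradient components are compared as properly transformed vectors
#' (`grad_L = t(A) grad_R`); under similarities, Galilean and temporal
#' scaling transforms, the scale-normalised (and velocity-adapted) scalar
#' responses are directly comparable and compared as such.
#'
#' @param input 2-D image (spatial specs) or 3-D video (spatio-temporal).
#' @param left_spec Receptive-field spec for the untransformed domain.
#' @param transform An [affine_map()], [galilean_map()] or
#'   [temporal_scaling_map()].
#' @param right_spec Override for the matched right spec (used by negative
#'   controls); default `NULL` applies the matching laws.
#' @param interp Interpolation order for warps (3 or 1).
#' @param nt_kernel Temporal kernel length in frames for video specs;
#'   `NULL` (default) sizes each kernel to its own temporal support.
#' @param oversample Temporal oversampling for kernel synthesis.
#' @return The residual (dimensionless), with attribute `margins`.
#' @export
covariance_residual <- function(input, left_spec, transform,
                                right_spec = NULL, interp = 3L,
                                nt_kernel = NULL, oversample = 4L) {
  if (is.null(right_spec)) right_spec <- default_match(left_spec, transform)$right
  if (is_spatial_spec(left_spec)) {
    stopifnot(is.matrix(input), inherits(transform, "affine_map"))
    covariance_residual_spatial(input, left_spec, right_spec, transform,
                                interp)
  } else if (is_st_spec(left_spec)) {
    stopifnot(length(dim(input)) == 3L)
    covariance_residual_st(input, left_spec, right_spec, transform, interp,
                           nt_kernel, oversample)
  } else stop("unsupported spec")
}

covariance_residual_spatial <- function(f, left, right, A, interp) {
  kL <- build_spatial_kernel(left)
  kR <- build_spatial_kernel(right)
  hw <- max((dim(kL)[1] - 1) %/% 2, (dim(kR)[1] - 1) %/% 2)
  margin <- affine_crop_margin(A, nrow(f), hw)
  m <- if (inherits(left, "spatial_rf_spec")) left$m else 0L
  tensor <- !is_conformal(A) && m >= 1L
  if (!tensor) {
    pathA <- warp_affine(convolve_spatial(f, kL), A, interp)
    fw <- warp_affine(f, A, interp)
    pathB <- convolve_spatial(fw, kR)
    res <- relative_l2(pathA, pathB, margin)
  } else {
    if (m > 1L)
      stop("tensor comparison under anisotropic affine maps is implemented ",
           "for first-order derivatives only")
    # gradient route: compare grad_L(path A) with t(A) grad_R(path B)
    gradL <- lapply(c(0, pi / 2), function(phi)
      convolve_spatial(f, spatial_rf_kernel(
        spatial_rf_spec(left$s, left$Sigma, 1L, phi))))
    pathA <- lapply(gradL, warp_affine, A = A, interp = interp)
    fw <- warp_affine(f, A, interp)
    gradR <- lapply(c(0, pi / 2), function(phi)
      convolve_spatial(fw, spatial_rf_kernel(
        spatial_rf_spec(right$s, right$Sigma, 1L, phi))))
    At <- t(A$A)
    pathB <- list(At[1, 1] * gradR[[1]] + At[1, 2] * gradR[[2]],
                  At[2, 1] * gradR[[1]] + At[2, 2] * gradR[[2]])
    # stack the two components so the residual is over the full vector field
    stackA <- array(c(pathA[[1]], pathA[[2]]), c(dim(f), 2L))
    stackB <- array(c(pathB[[1]], pathB[[2]]), c(dim(f), 2L))
    res <- relative_l2(stackA, stackB, margin = c(margin, margin, 0L))
  }
  attr(res, "margins") <- margin
  res
}

covariance_residual_st <- function(f, left, right, transform, interp,
                                   nt_kernel, oversample) {
  d <- dim(f)
  kL <- build_st_kernel(left, nt = nt_kernel, oversample = oversample)
  kR <- build_st_kernel(right, nt = nt_kernel, oversample = oversample)
  hw <- max((dim(kL)[1] - 1) %/% 2, (dim(kR)[1] - 1) %/% 2)
  startupL <- dim(kL)[3] - 1L
  startupR <- dim(kR)[3] - 1L
  if (inherits(transform, "affine_map")) {
    m <- if (inherits(left, "st_rf_spec")) left$m else 0L
    margin_s <- affine_crop_margin(transform, d[1], hw)
    tensor <- !is_conformal(transform) && m >= 1L
    if (tensor && m > 1L)
      stop("tensor comparison under anisotropic affine maps is implemented ",
           "for first-order derivatives only")
    warpf <- function(v) {
      out <- v
      for (k in seq_len(d[3])) out[, , k] <- warp_affine(v[, , k], transform,
                                                         interp)
      out
    }
    if (!tensor) {
      pathA <- warpf(convolve_spatiotemporal(f, kL))
      pathB <- convolve_spatiotemporal(warpf(f), kR)
      res <- relative_l2(pathA, pathB,
                         margin_lo = c(margin_s, margin_s,
                                       max(startupL, startupR)),
                         margin_hi = c(margin_s, margin_s, 0L))
    } else {
      gradL <- lapply(c(0, pi / 2), function(phi)
        convolve_spatiotemporal(f, build_st_kernel(
          st_rf_spec(left$s, left$Sigma, left$tau, left$c, left$K, left$v,
                     1L, left$n, phi, left$causal),
          nt = nt_kernel, oversample = oversample)))
      pathA <- lapply(gradL, warpf)
      fw <- warpf(f)
      gradR <- lapply(c(0, pi / 2), function(phi)
        convolve_spatiotemporal(fw, build_st_kernel(
          st_rf_spec(right$s, right$Sigma, right$tau, right$c, right$K,
                     right$v, 1L, right$n, phi, right$causal),
          nt = nt_kernel, oversample = oversample)))
      At <- t(transform$A)
      pathB <- list(At[1, 1] * gradR[[1]] + At[1, 2] * gradR[[2]],
                    At[2, 1] * gradR[[1]] + At[2, 2] * gradR[[2]])
      stackA <- array(c(pathA[[1]], pathA[[2]]), c(d, 2L))
      stackB <- array(c(pathB[[1]], pathB[[2]]), c(d, 2L))
      res <- relative_l2(stackA, stackB,
                         margin_lo = c(margin_s, margin_s,
                                       max(startupL, startupR), 0L),
                         margin_hi = c(margin_s, margin_s, 0L, 0L))
    }
    attr(res, "margins") <- margin_s
    res
  } else if (inherits(transform, "galilean_map")) {
    pathA <- warp_galilean(convolve_spatiotemporal(f, kL), transform, interp)
    pathB <- convolve_spatiotemporal(warp_galilean(f, transform, interp), kR)
    lam1 <- if (inherits(left, "st_rf_spec")) left$Sigma$lam1 else 1
    hw_s <- ceiling(5 * sqrt(left$s * lam1)) + 3L
    res <- galilean_masked_l2(pathA, pathB, hw + 2L, hw_s, transform$u,
                              max(startupL, startupR))
    attr(res, "margins") <- c(hw + 2L, hw_s)
    res
  } else if (inherits(transform, "temporal_scaling_map")) {
    margin_s <- ceiling(hw)
    St <- transform$S_t
    t_start <- ceiling(max(St * startupL, startupR, startupL)) + 2L
    pathA <- warp_temporal_scale(convolve_spatiotemporal(f, kL), transform,
                                 interp)
    pathB <- convolve_spatiotemporal(warp_temporal_scale(f, transform,
                                                         interp), kR)
    res <- relative_l2(pathA, pathB,
                       margin_lo = c(margin_s, margin_s, t_start),
                       margin_hi = c(margin_s, margin_s, 2L))
    attr(res, "margins") <- c(margin_s, t_start)
    res
  } else stop("unsupported transform for spatio-temporal specs")
}
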