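#' Natural image transformations
#'
#' Constructors for the four transformation groups the receptive-field
#' families are covariant under: spatial affine maps (with spatial scalings
#' and rotations as special cases), Galilean maps (constant-velocity
#' space-time shears), and temporal scalings by integer powers of the limit
#' kernel's distribution parameter.
#'
#' @param a11,a12,a21,a22 Entries of the invertible 2x2 affine matrix.
#' @return An object of class `affine_map` with fields `a11..a22` and the
#'   matrix `A`.
#' @seealso [scaling_map()], [rotation_map()], [galilean_map()],
#'   [temporal_scaling_map()]
#' @export
affine_map <- function(a11, a12, a21, a22) {
  A <- matrix(c(a11, a21, a12, a22), 2L, 2L)
  if (abs(det(A)) < .Machine$double.eps^0.5)
    stop("affine map must be invertible")
  structure(list(a11 = a11, a12 = a12, a21 = a21, a22 = a22, A = A),
            class = "affine_map")
}

#' @rdname affine_map
#' @param Sx Uniform spatial scaling factor (> 0).
#' @export
scaling_map <- function(Sx) {
  stopifnot(Sx > 0)
  affine_map(Sx, 0, 0, Sx)
}

#' @rdname affine_map
#' @param theta Rotation angle, radians.
#' @export
rotation_map <- function(theta) {
  affine_map(cos(theta), -sin(theta), sin(theta), cos(theta))
}

#' @param u1,u2 Velocity components, pixels/frame.
#' @rdname affine_map
#' @export
galilean_map <- function(u1, u2 = 0) {
  stopifnot(is.finite(u1), is.finite(u2))
  structure(list(u1 = u1, u2 = u2, u = c(u1, u2)), class = "galilean_map")
}

#' @param i Integer exponent of the temporal scaling factor.
#' @param c Distribution parameter (> 1); the factor is `S_t = c^i`.
#' @rdname affine_map
#' @export
temporal_scaling_map <- function(i, c = sqrt(2)) {
  stopifnot(i == round(i), c > 1)
  structure(list(i = as.integer(i), c = c, S_t = c^i),
            class = "temporal_scaling_map")
}

#' Compose or invert transformations
#'
#' Affine maps compose by matrix product, Galilean maps by velocity
#' addition, temporal scalings by exponent addition (all exact algebra).
#'
#' @param f,g Transformations of the same class.
#' @return The composed map `f o g` (apply `g` first), or the inverse.
#' @export
transform_compose <- function(f, g) {
  stopifnot(identical(class(f), class(g)))
  if (inherits(f, "affine_map")) {
    M <- f$A %*% g$A
    affine_map(M[1, 1], M[1, 2], M[2, 1], M[2, 2])
  } else if (inherits(f, "galilean_map")) {
    galilean_map(f$u1 + g$u1, f$u2 + g$u2)
  } else if (inherits(f, "temporal_scaling_map")) {
    if (!isTRUE(all.equal(f$c, g$c))) stop("temporal scalings must share c")
    temporal_scaling_map(f$i + g$i, f$c)
  } else stop("unknown transform class")
}

#' @rdname transform_compose
#' @export
transform_inverse <- function(f) {
  if (inherits(f, "affine_map")) {
    M <- solve(f$A)
    affine_map(M[1, 1], M[1, 2], M[2, 1], M[2, 2])
  } else if (inherits(f, "galilean_map")) {
    galilean_map(-f$u1, -f$u2)
  } else if (inherits(f, "temporal_scaling_map")) {
    temporal_scaling_map(-f$i, f$c)
  } else stop("unknown transform class")
}

#' Warp an image by a spatial affine map
#'
#' Produces the transformed image `f_R` with `f_R(x_R) = f_L(x_L)` for
#' `x_R = A x_L`, by inverse mapping about the image centre with
#' interpolation. Out-of-domain samples are filled by mirror reflection.
#'
#' @param image 2-D array indexed `[x1, x2]`.
#' @param A An [affine_map()].
#' @param interp Interpolation order: 3 (bicubic, default) or 1 (bilinear).
#' @return Warped image, same shape.
#' @export
warp_affine <- function(image, A, interp = 3L) {
  stopifnot(inherits(A, "affine_map"), is.matrix(image))
  n1 <- nrow(image); n2 <- ncol(image)
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  Ainv <- solve(A$A)
  y1 <- rep(seq_len(n1), times = n2) - c1
  y2 <- rep(seq_len(n2), each = n1) - c2
  src1 <- Ainv[1, 1] * y1 + Ainv[1, 2] * y2 + c1
  src2 <- Ainv[2, 1] * y1 + Ainv[2, 2] * y2 + c2
  matrix(interp2(image, src1, src2, interp), n1, n2)
}

#' Warp a video by a Galilean transformation
#'
#' Frame at time `t` (frames counted from 0) is shifted spatially by
#' `u * t`: `f'(x, t) = f(x - u t, t)`. Displacements that sweep content
#' beyond the spatial extent are filled by reflection and flagged.
#'
#' @param video 3-D array `[x1, x2, t]`.
#' @param g A [galilean_map()].
#' @param interp Interpolation order, 3 or 1.
#' @return Warped video with attribute `cropped` (TRUE when the total
#'   displacement exceeds half the spatial extent).
#' @export
warp_galilean <- function(video, g, interp = 3L) {
  stopifnot(inherits(g, "galilean_map"), length(dim(video)) == 3L)
  d <- dim(video)
  nt <- d[3L]
  disp <- max(abs(g$u)) * (nt - 1)
  out <- video
  for (k in seq_len(nt)) {
    t <- k - 1
    if (t == 0 || (g$u1 == 0 && g$u2 == 0)) next
    n1 <- d[1L]; n2 <- d[2L]
    p1 <- rep(seq_len(n1), times = n2) - g$u1 * t
    p2 <- rep(seq_len(n2), each = n1) - g$u2 * t
    out[, , k] <- matrix(interp2(video[, , k], p1, p2, interp), n1, n2)
  }
  attr(out, "cropped") <- disp > min(d[1:2]) / 2
  out
}

#' Rescale the temporal axis of a video
#'
#' Content at time `t` appears at `t' = S_t t` (frames counted from 0):
#' `f'(x, t') = f(x, t' / S_t)`, realised by interpolated resampling along
#' the temporal axis. Values are interpolated with no density rescaling
#' (the function-composition reading of the transformation). The number of
#' frames is unchanged.
#'
#' @param video 3-D array `[x1, x2, t]`.
#' @param ts A [temporal_scaling_map()].
#' @param interp Interpolation order along `t`, 3 or 1.
#' @return Time-rescaled video, same shape.
#' @export
warp_temporal_scale <- function(video, ts, interp = 3L) {
  stopifnot(inherits(ts, "temporal_scaling_map"), length(dim(video)) == 3L)
  if (ts$S_t == 1) return(video)
  d <- dim(video)
  nt <- d[3L]
  src <- 1 + (seq_len(nt) - 1) / ts$S_t  # source slice for each output slice
  out <- array(0, d)
  if (interp == 1L) {
    i0 <- pmin(pmax(floor(src), 1), nt - 1); f <- src - i0
    for (k in seq_len(nt))
      out[, , k] <- (1 - f[k]) * video[, , i0[k]] + f[k] * video[, , i0[k] + 1]
  } else {
    i0 <- floor(src); f <- src - i0
    for (k in seq_len(nt)) {
      acc <- array(0, d[1:2])
      for (dd in -1:2)
        acc <- acc + keys_w(dd - f[k]) * video[, , fold_int(i0[k] + dd, nt)]
      out[, , k] <- acc
    }
  }
  out
}

#' Transform a derivative vector between image domains
#'
#' Maps right-domain (transformed-domain) partial derivatives to left-domain
#' ones. Under a spatial affine map the gradients satisfy
#' `grad_L = t(A) %*% grad_R`; under a Galilean map the spatio-temporal
#' gradients satisfy `grad = t(G) %*% grad'`, where the spatial components
#' pass through unchanged and the temporal component gains
#' `u1 * d/dx1' + u2 * d/dx2'`.
#'
#' @param grad Length-2 (spatial) or length-3 (spatio-temporal, ordered
#'   `x1, x2, t`) numeric vector of partial derivatives in the transformed
#'   domain.
#' @param map An [affine_map()] (length-2) or [galilean_map()] (length-3).
#' @return Transformed derivative vector in the original domain.
#' @export
transform_derivative_vector <- function(grad, map) {
  if (inherits(map, "affine_map")) {
    if (length(grad) != 2L) stop("affine maps act on 2-vectors of derivatives")
    as.numeric(t(map$A) %*% grad)
  } else if (inherits(map, "galilean_map")) {
    if (length(grad) != 3L)
      stop("Galilean maps act on 3-vectors of derivatives")
    G <- rbind(c(1, 0, map$u1), c(0, 1, map$u2), c(0, 0, 1))
    as.numeric(t(G) %*% grad)
  } else stop("unsupported map kind for derivative transformation")
}

#' Serialise and deserialise transformations as JSON
#'
#' Schema: `{"type": "affine", "a11": ., "a12": ., "a21": ., "a22": .}`,
#' `{"type": "galilean", "u1": ., "u2": .}`,
#' `{"type": "temporal_scale", "i": ., "c": .}`.
#'
#' @param map A transformation object.
#' @return `transform_to_json()`: a JSON string; `transform_from_json()`:
#'   the reconstructed transformation.
#' @export
transform_to_json <- function(map) {
  x <- if (inherits(map, "affine_map")) {
    list(type = "affine", a11 = map$a11, a12 = map$a12,
         a21 = map$a21, a22 = map$a22)
  } else if (inherits(map, "galilean_map")) {
    list(type = "galilean", u1 = map$u1, u2 = map$u2)
  } else if (inherits(map, "temporal_scaling_map")) {
    list(type = "temporal_scale", i = map$i, c = map$c)
  } else stop("unknown transform class")
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname transform_to_json
#' @param json A JSON string produced by [transform_to_json()].
#' @export
transform_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  switch(x$type,
         affine = affine_map(x$a11, x$a12, x$a21, x$a22),
         galilean = galilean_map(x$u1, x$u2),
         temporal_scale = temporal_scaling_map(x$i, x$c),
         stop("unknown transform type: ", x$type))
}
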