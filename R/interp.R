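# Interpolated sampling of images at arbitrary (fractional) positions,
# with out-of-domain coordinates folded back by mirror reflection
# (consistent with the reflect boundary mode used for convolution).
#
# order 1: bilinear; order 3: Keys bicubic convolution (a = -1/2), an
# interpolating kernel (exact at integer sample positions).

# mirror-fold a (possibly fractional) coordinate into [1, n]
fold_coord <- function(p, n) {
  if (n == 1L) return(rep_len(1, length(p)))
  period <- 2 * (n - 1)
  q <- (p - 1) %% period
  1 + (n - 1) - abs(q - (n - 1))
}

# Keys cubic weight, a = -1/2
keys_w <- function(x) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  w[i1] <- (1.5 * ax[i1] - 2.5) * ax[i1]^2 + 1
  i2 <- ax > 1 & ax < 2
  w[i2] <- -0.5 * (ax[i2]^3 - 5 * ax[i2]^2 + 8 * ax[i2] - 4)
  w
}

# Sample a matrix at fractional positions (px, py) in 1-based array
# coordinates (first index = x1). Returns a vector of values.
interp2 <- function(img, px, py, order = 3L) {
  n1 <- nrow(img); n2 <- ncol(img)
  px <- fold_coord(px, n1)
  py <- fold_coord(py, n2)
  if (order == 1L) {
    i0 <- pmin(pmax(floor(px), 1), n1 - 1); fx <- px - i0
    j0 <- pmin(pmax(floor(py), 1), n2 - 1); fy <- py - j0
    v00 <- img[cbind(i0, j0)];     v10 <- img[cbind(i0 + 1, j0)]
    v01 <- img[cbind(i0, j0 + 1)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
    (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
      (1 - fx) * fy * v01 + fx * fy * v11
  } else if (order == 3L) {
    i0 <- floor(px); fx <- px - i0
    j0 <- floor(py); fy <- py - j0
    out <- numeric(length(px))
    for (di in -1:2) {
      ii <- fold_int(i0 + di, n1)
      wx <- keys_w(di - fx)
      for (dj in -1:2) {
        jj <- fold_int(j0 + dj, n2)
        wy <- keys_w(dj - fy)
        out <- out + wx * wy * img[cbind(ii, jj)]
      }
    }
    out
  } else stop("interpolation order must be 1 or 3")
}

# mirror-fold integer indices into 1..n
fold_int <- function(i, n) {
  if (n == 1L) return(rep_len(1L, length(i)))
  period <- 2L * (n - 1L)
  q <- (i - 1L) %% period
  as.integer(1L + (n - 1L) - abs(q - (n - 1L)))
}

# 1-D interpolated sampling of a vector at fractional positions
interp1 <- function(y, p, order = 3L) {
  n <- length(y)
  p <- fold_coord(p, n)
  if (order == 1L) {
    i0 <- pmin(pmax(floor(p), 1), n - 1); f <- p - i0
    (1 - f) * y[i0] + f * y[i0 + 1]
  } else if (order == 3L) {
    i0 <- floor(p); f <- p - i0
    out <- numeric(length(p))
    for (d in -1:2) out <- out + keys_w(d - f) * y[fold_int(i0 + d, n)]
    out
  } else stop("interpolation order must be 1 or 3")
}
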