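# FFT-based n-D convolution with explicit boundary extension.
#
# Convention: result[p] = sum_u K[u] X[p - u], with the kernel origin at its
# centre sample on "centred" axes and at the first sample on causal axes
# (support u >= 0, so only past samples are accessed along that axis).

# Extend one axis of an array by l samples on the left and r on the right.
extend_axis <- function(arr, axis, l, r, mode) {
  d <- dim(arr)
  nd <- length(d)
  if (l == 0L && r == 0L) return(arr)
  perm <- c(axis, seq_len(nd)[-axis])
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  if (mode == "zero") {
    top <- matrix(0, l, ncol(m))
    bot <- matrix(0, r, ncol(m))
  } else if (mode == "circular") {
    top <- m[(n - l + 1L):n, , drop = FALSE]
    bot <- m[1L:r, , drop = FALSE]
  } else if (mode == "replicate") {
    top <- m[rep(1L, l), , drop = FALSE]
    bot <- m[rep(n, r), , drop = FALSE]
  } else if (mode == "reflect") {
    if (l > n - 1L || r > n - 1L)
      stop("reflect padding wider than the array extent")
    top <- m[if (l > 0L) (l + 1L):2L else integer(0), , drop = FALSE]
    bot <- m[if (r > 0L) (n - 1L):(n - r) else integer(0), , drop = FALSE]
  } else stop("unknown boundary mode: ", mode)
  m2 <- rbind(top, m, bot)
  out <- array(m2, dim = c(n + l + r, d[perm][-1L]))
  aperm(out, order(perm))
}

# n-D linear convolution via FFT. `boundary` is recycled per axis;
# `causal_axes` lists axes whose kernel origin is the first sample.
fft_convolve_nd <- function(x, k, boundary = "reflect",
                            causal_axes = integer(0)) {
  dx <- dim(x); dk <- dim(k)
  nd <- length(dx)
  stopifnot(length(dk) == nd)
  boundary <- rep_len(boundary, nd)
  # kernel left/right extents per axis
  Lk <- integer(nd); Rk <- integer(nd)
  for (i in seq_len(nd)) {
    if (i %in% causal_axes) {
      Lk[i] <- 0L; Rk[i] <- dk[i] - 1L
    } else {
      if (dk[i] %% 2L == 0L) stop("centred kernel axes must be odd-sized")
      Lk[i] <- Rk[i] <- (dk[i] - 1L) %/% 2L
    }
  }
  # pad input: left by Rk (deepest past reach), right by Lk
  xp <- x
  for (i in seq_len(nd)) xp <- extend_axis(xp, i, Rk[i], Lk[i], boundary[i])
  dpad <- dim(xp)
  P <- vapply(dpad, function(n) stats::nextn(n, c(2, 3, 5)), integer(1))
  xz <- array(0, P)
  do.call(`[<-`, c(list(xz), lapply(dpad, seq_len), list(value = xp))) -> xz
  kz <- array(0, P)
  pos <- lapply(seq_len(nd), function(i) ((seq_len(dk[i]) - 1L - Lk[i]) %% P[i]) + 1L)
  do.call(`[<-`, c(list(kz), pos, list(value = k))) -> kz
  res <- Re(stats::fft(stats::fft(xz) * stats::fft(kz), inverse = TRUE)) / prod(P)
  crop <- lapply(seq_len(nd), function(i) Rk[i] + seq_len(dx[i]))
  do.call(`[`, c(list(res), crop, list(drop = FALSE))) |> array(dim = dx)
}

# Relative L2 distance between two equally shaped arrays over an interior
# crop that discards `margin_lo`/`margin_hi` samples per axis (recycled;
# `margin` sets both); the metric used for all commutative-diagram residuals.
relative_l2 <- function(a, b, margin = 0L, margin_lo = margin,
                        margin_hi = margin) {
  d <- dim(a)
  if (is.null(d)) { d <- length(a); dim(a) <- d; dim(b) <- d }
  stopifnot(all(dim(b) == d))
  margin_lo <- rep_len(as.integer(margin_lo), length(d))
  margin_hi <- rep_len(as.integer(margin_hi), length(d))
  idx <- lapply(seq_along(d), function(i) {
    lo <- margin_lo[i] + 1L; hi <- d[i] - margin_hi[i]
    if (lo > hi) stop("interior crop is empty; reduce margin or enlarge input")
    lo:hi
  })
  aa <- do.call(`[`, c(list(a), idx))
  bb <- do.call(`[`, c(list(b), idx))
  denom <- sqrt(sum(aa^2))
  if (denom == 0) stop("reference signal has zero norm; residual undefined")
  sqrt(sum((aa - bb)^2)) / denom
}
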