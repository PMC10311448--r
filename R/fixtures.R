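#' Deterministic test-pattern specification
#'
#' Describes a synthetic image or video fixture so every covariance and
#' population experiment runs without external data. Identical specs
#' (including `seed`) produce bit-identical output.
#'
#' @param kind One of `"gaussian_blob"`, `"sine_grating"`,
#'   `"band_limited_noise"`, `"translating_pattern"`, `"flashing_blob"`.
#' @param size Image side length in pixels (images are square), default 129.
#' @param nt Number of frames for video kinds, default 64.
#' @param std Blob standard deviation (blob kinds), default 4.
#' @param wavelength Grating wavelength in pixels, default 16.
#' @param theta Grating wavevector direction (radians), default 0.
#' @param phase Grating phase (radians), default 0.
#' @param cutoff Noise band limit as a fraction of the Nyquist frequency,
#'   default 1/6 (keeps interpolation error during warps well below the
#'   diagram tolerances).
#' @param v Translation velocity (pixels/frame) for `translating_pattern`.
#' @param event_frame Temporal position (0-based frame) of the flash for
#'   `flashing_blob`, default `nt / 2`.
#' @param event_std Temporal standard deviation of the flash, default 2.
#' @param seed Integer seed for stochastic kinds, default 0.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, size = 129L, nt = 64L, std = 4,
                         wavelength = 16, theta = 0, phase = 0,
                         cutoff = 1 / 6, v = c(1, 0),
                         event_frame = NULL, event_std = 2, seed = 0L) {
  kinds <- c("gaussian_blob", "sine_grating", "band_limited_noise",
             "translating_pattern", "flashing_blob")
  if (!kind %in% kinds)
    stop("unknown fixture kind: ", kind)
  if (is.null(event_frame)) event_frame <- nt %/% 2L
  structure(list(kind = kind, size = as.integer(size), nt = as.integer(nt),
                 std = std, wavelength = wavelength, theta = theta,
                 phase = phase, cutoff = cutoff, v = as.numeric(v),
                 event_frame = event_frame, event_std = event_std,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# centred coordinate matrices for an n x n image
centred_coords <- function(n) {
  cc <- (n + 1) / 2
  list(x1 = matrix(rep(seq_len(n) - cc, times = n), n, n),
       x2 = matrix(rep(seq_len(n) - cc, each = n), n, n))
}

#' Generate a deterministic test image
#'
#' `gaussian_blob`: centred (optionally anisotropic) Gaussian intensity
#' profile; `sine_grating`: `sin(k . x + phase)` shifted to be nonnegative;
#' `band_limited_noise`: seeded white noise low-pass filtered at the stated
#' cut-off with a hard radial frequency mask.
#'
#' @param spec A [fixture_spec()].
#' @return 2-D intensity array indexed `[x1, x2]`.
#' @export
make_test_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$size
  co <- centred_coords(n)
  switch(spec$kind,
    gaussian_blob = {
      std <- rep_len(spec$std, 2L)
      exp(-(co$x1^2 / std[1L]^2 + co$x2^2 / std[2L]^2) / 2)
    },
    sine_grating = {
      k <- 2 * pi / spec$wavelength
      0.5 + 0.5 * sin(k * (cos(spec$theta) * co$x1 + sin(spec$theta) * co$x2) +
                        spec$phase)
    },
    band_limited_noise = {
      set.seed(spec$seed)
      w <- matrix(stats::rnorm(n * n), n, n)
      f <- stats::fft(w)
      fr <- c(0:(n %/% 2), -((n - 1L) %/% 2):-1) / n  # cycles per pixel
      r <- sqrt(outer(fr^2, fr^2, `+`))
      mask <- r <= spec$cutoff * 0.5   # Nyquist = 0.5 cycles/pixel
      g <- Re(stats::fft(f * mask, inverse = TRUE)) / (n * n)
      g / stats::sd(g)
    },
    stop("fixture kind ", spec$kind, " is a video kind; use make_test_video")
  )
}

# shift a 2-D frame by (d1, d2) pixels; exact circular roll for integer
# displacements, FFT phase shift otherwise (exact continuous translation
# for the band-limited periodic noise base, with no boundary strip)
shift_frame <- function(img, d1, d2) {
  n1 <- nrow(img); n2 <- ncol(img)
  if (d1 == round(d1) && d2 == round(d2)) {
    i <- ((seq_len(n1) - 1 - d1) %% n1) + 1
    j <- ((seq_len(n2) - 1 - d2) %% n2) + 1
    img[i, j]
  } else {
    f1 <- c(0:(n1 %/% 2), -((n1 - 1L) %/% 2):-1) / n1
    f2 <- c(0:(n2 %/% 2), -((n2 - 1L) %/% 2):-1) / n2
    ph <- exp(-2i * pi * (outer(f1 * d1, rep(1, n2)) +
                            outer(rep(1, n1), f2 * d2)))
    Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n1 * n2)
  }
}

#' Generate a deterministic test video
#'
#' `translating_pattern`: frame `t` is frame 0 (band-limited noise) shifted
#' by `v * t` - exact circular roll for integer per-frame displacement,
#' bicubic shift otherwise; `flashing_blob`: a spatial Gaussian blob
#' modulated by a temporal Gaussian bump centred on `event_frame`.
#'
#' @param spec A [fixture_spec()].
#' @return 3-D intensity array `[x1, x2, t]`.
#' @export
make_test_video <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$size; nt <- spec$nt
  out <- array(0, c(n, n, nt))
  switch(spec$kind,
    translating_pattern = {
      base <- make_test_image(fixture_spec("band_limited_noise", size = n,
                                           cutoff = spec$cutoff,
                                           seed = spec$seed))
      for (k in seq_len(nt)) {
        t <- k - 1
        out[, , k] <- shift_frame(base, spec$v[1L] * t, spec$v[2L] * t)
      }
      out
    },
    flashing_blob = {
      blob <- make_test_image(fixture_spec("gaussian_blob", size = n,
                                           std = spec$std))
      bump <- exp(-((seq_len(nt) - 1 - spec$event_frame)^2) /
                    (2 * spec$event_std^2))
      for (k in seq_len(nt)) out[, , k] <- blob * bump[k]
      out
    },
    stop("fixture kind ", spec$kind, " is an image kind; use make_test_image")
  )
}

#' Logarithmic brightness transform
#'
#' Maps intensities to `log(floor + f)`. On a logarithmic brightness scale a
#' multiplicative intensity change `k * f` becomes an additive constant
#' (`log k` where `f >> floor`), so any derivative receptive-field response
#' (`m + n >= 1`) is invariant to multiplicative illumination or exposure
#' changes.
#'
#' @param x Image or video array with nonnegative intensities.
#' @param floor Small positive offset guarding exact zeros, default 1e-3.
#' @return Transformed array, same shape.
#' @export
log_brightness <- function(x, floor = 1e-3) {
  if (any(x < 0)) stop("log brightness requires nonnegative intensities")
  stopifnot(floor > 0)
  log(floor + x)
}
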