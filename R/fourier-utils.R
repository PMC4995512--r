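# Small FFT helpers shared across modules. Frequencies are in cycles per
# micrometer throughout; pitches in micrometers.

#' Sample frequencies of a discrete Fourier transform
#'
#' @param n number of samples.
#' @param pitch sample spacing in micrometers.
#' @return numeric vector of length `n` in cycles/um, in FFT order
#'   (DC first, then positive, then negative frequencies).
#' @keywords internal
fft_freq <- function(n, pitch) {
  f <- seq_len(n) - 1L
  f[f > n / 2] <- f[f > n / 2] - n
  f / (n * pitch)
}

#' @keywords internal
fft2 <- function(x) stats::fft(x)

#' @keywords internal
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Move a kernel centered at `center` to the DFT origin (index 1)
#'
#' The inverse of an fftshift: after this, a convolution kernel built with its
#' peak at the array center produces unshifted output when applied by FFT.
#'
#' @param x matrix or 3-D array.
#' @param center integer vector of center indices, one per dimension.
#'   Defaults to `floor(dim/2) + 1`.
#' @keywords internal
ifftshift <- function(x, center = NULL) {
  d <- dim(x)
  if (is.null(center)) center <- floor(d / 2) + 1L
  idx <- lapply(seq_along(d), function(i) {
    ((seq_len(d[i]) - 1L + (center[i] - 1L)) %% d[i]) + 1L
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Move the DFT origin (index 1) to the array center
#'
#' Inverse of [ifftshift()].
#' @keywords internal
fftshift <- function(x) {
  d <- dim(x)
  center <- floor(d / 2) + 1L
  idx <- lapply(seq_along(d), function(i) {
    ((seq_len(d[i]) - center[i]) %% d[i]) + 1L
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Radial frequency magnitude grid for a 2-D transform
#'
#' @param n dimensions (length 2).
#' @param pitch pitches in micrometers (length 2).
#' @return matrix of |k| in cycles/um, FFT layout.
#' @keywords internal
k_radial_grid <- function(n, pitch) {
  kx <- fft_freq(n[1], pitch[1])
  kz <- fft_freq(n[2], pitch[2])
  sqrt(outer(kx^2, kz^2, `+`))
}

#' Azimuth grid (mod pi) for a 2-D transform
#'
#' Angle 0 is the first (k_x) axis; spectra of real images are Hermitian so
#' directions are only defined modulo pi.
#' @keywords internal
k_azimuth_grid <- function(n, pitch) {
  kx <- fft_freq(n[1], pitch[1])
  kz <- fft_freq(n[2], pitch[2])
  th <- atan2(rep(kz, each = n[1]), rep(kx, times = n[2]))
  dim(th) <- n
  th %% pi
}

#' Embed a small matrix centered in a larger zero matrix
#' @keywords internal
embed_mat <- function(m, dims) {
  out <- matrix(0, dims[1], dims[2])
  d <- dim(m)
  off <- floor(dims / 2) + 1L - (floor(d / 2) + 1L)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- m
  out
}

#' Next FFT-friendly length (factors 2, 3, 5)
#' @keywords internal
good_fft_length <- function(n) as.integer(stats::nextn(n, c(2L, 3L, 5L)))

#' Interpolated full width at half maximum of a sampled profile
#'
#' @param y nonnegative profile samples.
#' @param pitch sample spacing.
#' @return FWHM in the units of `pitch`, or `NA` if the profile never drops
#'   below half of its maximum on either side.
#' @keywords internal
measure_fwhm <- function(y, pitch = 1) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  cross <- function(idx) {
    below <- which(y[idx] < half)
    if (!length(below)) return(NA_real_)
    b <- below[1]
    if (b == 1) return(NA_real_)
    i2 <- idx[b]; i1 <- idx[b - 1]
    frac <- (y[i1] - half) / (y[i1] - y[i2])
    abs(i1 - i0) + frac
  }
  up <- if (i0 < length(y)) cross(seq(i0 + 1, length(y))) else NA_real_
  dn <- if (i0 > 1) cross(seq(i0 - 1, 1)) else NA_real_
  if (is.na(up) || is.na(dn)) return(NA_real_)
  (up + dn) * pitch
}
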