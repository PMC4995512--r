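# Numerically computed k_z-axis response of the slit-gated optics to an
# isotropic lateral Gaussian blur of width sigma. Along the k_z axis the
# plane transfer of a confocally detected stack is NOT a simple re-weighting
# of the scattering orders by the central illumination profile: defocused
# structure of the illumination (e.g. the Bessel ring system) admits
# laterally displaced diffuse photons at off-center x. Tabulating
# A(sigma, k_z) through the actual PSFs captures all of that; the fit then
# uses T(k_z, y0) = sum_j c_j(y0) A(sigma_j(y0), k_z).

#' Tabulate the k_z-wedge transfer of the optics vs lateral blur width
#'
#' For each blur width sigma on a grid, blurs every y-slice of the detection
#' PSF with an isotropic 2-D Gaussian, gates it by the illumination slice,
#' sums the slice transfer functions and averages their magnitude over the
#' same k_z wedge and radial bins that [normalized_depth_spectrum()] uses for
#' its `"kz"` direction. The tabulated response therefore mirrors the
#' measurement statistic exactly, for a single scattering order of lateral
#' width sigma; [fit_scattering_params()] combines the orders in
#' `confocal_kz` mode.
#'
#' @param optics an [optics_config()].
#' @param n grid `(nx, ny, nz)` matching the analyzed stack laterally; `ny`
#'   is the number of PSF y-slices (odd).
#' @param pitch voxel pitch, micrometers.
#' @param n_theta azimuthal bin count defining the wedge half-width
#'   `pi/n_theta`; must match the spectra it will be fitted against.
#' @param sigma_max largest tabulated blur width, micrometers.
#' @param n_sigma number of sigma samples (including 0).
#' @return object of class `kz_transfer`: list with `sigma` grid, `kz` bin
#'   centers (nonnegative, cycles/um) and matrix `A` (`n_sigma` x `n_kz`),
#'   each row the wedge-binned response at one blur width, normalized to
#'   `A(sigma = 0, kz = 0) = 1`.
#' @export
system_kz_transfer <- function(optics, n, pitch, n_theta = 16,
                               sigma_max = 10, n_sigma = 41) {
  stopifnot(inherits(optics, "optics_config"))
  n <- as.integer(rep(n, length.out = 3))
  pitch <- rep(pitch, length.out = 3)
  if (n[2] %% 2L == 0L) n[2] <- n[2] + 1L
  sb <- beam_intensity(optics, n, pitch)
  h_ill <- illumination_psf(sb, optics$d_slit)
  h_det <- detection_psf(optics, n, pitch)
  kx <- fft_freq(n[1], pitch[1])
  kz <- fft_freq(n[3], pitch[3])
  k2 <- outer(kx^2, kz^2, `+`)
  # wedge + radial binning identical to the depth-spectrum "kz" direction
  latn <- n[c(1, 3)]; latp <- pitch[c(1, 3)]
  kr <- k_radial_grid(latn, latp)
  th <- k_azimuth_grid(latn, latp)
  k_n <- min(1 / (2 * latp))
  dk <- 1 / (max(latn * latp))
  in_kz <- pmin(abs(th - pi / 2), pi - abs(th - pi / 2)) <= pi / n_theta
  keep <- kr <= k_n & in_kz
  idx <- which(keep)
  fbin <- factor(round(kr / dk)[idx])
  kcenters <- as.numeric(levels(fbin)) * dk

  sigma <- seq(0, sigma_max, length.out = n_sigma)
  A <- matrix(0, n_sigma, length(kcenters))
  Adc <- numeric(n_sigma)
  Hdet <- vector("list", n[2])
  ill_s <- vector("list", n[2])
  for (s in seq_len(n[2])) {
    Hdet[[s]] <- fft2(ifftshift(h_det$data[, s, ]))
    ill_s[[s]] <- ifftshift(h_ill$data[, s, ])
  }
  for (i in seq_along(sigma)) {
    G <- exp(-2 * pi^2 * sigma[i]^2 * k2)
    acc <- matrix(0 + 0i, latn[1], latn[2])
    for (s in seq_len(n[2])) {
      blur <- Re(ifft2(Hdet[[s]] * G))
      blur[blur < 0] <- 0
      acc <- acc + fft2(ill_s[[s]] * blur)
    }
    m <- Mod(acc)
    A[i, ] <- as.numeric(tapply(m[idx], fbin, mean))
    Adc[i] <- m[1, 1]
  }
  A <- A / Adc[1]
  Adc <- Adc / Adc[1]
  structure(list(sigma = sigma, kz = kcenters, A = A, dc = Adc,
                 n_theta = n_theta, pitch = pitch, optics = optics),
            class = "kz_transfer")
}

# Interpolate the plane DC response (total gated light) over sigma.
kz_transfer_dc <- function(kzt, sigma) {
  stats::approx(kzt$sigma, kzt$dc, xout = pmin(pmax(sigma, 0), max(kzt$sigma)),
                rule = 2)$y
}

#' @export
print.kz_transfer <- function(x, ...) {
  cat(sprintf(
    "<kz_transfer> %d sigma values (0..%.3g um) x %d kz bins (0..%.3g cycles/um)\n",
    length(x$sigma), max(x$sigma), length(x$kz), max(x$kz)
  ))
  invisible(x)
}

# Interpolate A at arbitrary (sigma, kz): linear in both axes.
kz_transfer_eval <- function(kzt, sigma, k) {
  sg <- kzt$sigma
  si <- findInterval(pmin(pmax(sigma, sg[1]), max(sg)), sg,
                     rightmost.closed = TRUE)
  si <- pmin(si, length(sg) - 1L)
  ts <- (sigma - sg[si]) / (sg[si + 1L] - sg[si])
  ts <- pmin(pmax(ts, 0), 1)
  kg <- kzt$kz
  ki <- findInterval(pmin(pmax(k, kg[1]), max(kg)), kg,
                     rightmost.closed = TRUE)
  ki <- pmin(ki, length(kg) - 1L)
  tk <- (pmin(k, max(kg)) - kg[ki]) / (kg[ki + 1L] - kg[ki])
  tk <- pmin(pmax(tk, 0), 1)
  a00 <- kzt$A[cbind(si, ki)]
  a01 <- kzt$A[cbind(si, ki + 1L)]
  a10 <- kzt$A[cbind(si + 1L, ki)]
  a11 <- kzt$A[cbind(si + 1L, ki + 1L)]
  (1 - ts) * ((1 - tk) * a00 + tk * a01) + ts * ((1 - tk) * a10 + tk * a11)
}
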