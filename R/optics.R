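# Purely optical point-spread functions of the scanned-beam light-sheet
# microscope: single-beam illumination (Gaussian or Bessel), the confocal /
# widefield detection slit acting along the scan axis x, the widefield
# detection PSF (optical axis y), and their composition into the effective
# system PSF. Scalar diffraction via the angular spectrum method throughout.

#' Optics configuration of the light-sheet microscope
#'
#' @param beam_type `"gaussian"` or `"bessel"` illumination beam.
#' @param lambda_ill,lambda_det illumination / detection wavelengths
#'   (vacuum), micrometers.
#' @param na_ill illumination numerical aperture (Bessel ring NA).
#' @param na_det detection numerical aperture. Must exceed `na_ill` and not
#'   exceed `n_medium`.
#' @param n_medium refractive index of the immersion/sample medium.
#' @param sheet_fov axial FWHM of the beam along its propagation axis z,
#'   micrometers; sets the Gaussian beam waist.
#' @param d_slit detection slit width in object space, micrometers
#'   (confocal line detection ~ 1.3, widefield ~ 50).
#' @param magnification transverse magnification, used only to convert
#'   camera-pixel slit widths to object space.
#' @param bessel_ring_frac fractional radial width of the annular pupil that
#'   generates the Bessel beam.
#' @return object of class `optics_config`.
#' @export
optics_config <- function(beam_type = c("gaussian", "bessel"),
                          lambda_ill = 0.488, lambda_det = 0.52,
                          na_ill = 0.15, na_det = 0.8, n_medium = 1.33,
                          sheet_fov = 300, d_slit = 50, magnification = 40,
                          bessel_ring_frac = 0.05) {
  beam_type <- match.arg(beam_type)
  stopifnot(lambda_ill > 0, lambda_det > 0, d_slit > 0, sheet_fov > 0,
            bessel_ring_frac > 0, magnification > 0)
  if (!(na_ill > 0 && na_ill < na_det && na_det <= n_medium)) {
    stop("require 0 < na_ill < na_det <= n_medium")
  }
  structure(
    list(beam_type = beam_type, lambda_ill = lambda_ill,
         lambda_det = lambda_det, na_ill = na_ill, na_det = na_det,
         n_medium = n_medium, sheet_fov = sheet_fov, d_slit = d_slit,
         magnification = magnification, bessel_ring_frac = bessel_ring_frac),
    class = "optics_config"
  )
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "<optics_config> %s beam, NA_ill %.2f / NA_det %.2f (n = %.2f)\n  lambda %g/%g um, sheet FWHM %g um, slit %g um (%s detection)\n",
    x$beam_type, x$na_ill, x$na_det, x$n_medium, x$lambda_ill, x$lambda_det,
    x$sheet_fov, x$d_slit, if (x$d_slit <= 5) "confocal line" else "widefield"
  ))
  invisible(x)
}

#' PSF sample volume
#'
#' @param data 3-D nonnegative array `[x, y, z]`.
#' @param pitch voxel pitch, micrometers (length 3).
#' @param normalization `"peak"` (unit maximum) or `"mass"` (unit sum).
#' @return object of class `psf_volume`.
#' @export
psf_volume <- function(data, pitch, normalization = c("peak", "mass")) {
  normalization <- match.arg(normalization)
  stopifnot(is.array(data), length(dim(data)) == 3, all(data >= 0))
  s <- if (normalization == "peak") max(data) else sum(data)
  structure(
    list(data = data / s, pitch = stats::setNames(as.numeric(pitch), c("x", "y", "z")),
         center = floor(dim(data) / 2) + 1L, normalization = normalization),
    class = "psf_volume"
  )
}

#' @export
print.psf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<psf_volume> %d x %d x %d (x,y,z), pitch %.4g/%.4g/%.4g um, unit %s\n",
              d[1], d[2], d[3], x$pitch[1], x$pitch[2], x$pitch[3],
              x$normalization))
  invisible(x)
}

#' Convert a PSF volume to an image stack (e.g. for TIFF export)
#' @param psf a [psf_volume()].
#' @export
as_image_stack <- function(psf) {
  stopifnot(inherits(psf, "psf_volume"))
  image_stack(psf$data, psf$pitch)
}

#' Free-space propagation of a complex field by the angular spectrum method
#'
#' Exact scalar propagation: the field's plane-wave components acquire the
#' spectral phase `exp(2i pi d sqrt((n/lambda)^2 - k^2))`; evanescent
#' components decay exponentially.
#'
#' @param field 2-D complex matrix (transverse field).
#' @param pitch transverse sample pitches, micrometers (length 2).
#' @param distance propagation distance, micrometers (may be negative).
#' @param wavelength vacuum wavelength, micrometers.
#' @param n_medium refractive index.
#' @return propagated complex field, same dimensions.
#' @export
angular_spectrum_propagate <- function(field, pitch, distance, wavelength,
                                       n_medium = 1) {
  stopifnot(is.matrix(field))
  pitch <- rep(pitch, length.out = 2)
  if (distance == 0) return(field)
  n <- dim(field)
  k1 <- fft_freq(n[1], pitch[1])
  k2 <- fft_freq(n[2], pitch[2])
  kt2 <- outer(k1^2, k2^2, `+`)
  spec_pow <- Mod(fft2(field))^2
  outer_band <- sqrt(kt2) > 0.9 * min(1 / (2 * pitch))
  if (sum(spec_pow[outer_band]) > 1e-6 * sum(spec_pow)) {
    warning("field carries spectral energy near Nyquist; propagation may alias ",
            "(increase sampling for this NA)")
  }
  kz2 <- (n_medium / wavelength)^2 - kt2
  prop <- kz2 >= 0
  h <- matrix(0 + 0i, n[1], n[2])
  h[prop] <- exp(2i * pi * distance * sqrt(kz2[prop]))
  h[!prop] <- exp(-2 * pi * abs(distance) * sqrt(-kz2[!prop]))
  ifft2(fft2(field) * h)
}


#' Single-beam illumination intensity
#'
#' Propagates the focused beam along the illumination axis z and samples its
#' intensity on the requested grid. Gaussian beams use a waist chosen so the
#' axial intensity FWHM equals `sheet_fov`; Bessel beams arise from a thin
#' annular pupil of mean NA `na_ill`, giving the J0^2-like lateral profile.
#'
#' @param config an [optics_config()].
#' @param n grid size `(nx, ny, nz)`; the beam is transverse in (x, y) and
#'   focused at the grid center.
#' @param pitch voxel pitch, micrometers (length 3).
#' @return a [psf_volume()] (unit peak) holding `h_SB`.
#' @export
beam_intensity <- function(config, n, pitch) {
  stopifnot(inherits(config, "optics_config"))
  n <- as.integer(rep(n, length.out = 3))
  pitch <- rep(pitch, length.out = 3)
  nt <- n[c(1, 2)]; pt <- pitch[c(1, 2)]
  k1 <- fft_freq(nt[1], pt[1]); k2 <- fft_freq(nt[2], pt[2])
  if (config$beam_type == "gaussian") {
    w0 <- sqrt(config$sheet_fov * config$lambda_ill / (2 * pi * config$n_medium))
    cx <- (seq_len(nt[1]) - (floor(nt[1] / 2) + 1)) * pt[1]
    cy <- (seq_len(nt[2]) - (floor(nt[2] / 2) + 1)) * pt[2]
    u0 <- exp(-outer(cx^2, cy^2, `+`) / w0^2) * (1 + 0i)
    spec <- fft2(ifftshift(u0))       # focal-field spectrum, origin at index 1
  } else {
    k0 <- config$na_ill / config$lambda_ill
    dk <- k0 * config$bessel_ring_frac / 2
    kr <- sqrt(outer(k1^2, k2^2, `+`))
    spec <- (abs(kr - k0) <= dk) * (1 + 0i)   # annular pupil
    if (!any(Mod(spec) > 0)) stop("annular pupil empty: grid too small for na_ill")
  }
  kz2 <- (config$n_medium / config$lambda_ill)^2 - outer(k1^2, k2^2, `+`)
  prop <- kz2 >= 0
  rt <- sqrt(pmax(kz2, 0))
  out <- array(0, n)
  zc <- floor(n[3] / 2) + 1L
  for (iz in seq_len(n[3])) {
    d <- (iz - zc) * pitch[3]
    h <- matrix(0 + 0i, nt[1], nt[2])
    h[prop] <- exp(2i * pi * d * rt[prop])
    h[!prop] <- exp(-2 * pi * abs(d) * sqrt(-kz2[!prop]))
    u <- ifft2(spec * h)
    out[, , iz] <- Mod(fftshift(u))^2  # origin back to the grid center
  }
  psf_volume(out, pitch, "peak")
}

#' Effective illumination PSF: scanned beam seen through the detection slit
#'
#' The scanned beam convolved along the scan axis x with a unit-height
#' rectangle of width `d_slit` (object space). A wide slit recovers the
#' x-invariant scanned light-sheet, a one-voxel slit recovers the single-beam
#' intensity. The kernel's fractional end weights make the integral scale
#' exactly by `d_slit` in voxels.
#'
#' @param h_sb single-beam intensity, a [psf_volume()].
#' @param d_slit slit width in object space, micrometers.
#' @return a [psf_volume()] holding `h_ill` (same grid; kept on the peak
#'   normalization of the input so slit limits are comparable).
#' @export
illumination_psf <- function(h_sb, d_slit) {
  stopifnot(inherits(h_sb, "psf_volume"), d_slit > 0)
  d <- dim(h_sb$data)
  w <- d_slit / h_sb$pitch[["x"]]           # slit width in voxels
  half <- w / 2
  m <- max(0L, ceiling(half - 0.5))
  off <- (-m):m
  wt <- pmax(0, pmin(off + 0.5, half) - pmax(off - 0.5, -half))
  pad <- good_fft_length(d[1] + length(off))
  ker <- numeric(pad)
  ker[((off %% pad) + 1L)] <- wt
  x <- matrix(0, pad, d[2] * d[3])
  x[seq_len(d[1]), ] <- h_sb$data
  conv <- Re(stats::mvfft(stats::mvfft(x) * as.vector(stats::mvfft(matrix(ker))),
                          inverse = TRUE)) / pad
  res <- array(conv[seq_len(d[1]), ], d)
  res[res < 0] <- 0
  out <- h_sb
  out$data <- res
  out
}

#' Widefield detection PSF
#'
#' Scalar diffraction PSF of a circular pupil of `na_det`, optical axis along
#' the detection direction y; defocus by angular-spectrum propagation.
#'
#' @param config an [optics_config()].
#' @param n grid size `(nx, ny, nz)`; y spans defocus symmetric about the
#'   focal plane.
#' @param pitch voxel pitch, micrometers.
#' @return a [psf_volume()] (unit peak) holding `h_det`.
#' @export
detection_psf <- function(config, n, pitch) {
  stopifnot(inherits(config, "optics_config"),
            config$na_det < config$n_medium)
  n <- as.integer(rep(n, length.out = 3))
  pitch <- rep(pitch, length.out = 3)
  nt <- n[c(1, 3)]; pt <- pitch[c(1, 3)]
  kmax <- config$na_det / config$lambda_det
  k1 <- fft_freq(nt[1], pt[1]); k2 <- fft_freq(nt[2], pt[2])
  kr <- sqrt(outer(k1^2, k2^2, `+`))
  spec0 <- (kr <= kmax) * (1 + 0i)          # focal-field spectrum (uniform pupil)
  kz2 <- (config$n_medium / config$lambda_det)^2 - kr^2
  prop <- kz2 >= 0
  rt <- sqrt(pmax(kz2, 0))
  out <- array(0, n)
  yc <- floor(n[2] / 2) + 1L
  for (iy in seq_len(n[2])) {
    dfoc <- (iy - yc) * pitch[2]
    h <- matrix(0 + 0i, nt[1], nt[2])
    h[prop] <- exp(2i * pi * dfoc * rt[prop])
    h[!prop] <- exp(-2 * pi * abs(dfoc) * sqrt(-kz2[!prop]))
    u <- ifft2(spec0 * h)
    out[, iy, ] <- Mod(fftshift(u))^2
  }
  psf_volume(out, pitch, "peak")
}

#' Effective system PSF at one detection depth
#'
#' Composes `h_sys(r, y0) = h_ill(r) * [h_det (x) h_obj](r, y0)`: the lateral
#' (x, z) object kernel blurs every y-slice of the detection PSF, and the
#' illumination profile then gates the product. The object-induced spread is
#' thereby confined to the light-sheet thickness.
#'
#' @param h_ill,h_det [psf_volume()]s on one common grid.
#' @param object_kernel optional 2-D lateral kernel (matrix `[x, z]`, unit
#'   mass, centered as produced by [object_response()]) with the same lateral
#'   size as the PSFs; `NULL` means scatter-free (delta kernel).
#' @return a [psf_volume()] with unit mass.
#' @export
system_psf <- function(h_ill, h_det, object_kernel = NULL) {
  stopifnot(inherits(h_ill, "psf_volume"), inherits(h_det, "psf_volume"))
  if (!identical(dim(h_ill$data), dim(h_det$data)) ||
      max(abs(h_ill$pitch - h_det$pitch)) > 1e-9) {
    stop("h_ill and h_det must share one grid")
  }
  d <- dim(h_det$data)
  if (is.null(object_kernel)) {
    out <- h_ill$data * h_det$data
  } else {
    if (!identical(dim(object_kernel), d[c(1, 3)])) {
      stop("object_kernel must match the lateral (x, z) grid of the PSFs")
    }
    kf <- fft2(ifftshift(object_kernel))
    out <- array(0, d)
    for (iy in seq_len(d[2])) {
      blur <- Re(ifft2(fft2(h_det$data[, iy, ]) * kf))
      blur[blur < 0] <- 0
      out[, iy, ] <- h_ill$data[, iy, ] * blur
    }
  }
  psf_volume(out, h_ill$pitch, "mass")
}

#' Lateral x-profile of the effective illumination
#'
#' Builds the slit-gated scanned beam for the given optics and returns its
#' profile along the scan axis x at the beam focus. This is the weighting
#' that confocal detection applies to laterally displaced photons, used for
#' re-weighting scattering orders when fitting in `confocal_kz` mode.
#'
#' @param config an [optics_config()].
#' @param nx,ny number of x / y samples (y only to host the beam core).
#' @param pitch `(dx, dy)` pitches, micrometers.
#' @return tibble with columns `x` (micrometers, centered) and `u`
#'   (profile, unit peak).
#' @export
illumination_xprofile <- function(config, nx = 128, ny = 33,
                                  pitch = c(0.1625, 0.5)) {
  sb <- beam_intensity(config, c(nx, ny, 1L), c(pitch, 1))
  ill <- illumination_psf(sb, config$d_slit)
  yc <- floor(ny / 2) + 1L
  u <- ill$data[, yc, 1]
  u <- u / max(u)
  xc <- floor(nx / 2) + 1L
  tibble::tibble(x = (seq_len(nx) - xc) * pitch[1], u = u)
}
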