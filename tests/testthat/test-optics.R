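test_that("angular spectrum propagation is exact for the trivial cases", {
  set.seed(2)
  f <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
  expect_identical(angular_spectrum_propagate(f, 0.3, 0, 0.5, 1.33), f)
  pw <- matrix(1 + 0i, 64, 64)
  out <- angular_spectrum_propagate(pw, 0.3, 17, 0.5, 1.33)
  expect_equal(Mod(out), Mod(pw), tolerance = 1e-10)
})

test_that("propagated Gaussian beam follows the analytic waist evolution", {
  n <- 128; pitch <- 0.2; lam <- 0.488; nm <- 1.33; w0 <- 2
  x <- (seq_len(n) - (floor(n / 2) + 1)) * pitch
  u0 <- exp(-outer(x^2, x^2, `+`) / w0^2) * (1 + 0i)
  zr <- pi * w0^2 * nm / lam
  for (z in c(4, 10)) {
    u <- angular_spectrum_propagate(u0, pitch, z, lam, nm)
    prof <- Mod(u[, floor(n / 2) + 1])^2
    sel <- prof > max(prof) * 1e-3
    wz <- sqrt(-2 / stats::lm.fit(cbind(1, x[sel]^2), log(prof[sel]))$coefficients[2])
    expect_equal(unname(wz), w0 * sqrt(1 + (z / zr)^2), tolerance = 0.02)
    # energy conservation (no evanescent content in this field)
    expect_equal(sum(Mod(u)^2), sum(Mod(u0)^2), tolerance = 1e-6)
  }
})

test_that("Bessel beam has the J0 first-zero radius and even symmetry", {
  oc <- optics_config("bessel")
  b <- beam_intensity(oc, c(256, 256, 1), c(0.1625, 0.1625, 1))
  prof <- b$data[, 129, 1]
  r1 <- (which(diff(prof[129:256]) > 0)[1] - 1) * 0.1625
  expect_equal(r1, 2.405 * oc$lambda_ill / (2 * pi * oc$na_ill), tolerance = 0.1)
  # even symmetry about the grid center (index 129 on an even grid)
  sl <- b$data[2:256, 2:256, 1]
  expect_equal(sl, sl[rev(seq_len(255)), ], tolerance = 1e-8)
  expect_equal(sl, sl[, rev(seq_len(255))], tolerance = 1e-8)
})

test_that("Gaussian beam axial FWHM matches the configured sheet extent", {
  oc <- optics_config("gaussian", sheet_fov = 40)
  b <- beam_intensity(oc, c(64, 64, 129), c(0.3, 0.3, 1))
  onax <- b$data[33, 33, ]
  expect_equal(lightsieve:::measure_fwhm(onax, 1), 40, tolerance = 0.05)
})

test_that("slit convolution conserves mass exactly and has the printed limits", {
  # beam chosen narrow enough that no tail mass leaves the x-window
  oc <- optics_config("gaussian", sheet_fov = 30)
  sb <- beam_intensity(oc, c(128, 33, 128), c(0.1625, 0.5, 0.1625))
  ill <- illumination_psf(sb, 1.3)
  expect_equal(sum(ill$data) / sum(sb$data), 1.3 / 0.1625, tolerance = 1e-9)
  # one-voxel slit recovers the single beam
  ill1 <- illumination_psf(sb, 0.1625)
  expect_equal(ill1$data, sb$data, tolerance = 1e-9)
  # slit much wider than the field: x-invariant scanned sheet
  illw <- illumination_psf(sb, 3 * 128 * 0.1625)
  v <- illw$data[, 17, 65]
  expect_lt((max(v) - min(v)) / max(v), 0.01)
})

test_that("detection PSF has the scalar-diffraction width and focal symmetry", {
  oc <- optics_config()
  hd <- detection_psf(oc, c(128, 9, 128), c(0.1625, 0.5, 0.1625))
  prof <- hd$data[, 5, 65]
  expect_equal(lightsieve:::measure_fwhm(prof, 0.1625),
               0.51 * oc$lambda_det / oc$na_det, tolerance = 0.1)
  expect_equal(hd$data[, 4, ], hd$data[, 6, ], tolerance = 1e-8)
  # energy spreads monotonically away from focus (lateral second moment)
  x <- (seq_len(128) - 65) * 0.1625
  m2 <- vapply(1:9, function(iy) {
    s <- hd$data[, iy, ]
    sum(outer(x^2, x^2, `+`) * s) / sum(s)
  }, numeric(1))
  expect_true(all(diff(m2[5:9]) > 0))
  expect_true(all(diff(m2[1:5]) < 0))
})

test_that("system PSF composes gating and object blur correctly", {
  oc <- optics_config("gaussian", sheet_fov = 60, d_slit = 50)
  n <- c(64L, 25L, 64L); pitch <- c(0.1625, 0.5, 0.1625)
  sb <- beam_intensity(oc, n, pitch)
  h_ill <- illumination_psf(sb, oc$d_slit)
  h_det <- detection_psf(oc, n, pitch)
  # scatter-free: h_sys is the plain product (unit mass)
  hs0 <- system_psf(h_ill, h_det)
  prod <- h_ill$data * h_det$data
  expect_equal(hs0$data, prod / sum(prod), tolerance = 1e-12)
  # object blur never increases any spectral magnitude
  sp <- scattering_params(50, 22.4)
  ker1 <- object_response(n[c(1, 3)], pitch[c(1, 3)], 20, sp)
  ker2 <- object_response(n[c(1, 3)], pitch[c(1, 3)], 60, sp)
  hs1 <- system_psf(h_ill, h_det, ker1)
  hs2 <- system_psf(h_ill, h_det, ker2)
  f1 <- Mod(fft(hs1$data)); f2 <- Mod(fft(hs2$data))
  expect_true(all(f2 <= f1 + 1e-9 * max(f1)))
  # object-induced spread is confined by the sheet: y-FWHM(h_sys) <= y-FWHM(h_ill)
  yprof_sys <- apply(hs2$data, 2, sum)
  yprof_ill <- apply(h_ill$data * 0 + h_ill$data, 2, sum)
  expect_lte(lightsieve:::measure_fwhm(yprof_sys, 0.5),
             lightsieve:::measure_fwhm(yprof_ill, 0.5) + 1e-9)
  # grid mismatch is refused
  h_small <- detection_psf(oc, c(32, 25, 32), pitch)
  expect_error(system_psf(h_ill, h_small, NULL), "grid")
})

test_that("confocal slit narrows the system PSF along the detection axis", {
  oc <- optics_config("bessel", d_slit = 1.3)
  n <- c(64L, 33L, 64L); pitch <- c(0.1625, 0.5, 0.1625)
  sb <- beam_intensity(oc, n, pitch)
  h_ill <- illumination_psf(sb, oc$d_slit)
  h_det <- detection_psf(oc, n, pitch)
  hs <- system_psf(h_ill, h_det)
  y_sys <- lightsieve:::measure_fwhm(apply(hs$data, 2, sum), 0.5)
  y_ill <- lightsieve:::measure_fwhm(apply(h_ill$data, 2, sum), 0.5)
  expect_lt(y_sys, y_ill)
})
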