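test_that("shifted Hann windows form an exact partition of unity", {
  plan <- deconv_plan(60, 12, 100)
  set.seed(11)
  y <- c(0, 60, runif(1000, 0, 60))
  W <- vapply(seq_len(plan$n_sections), function(i) hann_weight(y, i, plan),
              numeric(length(y)))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
  # window peak at the section center, half weight midway between centers
  expect_equal(hann_weight(plan$y0[5], 5, plan), 1)
  mid <- mean(plan$y0[5:6])
  expect_equal(hann_weight(mid, 5, plan), 0.5, tolerance = 1e-12)
  expect_equal(hann_weight(mid, 6, plan), 0.5, tolerance = 1e-12)
  expect_error(deconv_plan(60, 12, -1), "wiener_A")
  expect_error(deconv_plan(60, 1), "n_sections")
})

test_that("Wiener gain has the inverse-filter and zero-transfer limits", {
  # a kernel with spectral zeros: 4-voxel box along x
  h <- array(0, c(16, 5, 16))
  h[7:10, 3, 8] <- 0.25
  filt_hi <- build_wiener(h, c(1, 1, 1), wiener_A = 1e12)
  H <- fft(lightsieve:::ifftshift(h / sum(h)))
  big <- Mod(H) > 0.5
  expect_equal(Mod(filt_hi$gain[big] * H[big]), rep(1, sum(big)),
               tolerance = 1e-3)
  small <- Mod(H) < 1e-10
  expect_true(any(small))
  expect_true(all(Mod(filt_hi$gain[small]) < 1e-3))
  expect_true(all(is.finite(Mod(filt_hi$gain))))
  expect_error(build_wiener(h, c(1, 1, 1), wiener_A = 0), "wiener_A")
})

test_that("noiseless Wiener round trip recovers the phantom in the support band", {
  ph <- generate_phantom(small_membrane_spec())
  oc <- optics_config("gaussian", d_slit = 50)
  sp <- scattering_params(50, 22.4)
  d <- dim(ph$density$data)
  cache <- lightsieve:::build_psf_cache(oc, d, as.numeric(ph$density$pitch),
                                        lat_support = 33, y_support = 6)
  hs <- system_psf(cache$h_ill, cache$h_det,
                   object_response(cache$lat_n, ph$density$pitch[c(1, 3)], 20, sp))
  # blur by an exact (circular) convolution with h_sys, then invert
  Hf <- fft(lightsieve:::ifftshift(lightsieve:::embed_psf(hs$data, d)))
  blurred <- Re(fft(fft(ph$density$data) * Hf, inverse = TRUE)) / prod(d)
  filt <- build_wiener(lightsieve:::embed_psf(hs$data, d),
                       as.numeric(ph$density$pitch), wiener_A = 1e6)
  dec <- Re(fft(fft(blurred) * filt$gain, inverse = TRUE)) / prod(d)
  Fd <- fft(dec); Fp <- fft(ph$density$data)
  band <- Mod(Hf) / max(Mod(Hf)) > 0.2
  err <- sqrt(sum(Mod(Fd[band] - Fp[band])^2) / sum(Mod(Fp[band])^2))
  expect_lt(err, 0.05)
})

test_that("scatter-free depth-dependent deconvolution equals the single filter", {
  ph <- generate_phantom(small_membrane_spec())
  oc <- optics_config("gaussian", d_slit = 50)
  sp0 <- scattering_params(0, 22.4)
  stack <- simulate_imaging(ph, oc, sp0, noise = NULL)
  cache <- lightsieve:::build_psf_cache(oc, dim(stack$data),
                                        as.numeric(stack$pitch),
                                        lat_support = 33, y_support = 6)
  hs <- system_psf(cache$h_ill, cache$h_det,
                   object_response(cache$lat_n, stack$pitch[c(1, 3)], 0, sp0))
  single <- wiener_deconvolve(stack, hs, wiener_A = 1e4)
  plan <- deconv_plan((dim(stack$data)[2] - 1) * stack$pitch[["y"]], 4, 1e4)
  dd <- depth_dependent_deconvolve(stack, sp0, oc, plan,
                                   lat_support = 33, y_support = 6)
  expect_equal(dd$data, single$data, tolerance = 1e-12)
})

test_that("deconvolution is linear and preserves the mean at large SNR", {
  ph <- generate_phantom(small_membrane_spec())
  oc <- optics_config("gaussian", d_slit = 50)
  sp <- scattering_params(50, 22.4)
  stack <- simulate_imaging(ph, oc, sp, noise = NULL)
  plan <- deconv_plan((dim(stack$data)[2] - 1) * stack$pitch[["y"]], 3, 1e4)
  d1 <- depth_dependent_deconvolve(stack, sp, oc, plan,
                                   lat_support = 33, y_support = 6)
  stack5 <- image_stack(stack$data * 5, stack$pitch)
  d5 <- depth_dependent_deconvolve(stack5, sp, oc, plan,
                                   lat_support = 33, y_support = 6)
  expect_equal(d5$data, 5 * d1$data, tolerance = 1e-10)
  expect_equal(mean(d1$data), mean(stack$data), tolerance = 0.01)
})

test_that("neighborhood-mode deconvolution matches the full-stack mode", {
  ph <- generate_phantom(small_membrane_spec())
  oc <- optics_config("gaussian", d_slit = 50)
  sp <- scattering_params(50, 22.4)
  stack <- simulate_imaging(ph, oc, sp, noise = NULL)
  plan <- deconv_plan((dim(stack$data)[2] - 1) * stack$pitch[["y"]], 4, 100)
  full <- depth_dependent_deconvolve(stack, sp, oc, plan,
                                     lat_support = 33, y_support = 6)
  nb <- depth_dependent_deconvolve(stack, sp, oc, plan, neighborhood = TRUE,
                                   lat_support = 33, y_support = 6)
  # interior planes agree closely; edges differ only through padding context
  mid <- 10:30
  rel <- max(abs(nb$data[, mid, ] - full$data[, mid, ])) / max(abs(full$data))
  expect_lt(rel, 0.05)
  # plan/stack extent mismatch is refused
  expect_error(depth_dependent_deconvolve(stack, sp, oc, deconv_plan(99, 4)),
               "extent")
})
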