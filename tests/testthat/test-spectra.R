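make_plane_with_spectrum <- function(n, pitch, spec_fun) {
  # builds a real image whose DC-normalized magnitude spectrum equals spec_fun(k)
  k <- lightsieve:::k_radial_grid(c(n, n), c(pitch, pitch))
  s <- spec_fun(k)
  Re(lightsieve:::ifft2(s))
}

test_that("noise adaptation reaches the target level and respects fixed points", {
  pitch <- c(1, 1)
  set.seed(4)
  img <- matrix(runif(64 * 64), 64)
  s <- lightsieve:::plane_magnitude(img)
  # zero-noise-like spectrum (fast decay): band integral hits n_l by construction
  s0 <- exp(-lightsieve:::k_radial_grid(c(64, 64), pitch) * 20)
  ad <- noise_adapt_spectrum(s0, 0.01, pitch)
  kx <- lightsieve:::fft_freq(64, 1) * 2
  knorm <- sqrt(outer(kx^2, kx^2, `+`))
  expect_equal(mean(ad[knorm > 0.9]), 0.01, tolerance = 1e-3)
  # already at/above target: unchanged with warning
  expect_warning(out <- noise_adapt_spectrum(s, 1e-6, pitch), "noise level")
  expect_identical(out, s)
  # the floor is only ever raised
  expect_true(all(ad >= s0))
})

test_that("exposure scaling leaves adapted spectra and Q unchanged", {
  set.seed(5)
  img <- matrix(rpois(128 * 128, 40), 128)
  a1 <- noise_adapt_spectrum(lightsieve:::plane_magnitude(img), 0.05, c(1, 1))
  a2 <- noise_adapt_spectrum(lightsieve:::plane_magnitude(img * 7.3), 0.05, c(1, 1))
  expect_equal(a1, a2, tolerance = 1e-12)
  q1 <- contrast_coefficient(img, c(1, 1), k_c = 0.05)
  q2 <- contrast_coefficient(img * 1e3, c(1, 1), k_c = 0.05)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("Q is exactly one for a flat spectrum and decreases under blur", {
  img <- matrix(0, 64, 64); img[20, 31] <- 5   # single bright pixel: |F| flat
  expect_equal(contrast_coefficient(img, c(1, 1), k_c = 0.1, n_l = 0), 1,
               tolerance = 1e-9)
  set.seed(6)
  sharp <- matrix(runif(128 * 128), 128)
  g <- outer(dnorm(-6:6, sd = 2), dnorm(-6:6, sd = 2))
  blurred <- Re(lightsieve:::ifft2(lightsieve:::fft2(sharp) *
    lightsieve:::fft2(lightsieve:::ifftshift(lightsieve:::embed_mat(g / sum(g), c(128, 128))))))
  q_sharp <- contrast_coefficient(sharp, c(1, 1), k_c = 0.05, n_l = 0)
  q_blur <- contrast_coefficient(blurred, c(1, 1), k_c = 0.05, n_l = 0)
  expect_lt(q_blur, q_sharp)
})

test_that("white-noise planes score near unity contrast", {
  set.seed(7)
  img <- matrix(rnorm(128 * 128, 100, 10), 128)
  q <- contrast_coefficient(img, c(1, 1), k_c = 0.05, n_l = 0)
  expect_gt(q, 0.9); expect_lt(q, 1.1)
})

test_that("contrast profile is constant for a stack of identical planes", {
  set.seed(8)
  plane <- matrix(runif(64 * 64), 64)
  arr <- array(plane, c(64, 1, 64))[, rep(1, 10), , drop = FALSE]
  dim(arr) <- c(64, 10, 64)
  st <- image_stack(arr, c(0.5, 1, 0.5))
  pr <- contrast_profile(st, d_cell = 15)
  expect_lt(diff(range(pr$Q)) / mean(pr$Q), 1e-9)
  expect_s3_class(pr, "contrast_profile")
  expect_named(pr, c("y0", "Q"))
})

test_that("spectral widths recover a pure exponential profile", {
  n <- 96; pitch <- 0.5; k0 <- 0.3
  plane <- make_plane_with_spectrum(n, pitch, function(k) exp(-k / k0))
  arr <- array(plane, c(n, 1, n)); dim(arr) <- c(n, 1, n)
  st <- image_stack(arr, c(pitch, 1, pitch))
  w <- spectral_width_map(st, n_theta = 16, debias = FALSE)
  # ring averaging of a convex spectrum biases each bin by O(var(k)/k0^2),
  # about 1e-3 relative on this grid
  expect_equal(unname(w$width), rep(k0, 16), tolerance = 1e-2)
  expect_false(any(w$saturated))
  # isotropy: all directions agree
  expect_lt(diff(range(w$width)) / mean(w$width), 0.03)
})

test_that("normalized depth spectra are unity for identical planes", {
  set.seed(9)
  plane <- matrix(runif(96 * 96), 96)
  arr <- array(plane, c(96, 1, 96))[, rep(1, 12), , drop = FALSE]
  dim(arr) <- c(96, 12, 96)
  st <- image_stack(arr, c(0.5, 1, 0.5))
  ds <- normalized_depth_spectrum(st, b = 1, debias = FALSE)
  expect_lt(max(abs(ds$profile$value - 1)), 1e-9)
  # DC bin present and exactly one
  dc <- dplyr::filter(ds$profile, k_perp == 0, direction == "radial")
  expect_equal(dc$value, rep(1, nrow(dc)), tolerance = 1e-6)
  # dark reference planes are refused
  st2 <- st; st2$data[, 1:3, ] <- 1e-7
  expect_error(normalized_depth_spectrum(st2), "reference planes")
})

test_that("spectra and contrast exports write readable tables", {
  set.seed(10)
  arr <- array(runif(48 * 6 * 48), c(48, 6, 48))
  st <- image_stack(arr, c(0.5, 1, 0.5))
  ds <- normalized_depth_spectrum(st, b = 0, n_ref = 2)
  tf <- tempfile(fileext = ".tsv")
  write_depth_spectrum(ds, tf)
  back <- utils::read.delim(tf)
  expect_equal(nrow(back), nrow(ds$profile))
  expect_true(all(c("y0", "k_perp", "value", "direction") %in% names(back)))
})
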