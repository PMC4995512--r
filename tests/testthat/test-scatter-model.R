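test_that("photon fractions follow the Poisson law and the Lambert-Beer limit", {
  expect_equal(photon_fraction(0, 0, 50), 1)
  expect_equal(photon_fraction(0, 100, 50), exp(-5), tolerance = 1e-12)
  # fractions over all retained orders sum to one
  jm <- max_scatter_order(50, 300)
  expect_gte(sum(photon_fraction(0:jm, 300, 50)), 1 - 1e-6)
  expect_error(photon_fraction(-1, 10, 50), "nonnegative")
  expect_error(photon_fraction(2, -1, 50), ">= 0")
})

test_that("Poisson truncation order closes the mass for optical depths up to 20", {
  for (x in c(0.01, 0.5, 2, 5, 10, 20)) {
    jm <- max_scatter_order(1000, x)   # mu*y0/1000 = x
    expect_gte(ppois(jm, x), 1 - 1e-6)
  }
})

test_that("phase function is a normalized Gaussian of width 1/gamma", {
  g <- 22.4
  expect_equal(integrate(phase_function, -Inf, Inf, gamma = g)$value, 1,
               tolerance = 1e-6)
  th <- seq(-0.2, 0.2, length.out = 101)
  expect_equal(which.max(phase_function(th, g)), 51L)
  set.seed(1)
  draws <- rphase_deflection(1e6, g)
  expect_equal(sd(draws), 1 / g, tolerance = 0.01)
  expect_error(phase_function(0, -1), "gamma")
})

test_that("anisotropy factor has the Rayleigh and forward-scattering limits", {
  expect_equal(anisotropy_factor(1), 1 / tanh(1) - 1, tolerance = 1e-12)
  expect_lt(anisotropy_factor(1e-6), 1e-6)      # gamma -> 0: isotropic
  expect_gt(anisotropy_factor(1e3), 0.998)      # gamma -> Inf: forward
  g <- anisotropy_factor(c(0.5, 1, 5, 20, 100))
  expect_true(all(diff(g) > 0))
  expect_true(all(g > 0 & g < 1))
})

test_that("lateral widths are zero for ballistic photons and linear in depth", {
  expect_equal(lateral_sigma(0, 123, 22.4), 0)
  expect_equal(lateral_sigma(3, 100, 22.4), 2 * lateral_sigma(3, 50, 22.4))
})

test_that("photon walk reproduces Lambert-Beer fraction and width law", {
  sp <- scattering_params(50, 22.4)
  w <- simulate_photon_walk(2e5, 50, sp, rng_seed = 7)
  p0 <- exp(-50 * 50 / 1000)
  se <- sqrt(p0 * (1 - p0) / 2e5)
  expect_lt(abs(mean(w$j == 0) - p0), 3 * se)
  # single-scatter displacement std (oracle for the sqrt(j/3) width law)
  expect_equal(sd(w$dx[w$j == 1]), lateral_sigma(1, 50, 22.4), tolerance = 0.02)
  # double-scatter variance: 2 (y0/gamma)^2 / 3 per axis
  expect_equal(var(w$dz[w$j == 2]), 2 * (50 / 22.4)^2 / 3, tolerance = 0.05)
  # scatter-free medium: nothing moves
  w0 <- simulate_photon_walk(100, 50, scattering_params(0, 22.4), rng_seed = 1)
  expect_true(all(w0$j == 0) && all(w0$dx == 0) && all(w0$dz == 0))
  # reproducibility
  a <- simulate_photon_walk(500, 40, sp, rng_seed = 5)
  b <- simulate_photon_walk(500, 40, sp, rng_seed = 5)
  expect_identical(a, b)
})

test_that("scatter-count histogram matches the Poisson fractions", {
  sp <- scattering_params(50, 22.4)
  n <- 1e5
  w <- simulate_photon_walk(n, 60, sp, rng_seed = 13)
  x <- 50 * 60 / 1000
  for (j in 0:6) {
    p <- dpois(j, x)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(w$j == j) - p), 3 * se + 1e-12)
  }
})

test_that("object response kernel is a unit-mass delta in the scatter-free limits", {
  sp <- scattering_params(50, 22.4)
  k0 <- object_response(33, 0.1625, 0, sp)
  expect_equal(sum(k0), 1, tolerance = 1e-4)
  expect_equal(max(k0), 1)
  k1 <- object_response(33, 0.1625, 30, scattering_params(0, 22.4))
  expect_equal(max(k1), 1)
  expect_warning(object_response(65, 0.1625, 100, sp, j_max = 1), "extended")
})

test_that("sampled kernel transform matches the analytic transfer", {
  sp <- scattering_params(50, 22.4)
  n <- 128; pitch <- 0.1625
  ker <- object_response(n, pitch, 30, sp)
  expect_equal(sum(ker), 1, tolerance = 1e-4)
  H_fft <- Re(lightsieve:::fft2(lightsieve:::ifftshift(ker)))
  k <- lightsieve:::k_radial_grid(c(n, n), c(pitch, pitch))
  H_ana <- object_transfer(k, 30, sp)
  expect_lt(max(abs(H_fft - H_ana)), 1e-3)
})

test_that("object transfer has unit DC, ballistic floor and monotone decay", {
  sp <- scattering_params(50, 22.4)
  expect_equal(object_transfer(0, 47, sp), 1, tolerance = 1e-9)
  # high-frequency limit: only the ballistic constant survives
  expect_equal(object_transfer(1e4, 40, sp), exp(-50 * 40 / 1000),
               tolerance = 1e-6)
  k <- seq(0, 2, by = 0.01)
  for (y0 in c(5, 20, 60)) {
    h <- object_transfer(k, y0, sp)
    expect_true(all(diff(h) <= 1e-12))
    expect_true(all(h >= exp(-50 * y0 / 1000) - 1e-9))
  }
  # monotone depth decay at fixed k
  for (kk in c(0.05, 0.2, 0.5)) {
    hy <- vapply(c(0, 10, 25, 40, 60), function(y) object_transfer(kk, y, sp),
                 numeric(1))
    expect_true(all(diff(hy) <= 1e-12))
  }
  # forward-scattering limit: no information loss at any frequency
  expect_equal(object_transfer(c(0.1, 1, 3), 60, scattering_params(50, 1e6)),
               rep(1, 3), tolerance = 1e-6)
})
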