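test_that("forward-simulated depth spectra match the analytic transfer model", {
  st <- texture_stack_input()
  sp <- scattering_params(50, 22.4)
  oc <- optics_config("gaussian", d_slit = 50)
  sim <- simulate_imaging(st, oc, sp, noise = NULL)
  ds <- normalized_depth_spectrum(sim, debias = FALSE)
  pr <- dplyr::filter(ds$profile, direction == "radial", k_perp > 0,
                      k_perp <= 0.8 * ds$k_N)
  for (y in c(10.2, 19.8, 34.8)) {
    row <- pr[abs(pr$y0 - y) < 0.01, ]
    m <- lightsieve:::model_spectrum(row$k_perp, row$y0, 50, 22.4, 1 / sqrt(3),
                                     ds$b, ds$dy, 60, ds$ref_depths)
    expect_lt(sqrt(mean((row$value - m)^2)) / mean(m), 0.05)
  }
})

test_that("blind fitting recovers the generating parameters on clean transfer data", {
  st <- texture_stack_input()
  sp <- scattering_params(50, 22.4)
  oc <- optics_config("gaussian", d_slit = 50)
  sim <- simulate_imaging(st, oc, sp, noise_model(5000, 3, 31))
  ds <- normalized_depth_spectrum(sim)
  fit <- fit_scattering_params(ds, n_boot = 25)
  expect_equal(fit$mu_sca, 50, tolerance = 0.1)
  expect_equal(fit$gamma, 22.4, tolerance = 0.1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("a scatter-free stack yields a near-zero scattering coefficient", {
  st <- texture_stack_input(n_lat = 96, n_y = 40)
  oc <- optics_config("gaussian", d_slit = 50)
  sim <- simulate_imaging(st, oc, scattering_params(0, 22.4),
                          noise_model(5000, 3, 41))
  ds <- normalized_depth_spectrum(sim)
  fit <- fit_scattering_params(ds, n_boot = 0)
  expect_lt(fit$mu_sca, 2)
})

test_that("the fit refuses a single depth plane", {
  st <- texture_stack_input(n_lat = 64, n_y = 6)
  oc <- optics_config("gaussian", d_slit = 50)
  sim <- simulate_imaging(st, oc, scattering_params(50, 22.4),
                          noise_model(5000, 3, 51))
  ds <- normalized_depth_spectrum(sim, n_ref = 2)
  one <- ds
  one$profile <- dplyr::filter(ds$profile, y0 <= max(ds$ref_depths) + ds$dy + 0.01)
  expect_error(suppressWarnings(fit_scattering_params(one, n_boot = 0)),
               "single depth")
})

test_that("recovery holds across the parameter plane at the default budget", {
  grid <- expand.grid(mu = c(20, 50, 80), gamma = c(10, 22.4, 40))
  oc <- optics_config("gaussian", d_slit = 50)
  errs <- purrr::pmap_dfr(grid, function(mu, gamma) {
    st <- texture_stack_input(seed = 100 + round(mu + gamma))
    sim <- simulate_imaging(st, oc, scattering_params(mu, gamma),
                            noise_model(5000, 3, round(mu * gamma)))
    ds <- normalized_depth_spectrum(sim)
    fit <- fit_scattering_params(ds, n_boot = 0)
    tibble::tibble(mu_err = abs(fit$mu_sca - mu) / mu,
                   gamma_err = abs(fit$gamma - gamma) / gamma)
  })
  expect_lte(median(errs$mu_err), 0.10)
  expect_lte(median(errs$gamma_err), 0.10)
})

test_that("normalized spectra stay between the ballistic floor and unity", {
  st <- texture_stack_input(n_lat = 96, n_y = 40)
  sp <- scattering_params(50, 22.4)
  oc <- optics_config("gaussian", d_slit = 50)
  sim <- simulate_imaging(st, oc, sp, noise_model(5000, 3, 61))
  ds <- normalized_depth_spectrum(sim)
  pr <- dplyr::filter(ds$profile, direction == "radial",
                      k_perp > 0.05, k_perp <= 0.5,
                      y0 > max(ds$ref_depths))
  floor_v <- exp(-50 * pr$y0 / 1000)
  eps <- 0.1
  expect_true(all(pr$value >= floor_v - eps))
  expect_true(all(pr$value <= 1 + eps))
})

test_that("the tabulated system kz response reduces to the optics at zero blur", {
  oc <- optics_config("gaussian", sheet_fov = 60, d_slit = 1.3)
  kzt <- system_kz_transfer(oc, c(64, 17, 64), c(0.325, 0.5, 0.325),
                            sigma_max = 3, n_sigma = 7)
  expect_s3_class(kzt, "kz_transfer")
  expect_equal(kzt$dc[1], 1)
  # gated light and high-frequency response decrease with blur width
  expect_true(all(diff(kzt$dc) <= 1e-9))
  expect_true(all(kzt$A[nrow(kzt$A), ] <= kzt$A[1, ] + 1e-6))
  mid <- kzt$A[4, ]
  expect_lt(mid[length(mid)], mid[1])
})
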