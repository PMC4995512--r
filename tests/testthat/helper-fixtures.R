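# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no data files.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# canonical study conditions: 41.6 x 60 x 41.6 um membrane lattice at the
# camera-limited pitch, imaged in Gauss/widefield with the fitted parameters
canonical_spec <- function(seed = 42L) phantom_spec(rng_seed = seed)

canonical_gauss_stack <- function() {
  fixture("gauss_stack", function() {
    ph <- generate_phantom(canonical_spec())
    oc <- optics_config("gaussian", d_slit = 50)
    sp <- scattering_params(50, 22.4)
    st <- simulate_imaging(ph, oc, sp, noise_model(5000, 3, 7))
    list(phantom = ph, optics = oc, params = sp, stack = st)
  })
}

# small, quickly packable membrane phantom for module tests
small_membrane_spec <- function(seed = 3L) {
  phantom_spec(dims_um = c(20.8, 20, 20.8), pitch = c(0.325, 0.5, 0.325),
               inner_cell_size = c(3, 4.5), outer_cell_size = c(5, 8),
               rng_seed = seed)
}

# y-invariant random texture: its object spectrum cancels exactly in the
# reference normalization, isolating the transfer estimation machinery
texture_stack_input <- function(n_lat = 128, n_y = 60, pitch = c(0.325, 0.6, 0.325),
                                seed = 11L, fill = 0.12, smooth_um = 0.4) {
  set.seed(seed)
  plane <- matrix(as.numeric(stats::runif(n_lat * n_lat) < fill), n_lat)
  # mild lateral smoothing gives the object a decaying spectrum, like tissue
  k2 <- lightsieve:::k_radial_grid(c(n_lat, n_lat), pitch[c(1, 3)])^2
  plane <- Re(lightsieve:::ifft2(lightsieve:::fft2(plane) *
                                   exp(-2 * pi^2 * smooth_um^2 * k2)))
  plane[plane < 0] <- 0
  arr <- array(plane, c(n_lat, 1L, n_lat))[, rep(1L, n_y), , drop = FALSE]
  dim(arr) <- c(n_lat, n_y, n_lat)
  image_stack(arr, pitch)
}

# mixed-distribution Kolmogorov-Smirnov distance (handles the ballistic atom
# at zero displacement, where ks.test() mis-handles ties)
ks_distance_mixed <- function(x, cdf) {
  n <- length(x)
  xs <- sort(unique(x))
  counts <- tabulate(match(x, xs), length(xs))
  Fn <- cumsum(counts) / n
  Fn_left <- Fn - counts / n
  Fx <- cdf(xs)
  Fx_left <- cdf(xs - 1e-9)
  max(abs(Fn - Fx), abs(Fn_left - Fx_left))
}

# analytic CDF of the pooled lateral-displacement mixture
scatter_mixture_cdf <- function(y0, params) {
  jm <- max_scatter_order(params$mu_sca, y0)
  j <- 0:jm
  cj <- photon_fraction(j, y0, params$mu_sca)
  sj <- lateral_sigma(j, y0, params$gamma, params$sigma_coef)
  function(q) {
    vapply(q, function(v) {
      sum(cj * ifelse(sj == 0, as.numeric(v >= 0), stats::pnorm(v, 0, sj)))
    }, numeric(1))
  }
}
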