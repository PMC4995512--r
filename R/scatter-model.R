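# Analytic photon-diffusion model for fluorescence detection through a
# scattering sample. A photon emitted at detection depth y0 (micrometers)
# traverses the tissue toward the detection objective; scattering events occur
# at rate mu_sca (per millimeter) and each event deflects the propagation
# direction by a small Gaussian-distributed angle of width 1/gamma per
# transverse axis. The number of events j is Poisson distributed; order j
# photons are laterally displaced by a zero-mean Gaussian whose per-axis
# standard deviation grows linearly with depth.

#' Scattering parameters of a turbid material
#'
#' Bundles the scattering coefficient and the angular-width parameter of the
#' Gaussian scattering phase function, the two material constants of the
#' photon-diffusion model.
#'
#' @param mu_sca scattering coefficient in 1/mm (0 allowed for a scatter-free
#'   medium). Probability per unit path length of a scattering event.
#' @param gamma dimensionless angular-width parameter (> 0). The per-axis
#'   deflection angle at each scattering event is Gaussian with standard
#'   deviation `1/gamma` radians; large `gamma` means forward scattering.
#' @param sigma_coef coefficient of the order-j lateral width law
#'   `sigma_j = sigma_coef * (y0 / gamma) * sqrt(j)`. The default
#'   `1/sqrt(3)` follows from deflections occurring uniformly along the exit
#'   path (mean-square lever arm `y0^2/3`) with independent events adding
#'   variances; it is exposed so alternative width laws can be injected.
#' @return object of class `scattering_params`.
#' @examples
#' sp <- scattering_params(mu_sca = 50, gamma = 22.4)
#' anisotropy_factor(sp$gamma)
#' @export
scattering_params <- function(mu_sca, gamma, sigma_coef = 1 / sqrt(3)) {
  stopifnot(is.numeric(mu_sca), length(mu_sca) == 1, is.finite(mu_sca),
            is.numeric(gamma), length(gamma) == 1, is.finite(gamma),
            is.numeric(sigma_coef), length(sigma_coef) == 1, sigma_coef > 0)
  if (mu_sca < 0) stop("`mu_sca` must be >= 0 (1/mm)")
  if (gamma <= 0) stop("`gamma` must be > 0")
  structure(
    list(mu_sca = mu_sca, gamma = gamma, sigma_coef = sigma_coef),
    class = "scattering_params"
  )
}

#' @export
print.scattering_params <- function(x, ...) {
  cat(sprintf(
    "<scattering_params> mu_sca = %.4g /mm, gamma = %.4g (g_HG = %.4f)\n",
    x$mu_sca, x$gamma, anisotropy_factor(x$gamma)
  ))
  invisible(x)
}

#' Fraction of j-times-scattered photons at a given detection depth
#'
#' The scattering orders follow a Poisson law in the optical depth
#' `mu_sca * y0`: `c_j = (mu_sca y0)^j / j! * exp(-mu_sca y0)`. For j = 0 this
#' is the Lambert-Beer law for the surviving ballistic fraction.
#'
#' @param j scattering order(s), nonnegative integer.
#' @param y0 detection depth in micrometers (>= 0).
#' @param mu_sca scattering coefficient in 1/mm.
#' @return fractions in `[0, 1]`; summing over all j gives 1.
#' @examples
#' photon_fraction(0, y0 = 100, mu_sca = 50)  # exp(-5)
#' @export
photon_fraction <- function(j, y0, mu_sca) {
  if (any(j < 0) || any(j != floor(j))) stop("`j` must be a nonnegative integer")
  if (any(y0 < 0)) stop("`y0` must be >= 0 (micrometers)")
  if (any(mu_sca < 0)) stop("`mu_sca` must be >= 0 (1/mm)")
  x <- mu_sca * y0 / 1000  # optical depth, dimensionless
  stats::dpois(j, x)
}

#' Smallest truncation order holding all but a tail of the Poisson mass
#'
#' @param mu_sca scattering coefficient, 1/mm.
#' @param y0 depth, micrometers.
#' @param tail tolerated missing mass (default 1e-6).
#' @return integer j_max with `sum(c_0..c_jmax) >= 1 - tail`.
#' @export
max_scatter_order <- function(mu_sca, y0, tail = 1e-6) {
  x <- mu_sca * y0 / 1000
  if (x == 0) return(0L)
  as.integer(stats::qpois(1 - tail, x))
}

#' Gaussian scattering phase function
#'
#' Probability density of the per-axis angular deflection at a single
#' scattering event: zero-mean Gaussian with standard deviation `1/gamma`.
#'
#' @param theta deflection angle(s) in radians.
#' @param gamma angular-width parameter (> 0).
#' @export
phase_function <- function(theta, gamma) {
  if (gamma <= 0) stop("`gamma` must be > 0")
  stats::dnorm(theta, mean = 0, sd = 1 / gamma)
}

#' Draw deflection angles from the scattering phase function
#'
#' @param n number of draws.
#' @inheritParams phase_function
#' @export
rphase_deflection <- function(n, gamma) {
  if (gamma <= 0) stop("`gamma` must be > 0")
  stats::rnorm(n, 0, 1 / gamma)
}

#' Anisotropy factor of the phase function
#'
#' Mean cosine of the scattering angle, as used by the Henyey-Greenstein
#' description: the Langevin function `coth(gamma) - 1/gamma`. Tends to 0 for
#' Rayleigh-like wide-angle scatterers (`gamma -> 0`) and to 1 for pure
#' forward scatterers (`gamma -> Inf`).
#'
#' @inheritParams phase_function
#' @return g in (0, 1).
#' @export
anisotropy_factor <- function(gamma) {
  if (any(gamma <= 0)) stop("`gamma` must be > 0")
  ifelse(
    gamma < 1e-4,
    gamma / 3 - gamma^3 / 45,            # series; avoids catastrophic cancellation
    1 / tanh(gamma) - 1 / gamma
  )
}

#' Per-axis lateral width of the order-j displacement kernel
#'
#' Standard deviation (micrometers, per transverse axis) of the lateral
#' displacement accumulated by a photon scattered j times while traversing a
#' depth `y0`: `sigma_coef * (y0 / gamma) * sqrt(j)`. Ballistic photons
#' (j = 0) have zero width.
#'
#' @param j scattering order(s).
#' @param y0 depth in micrometers.
#' @param gamma angular-width parameter.
#' @param sigma_coef width-law coefficient, default `1/sqrt(3)`.
#' @export
lateral_sigma <- function(j, y0, gamma, sigma_coef = 1 / sqrt(3)) {
  if (any(j < 0)) stop("`j` must be >= 0")
  if (any(y0 < 0)) stop("`y0` must be >= 0")
  if (gamma <= 0) stop("`gamma` must be > 0")
  sigma_coef * (y0 / gamma) * sqrt(j)
}

#' Depth-dependent object transfer function
#'
#' Fourier-domain attenuation that propagation through the scattering sample
#' applies to each lateral spatial frequency of the image:
#' `H_obj(k, y0) = sum_j c_j(y0) exp(-2 pi^2 sigma_j(y0)^2 k^2)`,
#' a Gaussian mixture whose constant high-frequency floor `exp(-mu_sca y0)`
#' is the ballistic fraction. Frequencies are in cycles/um.
#'
#' @param k_perp lateral spatial frequency (vector, matrix or array),
#'   cycles/um.
#' @param y0 detection depth, micrometers (scalar).
#' @param params a [scattering_params()] object.
#' @param j_max truncation order; default holds all but 1e-6 of the Poisson
#'   mass.
#' @return transfer values in (0, 1], same shape as `k_perp`.
#' @export
object_transfer <- function(k_perp, y0, params, j_max = NULL) {
  stopifnot(inherits(params, "scattering_params"), y0 >= 0)
  if (is.null(j_max)) j_max <- max_scatter_order(params$mu_sca, y0)
  j <- 0:j_max
  cj <- photon_fraction(j, y0, params$mu_sca)
  sj <- lateral_sigma(j, y0, params$gamma, params$sigma_coef)
  out <- 0
  k2 <- k_perp^2
  for (i in seq_along(j)) out <- out + cj[i] * exp(-2 * pi^2 * sj[i]^2 * k2)
  # renormalize away the truncated tail so H(0) = 1 exactly
  out / sum(cj)
}

#' Real-space object response kernel
#'
#' Samples the lateral (x, z) displacement kernel of the scattering model on a
#' regular grid: a central delta of mass `c_0` plus isotropic Gaussians of
#' mass `c_j` and per-axis width `sigma_j`. The kernel has unit mass.
#'
#' @param n number of samples per axis (scalar or length 2); use an odd count
#'   to center the delta on a sample, even counts center at `n/2 + 1`.
#' @param pitch grid pitch in micrometers (scalar or length 2).
#' @param y0 detection depth, micrometers.
#' @param params a [scattering_params()] object.
#' @param j_max truncation order (default: Poisson mass rule). If the given
#'   order leaves more than 1e-6 of mass it is extended with a warning.
#' @return matrix kernel with `sum(kernel) == 1` (within 1e-4), centered at
#'   `floor(n/2) + 1`.
#' @export
object_response <- function(n, pitch, y0, params, j_max = NULL) {
  stopifnot(inherits(params, "scattering_params"))
  n <- rep(as.integer(n), length.out = 2)
  pitch <- rep(pitch, length.out = 2)
  j_need <- max_scatter_order(params$mu_sca, y0)
  if (is.null(j_max)) {
    j_max <- j_need
  } else if (j_max < j_need) {
    warning(sprintf("j_max = %d misses > 1e-6 of the Poisson mass; extended to %d",
                    j_max, j_need))
    j_max <- j_need
  }
  cen <- floor(n / 2) + 1L
  xs <- (seq_len(n[1]) - cen[1]) * pitch[1]
  zs <- (seq_len(n[2]) - cen[2]) * pitch[2]
  j <- 0:j_max
  cj <- photon_fraction(j, y0, params$mu_sca)
  cj <- cj / sum(cj)
  sj <- lateral_sigma(j, y0, params$gamma, params$sigma_coef)
  ker <- matrix(0, n[1], n[2])
  ker[cen[1], cen[2]] <- cj[1]
  for (i in seq_along(j)[-1]) {
    if (sj[i] < pitch[1] / 4) {  # unresolvable: bin into the central pixel
      ker[cen[1], cen[2]] <- ker[cen[1], cen[2]] + cj[i]
      next
    }
    gx <- exp(-xs^2 / (2 * sj[i]^2))
    gz <- exp(-zs^2 / (2 * sj[i]^2))
    g <- outer(gx, gz)
    ker <- ker + cj[i] * g / sum(g)   # discrete normalization: mass exactly c_j
  }
  ker
}

#' Monte-Carlo photon walk through the scattering slab
#'
#' Independent verification oracle for the analytic model: each photon
#' traverses depth `y0` with exponential free paths at rate `mu_sca`; at every
#' scattering event the propagation direction acquires a Gaussian deflection
#' (std `1/gamma` per transverse axis) and the lateral displacement is
#' accumulated segment by segment in the small-angle approximation.
#'
#' @param n_photons number of photons (>= 1).
#' @param y0 slab thickness / detection depth, micrometers.
#' @param params a [scattering_params()] object.
#' @param rng_seed optional integer seed for reproducibility.
#' @return tibble with one row per photon: scattering order `j` and lateral
#'   exit displacements `dx`, `dz` in micrometers.
#' @export
simulate_photon_walk <- function(n_photons, y0, params, rng_seed = NULL) {
  stopifnot(n_photons >= 1, inherits(params, "scattering_params"), y0 >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- as.integer(n_photons)
  rate <- params$mu_sca / 1000  # events per micrometer
  j <- integer(n); dx <- numeric(n); dz <- numeric(n)
  if (rate == 0 || y0 == 0) {
    return(tibble::tibble(photon = seq_len(n), j = j, dx = dx, dz = dz))
  }
  pos <- stats::rexp(n, rate)          # position of next scattering event
  ax <- numeric(n); az <- numeric(n)   # current propagation angles
  last <- numeric(n)                   # position of previous event
  active <- which(pos < y0)
  while (length(active)) {
    seg <- pos[active] - last[active]
    dx[active] <- dx[active] + ax[active] * seg
    dz[active] <- dz[active] + az[active] * seg
    j[active] <- j[active] + 1L
    ax[active] <- ax[active] + stats::rnorm(length(active), 0, 1 / params$gamma)
    az[active] <- az[active] + stats::rnorm(length(active), 0, 1 / params$gamma)
    last[active] <- pos[active]
    pos[active] <- pos[active] + stats::rexp(length(active), rate)
    active <- active[pos[active] < y0]
  }
  # final straight segment to the exit plane
  seg <- y0 - last
  dx <- dx + ax * seg
  dz <- dz + az * seg
  tibble::tibble(photon = seq_len(n), j = j, dx = dx, dz = dz)
}
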