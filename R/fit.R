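# Blind extraction of the scattering parameters (mu_sca, gamma) from
# reference-normalized depth spectra: joint nonlinear least squares of the
# Gaussian-mixture object transfer model across all depths, with optional
# confocal re-weighting of the scattering orders and bootstrap confidence
# intervals from resampled depth planes.

# Model evaluation ------------------------------------------------------------

# Per-order weight modifiers for confocal k_z-axis fitting. A confocal slit
# gates laterally displaced photons, so along the k_z axis each order-j
# Gaussian enters with the overlap of its x-marginal with the illumination
# x-profile u(x): beta_j = sum(u * N(x; sigma_j)) / sum(N(x; sigma_j)),
# normalized so sigma -> 0 gives u(0) = 1 (unit-peak profile). For a wide
# (widefield) profile all beta_j -> 1.
confocal_order_weights <- function(sigma, profile) {
  if (is.null(profile)) return(rep(1, length(sigma)))
  x <- profile$x
  u <- profile$u / max(profile$u)
  dx <- stats::median(diff(x))
  vapply(sigma, function(s) {
    if (s < dx / 4) return(1)
    w <- stats::dnorm(x, 0, s)
    sum(u * w) / sum(w)
  }, numeric(1))
}

# Transfer of the scattering-order mixture at one depth. Three flavours:
# plain Gaussian mixture (widefield), mixture re-weighted by the central
# illumination x-profile (simple confocal approximation), or the numerically
# tabulated k_z system response (full confocal treatment, see
# [system_kz_transfer()]).
transfer_at_depth <- function(k, y0, mu, gamma, sigma_coef, profile = NULL,
                              kz_transfer = NULL, j_cap = 80L) {
  x <- mu * y0 / 1000
  jm <- min(max_scatter_order(mu, y0), j_cap)
  j <- 0:jm
  cj <- stats::dpois(j, x)
  sj <- sigma_coef * (y0 / gamma) * sqrt(j)
  if (!is.null(kz_transfer)) {
    nk <- length(k)
    vals <- kz_transfer_eval(kz_transfer,
                             rep(sj, each = nk), rep(k, times = length(j)))
    num <- as.vector(matrix(vals, nk, length(j)) %*% cj)
    dc <- sum(kz_transfer_dc(kz_transfer, sj) * cj)
    return(num / dc)
  }
  bj <- confocal_order_weights(sj, profile)
  w <- cj * bj
  num <- 0
  k2 <- k^2
  for (i in seq_along(j)) num <- num + w[i] * exp(-2 * pi^2 * sj[i]^2 * k2)
  num / sum(w)   # DC normalization: each plane spectrum is divided by its DC
}

# Model prediction replicating the measurement pipeline: plane smoothing over
# y0 +- b planes and division by the mean reference transfer.
model_spectrum <- function(k, y0, mu, gamma, sigma_coef, b, dy, ny,
                           ref_depths, profile = NULL, kz_transfer = NULL) {
  uy <- sort(unique(y0))
  uk <- sort(unique(k))
  # transfer once per needed depth on the common frequency grid
  windows <- lapply(uy, function(u) {
    iy <- round(u / dy) + 1
    (seq(max(1, iy - b), min(ny, iy + b)) - 1) * dy
  })
  need <- sort(unique(c(unlist(windows), ref_depths)))
  Tm <- vapply(need, function(yd) {
    transfer_at_depth(uk, yd, mu, gamma, sigma_coef, profile, kz_transfer)
  }, numeric(length(uk)))
  Tm <- matrix(Tm, nrow = length(uk))
  ki <- match(k, uk)
  pred <- numeric(length(k))
  for (i in seq_along(uy)) {
    rows <- which(y0 == uy[i])
    cols <- match(windows[[i]], need)
    sm <- rowMeans(Tm[, cols, drop = FALSE])
    pred[rows] <- sm[ki[rows]]
  }
  # reference transfer on every k (deviates from 1 only by a few percent at
  # shallow reference depths, but correcting it removes a bias)
  refv <- rowMeans(Tm[, match(ref_depths, need), drop = FALSE])
  pred / refv[ki]
}

# Fitting ----------------------------------------------------------------------

#' Fit scattering parameters to normalized depth spectra
#'
#' Joint weighted nonlinear least squares of the depth-dependent transfer
#' model (Poisson order weights, Gaussian widths growing as
#' `sigma_coef * y0 sqrt(j) / gamma`) to the reference-normalized spectra of
#' all planes, sharing one `(mu_sca, gamma)` across depths. The model
#' prediction reproduces the measurement pipeline (plane smoothing, reference
#' division), and in `confocal_kz` mode only the k_z-axis wedge is used, with
#' scattering orders optionally re-weighted by the illumination x-profile.
#'
#' @param spectrum a [normalized_depth_spectrum()] result.
#' @param mode `"widefield"` (azimuthally averaged data) or `"confocal_kz"`
#'   (k_z-axis wedge only).
#' @param k_min,k_max fit band, cycles/um; `k_max = NULL` caps the band at
#'   `0.8 k_N`. Independently, frequencies whose reference spectrum falls
#'   below `ref_snr_min` times its white-noise floor are excluded (there the
#'   normalized ratio measures noise against noise, not transfer).
#' @param ref_snr_min minimum reference-spectrum SNR retained in the fit.
#' @param ref_abs_min minimum reference magnitude (relative to DC) retained;
#'   guards the noise-free limit, where beyond the optical passband the
#'   reference is numerically zero and ratios are meaningless.
#' @param y_min depths below this (micrometers) are excluded (the reference
#'   planes carry no depth information); default just above the last
#'   reference plane.
#' @param objective `"log"` (default) fits log-transfer residuals, which
#'   balances the ballistic plateau against the low-frequency Gaussian and is
#'   robust to the multiplicative object-spectrum confound; `"linear"` fits
#'   plain differences.
#' @param scale_per_depth profile out one free amplitude per depth plane
#'   (default TRUE). The object's spectral content varies with depth (cells
#'   change size along the detection path), which multiplies each plane's
#'   normalized spectrum by a nuisance factor; a per-depth scale absorbs it
#'   while `(mu_sca, gamma)` remain identified by the within-plane shape.
#' @param scale_per_freq additionally profile out one free amplitude per
#'   frequency bin (default TRUE with the log objective, unavailable with
#'   the linear one). The reference spectrum is measured from only `n_ref`
#'   planes, so its realization noise — and any depth-stable part of the
#'   object confound — enters every depth as a common k-dependent factor
#'   that does not average out; a per-frequency scale absorbs it. The two
#'   nuisance sets leave `(mu_sca, gamma)` identified by the non-separable
#'   part of the transfer, the depth-progressive spectral narrowing, which
#'   no product of a depth factor and a frequency factor can imitate.
#' @param sigma_coef width-law coefficient (see [scattering_params()]).
#' @param illumination_profile optional tibble `(x, u)` from
#'   [illumination_xprofile()] for confocal order re-weighting; ignored in
#'   widefield mode.
#' @param kz_transfer optional [system_kz_transfer()] table; when given (in
#'   `confocal_kz` mode) the numerically tabulated optics response replaces
#'   both the Gaussian transfer and the profile re-weighting. Preferred for
#'   beams with out-of-focus structure (Bessel ring system).
#' @param n_boot bootstrap resamples of depth planes for confidence
#'   intervals (0 disables).
#' @param start optional `c(mu_sca, gamma)` starting values; by default a
#'   small grid of plausible starts is screened.
#' @param lower,upper box constraints for `c(mu_sca, gamma)`.
#' @return object of class `scatter_fit` with elements `params`
#'   ([scattering_params()]), estimates, bootstrap CIs, residual norm and the
#'   fitted data. Methods: [tidy()], [glance()], `autoplot()`.
#' @export
fit_scattering_params <- function(spectrum,
                                  mode = c("widefield", "confocal_kz"),
                                  k_min = 0, k_max = NULL,
                                  ref_snr_min = 20, ref_abs_min = 1e-5,
                                  y_min = NULL,
                                  objective = c("log", "linear"),
                                  scale_per_depth = TRUE,
                                  scale_per_freq = NULL,
                                  sigma_coef = 1 / sqrt(3),
                                  illumination_profile = NULL,
                                  kz_transfer = NULL,
                                  n_boot = 200, start = NULL,
                                  lower = c(0, 0.5), upper = c(500, 500)) {
  stopifnot(inherits(spectrum, "depth_spectrum"))
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  if (is.null(scale_per_freq)) scale_per_freq <- objective == "log"
  if (scale_per_freq && objective != "log") {
    stop("`scale_per_freq` is only available with the log objective")
  }
  if (scale_per_freq && !scale_per_depth) {
    stop("`scale_per_freq` requires `scale_per_depth`")
  }
  dir <- if (mode == "widefield") "radial" else "kz"
  if (mode != "confocal_kz") kz_transfer <- NULL
  profile <- if (mode == "confocal_kz" && is.null(kz_transfer)) {
    illumination_profile
  } else NULL
  pr <- dplyr::filter(spectrum$profile, .data$direction == dir)

  if (is.null(y_min)) y_min <- max(spectrum$ref_depths) + spectrum$dy / 2
  if (is.null(k_max)) k_max <- 0.8 * spectrum$k_N
  # keep only frequencies where the reference spectrum carries signal
  refp <- dplyr::filter(spectrum$ref_profile, .data$direction == dir)
  k_ok <- refp$k_perp[refp$ref_value >= ref_snr_min * spectrum$ref_floor &
                        refp$ref_value >= ref_abs_min]
  pr <- dplyr::filter(pr, .data$k_perp > k_min, .data$k_perp <= k_max,
                      .data$k_perp %in% k_ok,
                      .data$y0 >= y_min, is.finite(.data$value),
                      .data$value > 0)
  depths <- sort(unique(pr$y0))
  if (length(depths) < 2) {
    stop("scattering parameters are not identifiable from a single depth plane; ",
         "need spectra from at least 2 (ideally >= 3) depths")
  }
  if (scale_per_freq && length(unique(pr$k_perp)) < 3) {
    stop("fewer than 3 usable frequency bins; the per-frequency nuisance ",
         "scale leaves nothing to fit (set `scale_per_freq = FALSE`)")
  }
  if (length(depths) < 3 || diff(range(depths)) < 20) {
    warning("fewer than 3 depths or depth span < 20 um; fit may be poorly ",
            "constrained")
  }
  ny <- max(round(max(pr$y0) / spectrum$dy)) + 1

  resid_fun <- function(p, dat) {
    m <- model_spectrum(dat$k_perp, dat$y0, p[1], p[2], sigma_coef,
                        spectrum$b, spectrum$dy, ny, spectrum$ref_depths,
                        profile, kz_transfer)
    w <- dat$n_pix
    fy <- dat$fy
    if (objective == "log") {
      lr <- log(m) - log(dat$value)
      if (scale_per_depth && scale_per_freq) {
        # weighted two-way (depth x frequency) nuisance fit by alternating
        # sweeps; converges geometrically for this balanced layout
        fk <- droplevels(dat$fk)
        ak <- rep(0, nlevels(fk)); names(ak) <- levels(fk)
        wy <- tapply(w, fy, sum); wk <- tapply(w, fk, sum)
        for (it in seq_len(15)) {
          la <- tapply(w * (lr - ak[fk]), fy, sum) / wy
          ak <- tapply(w * (lr - la[fy]), fk, sum) / wk
        }
        lr <- lr - la[fy] - ak[fk]
      } else if (scale_per_depth) {
        la <- (tapply(w * lr, fy, sum) / tapply(w, fy, sum))[fy]
        lr <- lr - la
      }
      lr * sqrt(w)
    } else {
      if (scale_per_depth) {
        a <- (tapply(w * m * dat$value, fy, sum) / tapply(w * m * m, fy, sum))[fy]
        m <- a * m
      }
      (m - dat$value) * sqrt(w)
    }
  }
  pr$fy <- factor(pr$y0)
  pr$fk <- factor(pr$k_perp)
  ssq <- function(p, dat) sum(resid_fun(p, dat)^2)

  if (is.null(start)) {
    grid <- expand.grid(mu = c(1, 10, 25, 50, 90, 150),
                        gamma = c(5, 12, 22, 40, 80))
    sc <- apply(grid, 1, function(g) ssq(c(g[1], g[2]), pr))
    start <- as.numeric(grid[which.min(sc), ])
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = resid_fun, dat = pr,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- fit$par
  if (fit$info %in% c(0, 5, 9)) {
    stop("scattering-parameter fit did not converge: ", fit$message)
  }
  # degeneracy tie-break: a transfer that is flat in k is explained equally by
  # mu = 0 (no scattering) and by gamma at its upper bound (pure forward
  # scattering at any mu); prefer the scatter-free reading when it fits as well
  if (abs(est[2] - upper[2]) < 1e-6) {
    s_est <- sum(resid_fun(est, pr)^2)
    s_null <- sum(resid_fun(c(0, est[2]), pr)^2)
    if (s_null <= s_est * 1.05) est[1] <- 0
  }
  at_bound <- any(abs(est - lower) < 1e-8) || any(abs(est - upper) < 1e-8)

  boot <- NULL
  if (n_boot > 0) {
    boot <- purrr::map_dfr(seq_len(n_boot), function(i) {
      ds <- sample(depths, replace = TRUE)
      dat <- purrr::map_dfr(seq_along(ds), function(j) {
        d <- pr[pr$y0 == ds[j], ]
        d$fy <- paste0(j)  # resampled planes stay distinct nuisance groups
        d
      })
      dat$fy <- factor(dat$fy)
      bf <- tryCatch(
        minpack.lm::nls.lm(par = est, lower = lower, upper = upper,
                           fn = resid_fun, dat = dat,
                           control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL
      )
      if (is.null(bf)) return(tibble::tibble())
      tibble::tibble(rep = i, mu_sca = bf$par[1], gamma = bf$par[2])
    })
  }

  structure(
    list(
      params = scattering_params(max(est[1], 0), est[2], sigma_coef),
      mu_sca = est[1], gamma = est[2],
      g_hg = anisotropy_factor(est[2]),
      residual_norm = sqrt(sum(fit$fvec^2)),
      n_obs = nrow(pr), depths = depths, mode = mode,
      k_band = c(k_min, k_max), at_bound = at_bound,
      objective = objective, scale_per_depth = scale_per_depth,
      scale_per_freq = scale_per_freq,
      info = fit$info, message = fit$message,
      boot = boot, data = pr,
      model_args = list(sigma_coef = sigma_coef, b = spectrum$b,
                        dy = spectrum$dy, ny = ny,
                        ref_depths = spectrum$ref_depths, profile = profile,
                        kz_transfer = kz_transfer)
    ),
    class = "scatter_fit"
  )
}

#' Fitted transfer values for the data underlying a scatter_fit
#' @param fit a `scatter_fit`.
#' @keywords internal
predict_scatter_fit <- function(fit, data = fit$data) {
  a <- fit$model_args
  model_spectrum(data$k_perp, data$y0, fit$mu_sca, fit$gamma, a$sigma_coef,
                 a$b, a$dy, a$ny, a$ref_depths, a$profile, a$kz_transfer)
}

#' @export
print.scatter_fit <- function(x, ...) {
  cat(sprintf(
    "<scatter_fit> (%s) mu_sca = %.3g /mm, gamma = %.3g (g_HG = %.3f)\n  %d observations over %d depths; residual norm %.3g%s\n",
    x$mode, x$mu_sca, x$gamma, x$g_hg, x$n_obs, length(x$depths),
    x$residual_norm, if (x$at_bound) " [estimate at bound]" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the scattering-parameter estimates
#'
#' @param x a `scatter_fit`.
#' @param conf.level bootstrap percentile interval level.
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `estimate`, and, when
#'   bootstrap replicates exist, `conf.low`/`conf.high`.
#' @method tidy scatter_fit
#' @export
tidy.scatter_fit <- function(x, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = c("mu_sca", "gamma"),
    estimate = c(x$mu_sca, x$gamma)
  )
  if (!is.null(x$boot) && nrow(x$boot) > 1) {
    a <- (1 - conf.level) / 2
    out$conf.low <- c(stats::quantile(x$boot$mu_sca, a, names = FALSE),
                      stats::quantile(x$boot$gamma, a, names = FALSE))
    out$conf.high <- c(stats::quantile(x$boot$mu_sca, 1 - a, names = FALSE),
                       stats::quantile(x$boot$gamma, 1 - a, names = FALSE))
  }
  out
}

#' One-line fit summary
#' @param x a `scatter_fit`.
#' @param ... unused.
#' @method glance scatter_fit
#' @export
glance.scatter_fit <- function(x, ...) {
  tibble::tibble(
    mu_sca = x$mu_sca, gamma = x$gamma, g_hg = x$g_hg,
    residual_norm = x$residual_norm, n_obs = x$n_obs,
    n_depths = length(x$depths), mode = x$mode,
    at_bound = x$at_bound, converged = !(x$info %in% c(0, 5, 9))
  )
}

#' Plot data and fitted transfer curves
#' @param object a `scatter_fit`.
#' @param max_curves number of depths to draw.
#' @param ... unused.
#' @method autoplot scatter_fit
#' @export
autoplot.scatter_fit <- function(object, max_curves = 6, ...) {
  dat <- object$data
  dat$fitted <- predict_scatter_fit(object)
  depths <- sort(unique(dat$y0))
  show <- depths[unique(round(seq(1, length(depths), length.out = max_curves)))]
  dat <- dplyr::filter(dat, .data$y0 %in% show)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k_perp,
                                    colour = factor(signif(.data$y0, 3)),
                                    group = .data$y0)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "k_perp (cycles/um)", y = "frequency transfer",
                  colour = "y0 (um)")
}
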