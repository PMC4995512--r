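# Depth-resolved spectral analysis: the noise-adapted contrast coefficient Q,
# per-direction 1/e spectral widths, and the reference-normalized depth
# spectra from which the scattering parameters are fitted.

plane_magnitude <- function(slice) {
  m <- Mod(fft2(slice))
  dc <- m[1, 1]
  if (dc <= 0) stop("plane has zero DC value; cannot normalize spectrum")
  m / dc
}

#' Raise a spectrum's white-noise floor to a target level
#'
#' Normalizes nothing away and never lowers the floor: a flat magnitude floor
#' `a` is mixed in (`sqrt(S^2 + a^2)`, the magnitude of adding independent
#' white noise in the image) until the mean magnitude over the pure-noise
#' band (radial normalized frequency beyond `k_noise_frac`) reaches the
#' target level `n_l` within 0.1%. Deterministic. If the spectrum is already
#' at or above `n_l` it is returned unchanged with a warning.
#'
#' @param spectrum 2-D magnitude spectrum, DC-normalized (value 1 at `[1,1]`),
#'   FFT layout.
#' @param n_l target noise level (mean magnitude in the noise band, relative
#'   to DC).
#' @param pitch pixel pitches `(dx, dz)`, micrometers.
#' @param k_noise_frac start of the pure-noise band as a fraction of the
#'   per-axis Nyquist frequency (default 0.9).
#' @return adapted magnitude spectrum.
#' @export
noise_adapt_spectrum <- function(spectrum, n_l, pitch, k_noise_frac = 0.9) {
  stopifnot(is.matrix(spectrum), n_l > 0)
  pitch <- rep(pitch, length.out = 2)
  n <- dim(spectrum)
  kx <- fft_freq(n[1], pitch[1]) * 2 * pitch[1]  # per-axis normalized (+-1)
  kz <- fft_freq(n[2], pitch[2]) * 2 * pitch[2]
  knorm <- sqrt(outer(kx^2, kz^2, `+`))
  band <- knorm > k_noise_frac
  if (!any(band)) stop("noise band empty; lower k_noise_frac")
  cur <- mean(spectrum[band])
  if (cur >= n_l) {
    warning("spectrum already at or above the target noise level; unchanged")
    return(spectrum)
  }
  f <- function(a) mean(sqrt(spectrum[band]^2 + a^2)) - n_l
  a <- stats::uniroot(f, c(0, n_l), tol = n_l * 1e-6)$root
  sqrt(spectrum^2 + a^2)
}

#' Contrast coefficient Q of one image plane
#'
#' Ratio of the mean noise-adapted spectral magnitude in the high-spatial-
#' frequency band (`k_c < k <= k_N`) to the mean in the low band
#' (`0 < k <= k_c`). The DC term is excluded from both bands; magnitude (not
#' power) spectra are used, and the high band extends to the Nyquist
#' frequency with no upper signal cut.
#'
#' @param slice image plane, matrix `[x, z]` (at least 32 x 32).
#' @param pitch pixel pitches `(dx, dz)`, micrometers.
#' @param k_c corner frequency separating the bands, cycles/um (the largest
#'   object structure: `1/d_cell`).
#' @param n_l target noise level for [noise_adapt_spectrum()]; `0` skips
#'   noise adaptation.
#' @param k_noise_frac see [noise_adapt_spectrum()].
#' @return Q, a nonnegative scalar.
#' @export
contrast_coefficient <- function(slice, pitch, k_c, n_l = 0.002,
                                 k_noise_frac = 0.9) {
  stopifnot(is.matrix(slice))
  if (any(dim(slice) < 32)) stop("plane must be at least 32 x 32")
  pitch <- rep(pitch, length.out = 2)
  k_n <- min(1 / (2 * pitch))
  if (!(k_c > 0 && k_c < k_n)) stop("require 0 < k_c < Nyquist frequency")
  s <- plane_magnitude(slice)
  if (n_l > 0) {
    s <- withCallingHandlers(
      noise_adapt_spectrum(s, n_l, pitch, k_noise_frac),
      warning = function(w) {
        if (grepl("noise level", conditionMessage(w))) invokeRestart("muffleWarning")
      }
    )
  }
  k <- k_radial_grid(dim(slice), pitch)
  lsf <- k > 0 & k <= k_c
  hsf <- k > k_c & k <= k_n
  if (!any(lsf) || !any(hsf)) {
    stop("empty frequency band; k_c unresolvable on this grid")
  }
  mean(s[hsf]) / mean(s[lsf])
}

#' Depth profile of the contrast coefficient
#'
#' Computes Q for every xz-plane of the stack.
#'
#' @param stack an [image_stack()].
#' @param d_cell largest object structure, micrometers; sets the corner
#'   frequency `k_c = 1/d_cell` unless `k_c` is given.
#' @param n_l target noise level (see [noise_adapt_spectrum()]).
#' @param k_c optional explicit corner frequency, cycles/um.
#' @param k_noise_frac see [noise_adapt_spectrum()].
#' @return tibble of class `contrast_profile` with columns `y0` (um) and `Q`;
#'   attributes `k_c`, `n_l`, `k_N`.
#' @export
contrast_profile <- function(stack, d_cell = 20, n_l = 0.002, k_c = NULL,
                             k_noise_frac = 0.9) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(k_c)) k_c <- 1 / d_cell
  pitch <- stack$pitch[c("x", "z")]
  y0 <- stack_depths(stack)
  q <- vapply(seq_along(y0), function(i) {
    contrast_coefficient(xz_slice(stack, i), pitch, k_c, n_l, k_noise_frac)
  }, numeric(1))
  out <- tibble::tibble(y0 = y0, Q = q)
  class(out) <- c("contrast_profile", class(out))
  attr(out, "k_c") <- k_c
  attr(out, "n_l") <- n_l
  attr(out, "k_N") <- min(1 / (2 * pitch))
  out
}

#' Contrast relative to a baseline imaging mode
#'
#' @param profile,baseline `contrast_profile` tibbles on the same depth grid.
#' @return tibble with `y0`, `Q`, `Q_baseline`, `Q_rel = Q / Q_baseline`.
#' @export
contrast_relative <- function(profile, baseline) {
  dplyr::inner_join(
    tibble::as_tibble(profile),
    dplyr::rename(tibble::as_tibble(baseline), Q_baseline = "Q"),
    by = "y0"
  ) |>
    dplyr::mutate(Q_rel = .data$Q / .data$Q_baseline)
}

#' Plot a contrast-depth profile
#' @param object a `contrast_profile`.
#' @param ... unused.
#' @method autoplot contrast_profile
#' @export
autoplot.contrast_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y0, y = .data$Q)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "detection depth y0 (um)", y = "contrast coefficient Q")
}

#' Per-direction 1/e spectral widths of each plane
#'
#' For every xz-plane and azimuthal direction bin in the (k_x, k_z) plane,
#' fits an exponential decay to the radial magnitude profile and reports its
#' 1/e frequency. The set of widths traces the anisotropy signature of
#' confocal detection (wider along k_x at depth).
#'
#' @param stack an [image_stack()].
#' @param n_theta number of azimuthal bins over `[0, pi)` (>= 16 recommended).
#' @param k_max_frac upper fit limit as a fraction of the smaller per-axis
#'   Nyquist frequency.
#' @param floor_snr the exponential is fitted only over the decaying region
#'   where the radial profile exceeds `floor_snr` times the plane's
#'   white-noise magnitude floor (estimated beyond 0.9 Nyquist); bins past
#'   the first crossing are dropped so the flat noise/plateau tail cannot
#'   dilute the slope.
#' @return tibble with `y0`, `theta` (bin center, radians; 0 = k_x axis),
#'   `width` (1/e frequency, cycles/um) and `saturated` (TRUE where the
#'   profile did not decay and the Nyquist frequency is reported).
#' @param debias subtract the plane's white-noise power floor from the ring
#'   means before fitting (recommended for shot-noise-limited stacks; turn
#'   off for noise-free synthetic spectra).
#' @export
spectral_width_map <- function(stack, n_theta = 16, k_max_frac = 0.9,
                               floor_snr = 3, debias = TRUE) {
  stopifnot(inherits(stack, "image_stack"), n_theta >= 2)
  pitch <- stack$pitch[c("x", "z")]
  n <- dim(stack$data)[c(1, 3)]
  k <- k_radial_grid(n, pitch)
  th <- k_azimuth_grid(n, pitch)
  k_n <- min(1 / (2 * pitch))
  kxn <- fft_freq(n[1], pitch[1]) * 2 * pitch[1]
  kzn <- fft_freq(n[2], pitch[2]) * 2 * pitch[2]
  noise_band <- sqrt(outer(kxn^2, kzn^2, `+`)) > 0.9
  keep <- k > 0 & k <= k_max_frac * k_n
  bin <- pmin(floor(th / (pi / n_theta)), n_theta - 1)[keep]
  kv <- k[keep]
  dk <- 1 / max(n * pitch)
  rbin <- round(kv / dk)
  y0 <- stack_depths(stack)
  res <- purrr::map_dfr(seq_along(y0), function(i) {
    m <- plane_magnitude(xz_slice(stack, i))
    fl2 <- if (debias) mean(m[noise_band]^2) else 0
    s2 <- m[keep]^2
    purrr::map_dfr(0:(n_theta - 1), function(b) {
      inb <- bin == b
      # radial power profile of this direction, floor-debiased at ring level
      p2 <- tapply(s2[inb], rbin[inb], mean)
      nr <- tapply(rep(1, sum(inb)), rbin[inb], sum)
      kk <- as.numeric(names(p2)) * dk
      o <- order(kk)
      p2 <- as.numeric(p2)[o] - fl2
      nr <- as.numeric(nr)[o]
      kk <- kk[o]
      # stop at the first ring indistinguishable from the floor
      cut <- which(p2 < floor_snr * fl2 / sqrt(nr) + 1e-300)[1]
      if (!is.na(cut)) { p2 <- p2[seq_len(cut - 1)]; kk <- kk[seq_len(cut - 1)] }
      width <- k_n
      sat <- TRUE
      if (length(kk) >= 4) {
        fit <- stats::lm.fit(cbind(1, kk), 0.5 * log(p2))
        slope <- fit$coefficients[2]
        if (is.finite(slope) && slope < 0) {
          width <- min(-1 / slope, k_n)
          sat <- -1 / slope > k_n
        }
      }
      tibble::tibble(y0 = y0[i], theta = (b + 0.5) * pi / n_theta,
                     width = width, saturated = sat)
    })
  })
  class(res) <- c("spectral_widths", class(res))
  res
}

#' Reference-normalized depth spectra
#'
#' The substrate of the blind scattering-parameter fit. Every xz-plane is
#' Fourier transformed, DC-normalized, smoothed over `2b + 1` neighboring
#' planes along y, and divided by a reference spectrum taken near the
#' detection objective where the object's influence is negligible. The
#' ratio is then averaged over azimuth into radial frequency bins ("radial"
#' direction) and over a narrow wedge around the k_z axis ("kz" direction,
#' one azimuthal bin on each side).
#'
#' @param stack an [image_stack()].
#' @param b smoothing half-width in planes (default 2).
#' @param n_ref number of planes nearest the objective averaged into the
#'   reference spectrum (default 3).
#' @param ref_planes optional explicit reference plane indices (overrides
#'   `n_ref`).
#' @param n_theta azimuthal bins used for the k_z wedge width.
#' @param debias subtract each plane's white-noise magnitude floor (estimated
#'   from the band beyond 0.9 Nyquist) in quadrature before forming ratios.
#'   Keeps deep-plane ratios centered on the true transfer instead of the
#'   noise ratio.
#' @param min_ref_intensity reference planes whose mean intensity falls below
#'   this fraction of the stack's brightest plane trigger an error.
#' @return object of class `depth_spectrum`: list with `profile` (tibble:
#'   `y0`, `k_perp`, `value`, `n_pix`, `direction`), the reference depths,
#'   smoothing width, pixel pitch and Nyquist frequency.
#' @export
normalized_depth_spectrum <- function(stack, b = 2, n_ref = 3,
                                      ref_planes = NULL, n_theta = 16,
                                      debias = TRUE,
                                      min_ref_intensity = 1e-3) {
  stopifnot(inherits(stack, "image_stack"), b >= 0, n_theta >= 2)
  d <- dim(stack$data)
  ny <- d[2]
  pitch <- stack$pitch[c("x", "z")]
  y0 <- stack_depths(stack)
  if (is.null(ref_planes)) ref_planes <- seq_len(min(n_ref, ny))
  plane_means <- vapply(seq_len(ny), function(i) mean(xz_slice(stack, i)),
                        numeric(1))
  if (any(plane_means[ref_planes] < min_ref_intensity * max(plane_means))) {
    stop("reference planes have inadequate signal")
  }
  n <- d[c(1, 3)]
  k_n <- min(1 / (2 * pitch))
  kx_norm <- fft_freq(n[1], pitch[1]) * 2 * pitch[1]
  kz_norm <- fft_freq(n[2], pitch[2]) * 2 * pitch[2]
  noise_band <- sqrt(outer(kx_norm^2, kz_norm^2, `+`)) > 0.9

  mags <- vector("list", ny)
  floors <- numeric(ny)
  for (i in seq_len(ny)) {
    m <- plane_magnitude(xz_slice(stack, i))
    floors[i] <- mean(m[noise_band])
    if (debias) {
      m <- sqrt(pmax(m^2 - floors[i]^2, 0))
      m[1, 1] <- 1
    }
    mags[[i]] <- m
  }
  ref <- Reduce(`+`, mags[ref_planes]) / length(ref_planes)
  if (all(ref == 0)) stop("reference spectrum is all zero")

  # radial and kz-wedge bin assignment (shared across planes)
  k <- k_radial_grid(n, pitch)
  th <- k_azimuth_grid(n, pitch)
  dk <- 1 / (max(n * pitch))          # bin width: finest frequency pixel
  kbin <- round(k / dk)
  keep <- k <= k_n & ref > 0
  wedge_half <- pi / n_theta           # kz axis +- one azimuthal bin
  in_kz <- pmin(abs(th - pi / 2), pi - abs(th - pi / 2)) <= wedge_half

  idx_all <- which(keep)
  idx_kz <- which(keep & in_kz)
  f_all <- factor(kbin[idx_all])
  f_kz <- factor(kbin[idx_kz])
  k_all <- as.numeric(levels(f_all)) * dk
  k_kz <- as.numeric(levels(f_kz)) * dk
  n_all <- as.integer(table(f_all))
  n_kz <- as.integer(table(f_kz))

  smooth_mag <- function(i) {
    lo <- max(1, i - b); hi <- min(ny, i + b)
    Reduce(`+`, mags[lo:hi]) / (hi - lo + 1)
  }

  profile <- purrr::map_dfr(seq_len(ny), function(i) {
    ratio <- smooth_mag(i) / ref
    ratio[!is.finite(ratio)] <- NA_real_
    va <- tapply(ratio[idx_all], f_all, mean, na.rm = TRUE)
    vk <- tapply(ratio[idx_kz], f_kz, mean, na.rm = TRUE)
    dplyr::bind_rows(
      tibble::tibble(y0 = y0[i], k_perp = k_all, value = as.numeric(va),
                     n_pix = n_all, direction = "radial"),
      tibble::tibble(y0 = y0[i], k_perp = k_kz, value = as.numeric(vk),
                     n_pix = n_kz, direction = "kz")
    )
  })
  profile <- dplyr::filter(profile, is.finite(.data$value))
  # reference ring profile and its noise floor: used downstream to confine
  # fits to frequencies where the reference carries real signal
  ref_floor <- mean(floors[ref_planes])
  ref_profile <- dplyr::bind_rows(
    tibble::tibble(k_perp = k_all,
                   ref_value = as.numeric(tapply(ref[idx_all], f_all, mean)),
                   direction = "radial"),
    tibble::tibble(k_perp = k_kz,
                   ref_value = as.numeric(tapply(ref[idx_kz], f_kz, mean)),
                   direction = "kz")
  )
  structure(
    list(profile = profile, b = b, ref_planes = ref_planes,
         ref_depths = y0[ref_planes], pitch = pitch, k_N = k_n,
         n_theta = n_theta, dy = stack$pitch[["y"]], debias = debias,
         ref_profile = ref_profile, ref_floor = ref_floor),
    class = "depth_spectrum"
  )
}

#' @export
print.depth_spectrum <- function(x, ...) {
  cat(sprintf(
    "<depth_spectrum> %d depths x %d radial bins (k_N = %.3g cycles/um)\n  smoothing half-width b = %d planes, reference depths: %s um\n",
    dplyr::n_distinct(x$profile$y0),
    dplyr::n_distinct(x$profile$k_perp[x$profile$direction == "radial"]),
    x$k_N, x$b, paste(signif(x$ref_depths, 3), collapse = ", ")
  ))
  invisible(x)
}

#' Plot normalized depth spectra
#' @param object a `depth_spectrum`.
#' @param direction `"radial"` or `"kz"`.
#' @param max_curves number of depths to draw.
#' @param ... unused.
#' @method autoplot depth_spectrum
#' @export
autoplot.depth_spectrum <- function(object, direction = "radial",
                                    max_curves = 8, ...) {
  pr <- dplyr::filter(object$profile, .data$direction == !!direction)
  depths <- sort(unique(pr$y0))
  show <- depths[unique(round(seq(1, length(depths), length.out = max_curves)))]
  ggplot2::ggplot(
    dplyr::filter(pr, .data$y0 %in% show),
    ggplot2::aes(x = .data$k_perp, y = .data$value,
                 colour = factor(signif(.data$y0, 3)),
                 group = .data$y0)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "k_perp (cycles/um)", y = "normalized frequency transfer",
                  colour = "y0 (um)")
}

#' Export a depth spectrum's profile as tab-separated text
#' @param spectrum a `depth_spectrum`.
#' @param path output file.
#' @export
write_depth_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "depth_spectrum"))
  utils::write.table(spectrum$profile, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
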