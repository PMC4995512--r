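# Depth-dependent Wiener deconvolution: the stack is deconvolved once per
# depth section with a system PSF matched to that section's detection depth,
# and the section results are blended with shifted Hann windows that form an
# exact partition of unity along y.

#' Plan for depth-dependent deconvolution
#'
#' @param y_extent depth extent of the stack (micrometers); section centers
#'   span `[0, y_extent]`.
#' @param n_sections number of depth sections (>= 2; default 12).
#' @param wiener_A signal-to-noise scale of the Wiener regularization
#'   (> 0; larger means stronger high-frequency amplification).
#' @return object of class `deconv_plan` with section centers `y0` and
#'   section spacing `dy_sec`.
#' @export
deconv_plan <- function(y_extent, n_sections = 12, wiener_A = 1e4) {
  stopifnot(y_extent > 0, n_sections >= 2)
  if (wiener_A <= 0) stop("`wiener_A` must be > 0")
  structure(
    list(n_sections = as.integer(n_sections),
         y0 = seq(0, y_extent, length.out = n_sections),
         dy_sec = y_extent / (n_sections - 1),
         y_extent = y_extent, wiener_A = wiener_A),
    class = "deconv_plan"
  )
}

#' @export
print.deconv_plan <- function(x, ...) {
  cat(sprintf(
    "<deconv_plan> %d sections of %.3g um over [0, %.3g] um, Wiener A = %g\n",
    x$n_sections, x$dy_sec, x$y_extent, x$wiener_A
  ))
  invisible(x)
}

#' Shifted-Hann blending weight of one section
#'
#' Raised-cosine window centered on section `i` with 50% overlap between
#' neighbors; the first and last windows extend flat beyond their centers so
#' the weights sum to exactly 1 at every depth.
#'
#' @param y depth(s), micrometers.
#' @param i section index (1-based).
#' @param plan a [deconv_plan()].
#' @return weights in `[0, 1]`.
#' @export
hann_weight <- function(y, i, plan) {
  stopifnot(inherits(plan, "deconv_plan"), i >= 1, i <= plan$n_sections)
  ci <- plan$y0[i]
  d <- plan$dy_sec
  w <- ifelse(abs(y - ci) < d, cos(pi * (y - ci) / (2 * d))^2, 0)
  if (i == 1) w[y <= ci] <- 1
  if (i == plan$n_sections) w[y >= ci] <- 1
  w
}

#' Wiener filter for one system PSF
#'
#' Frequency-domain gain `conj(H) SNR / (|H|^2 SNR + 1)` with the
#' frequency-dependent signal-to-noise ratio estimated linearly,
#' `SNR(k) = A max(0, 1 - |k|/k_N)` on the radially normalized frequency
#' (per-axis Nyquist frequencies as the scale). The gain is finite
#' everywhere and vanishes wherever the system transfer vanishes.
#'
#' @param h_sys system PSF as a 3-D array already embedded on the target
#'   grid with its center at the grid center, or a [psf_volume()] matching
#'   the grid.
#' @param dims target grid dimensions (taken from `h_sys` if missing).
#' @param pitch voxel pitch, micrometers (length 3).
#' @param wiener_A SNR scale (> 0).
#' @return object of class `wiener_filter` holding the complex gain array.
#' @export
build_wiener <- function(h_sys, pitch, wiener_A = 1e4, dims = NULL) {
  if (wiener_A <= 0) stop("`wiener_A` must be > 0")
  h <- if (inherits(h_sys, "psf_volume")) h_sys$data else h_sys
  stopifnot(is.array(h), length(dim(h)) == 3)
  if (is.null(dims)) dims <- dim(h)
  if (!identical(dim(h), as.integer(dims))) stop("h_sys does not match `dims`")
  h <- h / sum(h)                       # H(0) = 1
  H <- stats::fft(ifftshift(h))
  kn <- 1 / (2 * rep(pitch, length.out = 3))
  kx <- fft_freq(dims[1], pitch[1]) / kn[1]
  ky <- fft_freq(dims[2], pitch[2]) / kn[2]
  kz <- fft_freq(dims[3], pitch[3]) / kn[3]
  knorm <- sqrt(
    outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  ) / sqrt(3)                           # 1 at the Nyquist corner
  snr <- wiener_A * pmax(0, 1 - knorm)
  gain <- Conj(H) * snr / (Mod(H)^2 * snr + 1)
  structure(list(gain = gain, pitch = pitch, wiener_A = wiener_A),
            class = "wiener_filter")
}

apply_wiener_padded <- function(data, filt, pad) {
  d <- dim(data)
  stopifnot(identical(dim(filt$gain), as.integer(d + 2 * pad)))
  padded <- mirror_pad(data, pad)
  out <- Re(stats::fft(stats::fft(padded) * filt$gain, inverse = TRUE)) /
    length(padded)
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])]
}

# enlarge pads so every padded dimension factors into 2/3/5 (fast FFTs)
fft_friendly_pad <- function(d, pad) {
  vapply(seq_along(d), function(i) {
    t <- good_fft_length(d[i] + 2 * pad[i])
    while ((t - d[i]) %% 2 != 0) t <- good_fft_length(t + 1L)
    as.integer((t - d[i]) / 2)
  }, integer(1))
}

mirror_pad <- function(a, pad) {
  d <- dim(a)
  idx <- lapply(1:3, function(i) {
    if (pad[i] == 0) return(seq_len(d[i]))
    pre <- pmin(pmax(seq(pad[i], 1), 1), d[i])
    post <- pmin(pmax(seq(d[i], d[i] - pad[i] + 1), 1), d[i])
    c(pre, seq_len(d[i]), post)
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Build the system PSF for one section depth on a compact support grid and
# return it embedded (centered) in an array of dimensions `dims`.
section_psf_array <- function(y0, params, optics, dims, pitch,
                              psf_cache) {
  ker <- object_response(psf_cache$lat_n, pitch[c(1, 3)], y0, params)
  hs <- system_psf(psf_cache$h_ill, psf_cache$h_det, ker)
  embed_psf(hs$data, dims)
}

embed_psf <- function(h, dims) {
  d <- dim(h)
  if (any(d > dims)) {
    # crop symmetric margins if support exceeds the target grid
    start <- floor((d - pmin(d, dims)) / 2) + 1L
    h <- h[start[1]:(start[1] + min(d[1], dims[1]) - 1),
           start[2]:(start[2] + min(d[2], dims[2]) - 1),
           start[3]:(start[3] + min(d[3], dims[3]) - 1), drop = FALSE]
    d <- dim(h)
  }
  out <- array(0, dims)
  off <- floor(dims / 2) + 1L - (floor(d / 2) + 1L)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- h
  out
}

build_psf_cache <- function(optics, stack_dims, pitch, lat_support = NULL,
                            y_support = NULL) {
  if (is.null(y_support)) {
    y_support <- if (optics$beam_type == "bessel") 14 else 8
  }
  n_dy <- 2L * as.integer(round(y_support / pitch[2])) + 1L
  if (is.null(lat_support)) lat_support <- min(stack_dims[c(1, 3)], 129L)
  lat_n <- rep(as.integer(lat_support), 2)
  sb <- beam_intensity(optics, c(lat_n[1], n_dy, lat_n[2]),
                       c(pitch[1], pitch[2], pitch[3]))
  h_ill <- illumination_psf(sb, optics$d_slit)
  h_det <- detection_psf(optics, c(lat_n[1], n_dy, lat_n[2]), pitch)
  list(h_ill = h_ill, h_det = h_det, lat_n = lat_n, n_dy = n_dy,
       y_support = y_support)
}

#' Single-PSF Wiener deconvolution of a whole stack
#'
#' @param stack an [image_stack()].
#' @param h_sys the system PSF ([psf_volume()] on a compact support grid).
#' @param wiener_A SNR scale.
#' @return deconvolved [image_stack()] (negative values retained).
#' @export
wiener_deconvolve <- function(stack, h_sys, wiener_A = 1e4) {
  stopifnot(inherits(stack, "image_stack"))
  h <- if (inherits(h_sys, "psf_volume")) h_sys$data else h_sys
  d <- dim(stack$data)
  pad <- fft_friendly_pad(d, pmin(floor(dim(h) / 2), d))
  dims <- as.integer(d + 2 * pad)
  filt <- build_wiener(embed_psf(h, dims), stack$pitch, wiener_A, dims)
  out <- apply_wiener_padded(stack$data, filt, pad)
  image_stack(out, stack$pitch)
}

#' Depth-dependent Wiener deconvolution
#'
#' For each section of the plan, builds the effective system PSF at the
#' section's detection depth from the optics and scattering model,
#' Wiener-deconvolves the stack with it, and blends the section results with
#' shifted-Hann weights along y. Mirror padding by one PSF half-support
#' suppresses FFT wrap-around. Negative output values are retained (set
#' `clamp = TRUE` for display).
#'
#' @param stack an [image_stack()].
#' @param params [scattering_params()] (fitted or known).
#' @param optics [optics_config()].
#' @param plan [deconv_plan()]; its extent must match the stack's y-extent.
#' @param lat_support,y_support PSF support: lateral samples per axis and
#'   half-extent along y in micrometers (defaults scale with beam type).
#' @param neighborhood deconvolve each section only on its blending
#'   neighborhood (plus one window span) instead of the full stack; reduces
#'   cost for many sections at identical interior output.
#' @param clamp set negative output voxels to zero.
#' @return deconvolved [image_stack()].
#' @export
depth_dependent_deconvolve <- function(stack, params, optics, plan,
                                       lat_support = NULL, y_support = NULL,
                                       neighborhood = FALSE, clamp = FALSE) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(params, "scattering_params"),
            inherits(optics, "optics_config"),
            inherits(plan, "deconv_plan"))
  d <- dim(stack$data)
  y_extent <- (d[2] - 1) * stack$pitch[["y"]]
  if (abs(plan$y_extent - y_extent) > stack$pitch[["y"]]) {
    stop(sprintf("plan extent (%.3g um) does not match stack y-extent (%.3g um)",
                 plan$y_extent, y_extent))
  }
  pitch <- as.numeric(stack$pitch)
  cache <- build_psf_cache(optics, d, pitch, lat_support, y_support)
  y <- stack_depths(stack)
  out <- array(0, d)

  if (!neighborhood) {
    pad <- fft_friendly_pad(d, pmin(c(floor(cache$lat_n[1] / 2),
                                      floor(cache$n_dy / 2),
                                      floor(cache$lat_n[2] / 2)), d))
    dims <- as.integer(d + 2 * pad)
    padded <- mirror_pad(stack$data, pad)
    Fstack <- stats::fft(padded)
    for (i in seq_len(plan$n_sections)) {
      w <- hann_weight(y, i, plan)
      if (all(w == 0)) next
      h <- section_psf_array(plan$y0[i], params, optics, dims, pitch, cache)
      filt <- build_wiener(h, pitch, plan$wiener_A, dims)
      dec <- Re(stats::fft(Fstack * filt$gain, inverse = TRUE)) / length(padded)
      dec <- dec[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
                 pad[3] + seq_len(d[3])]
      out <- out + dec * rep(w, each = d[1])
    }
  } else {
    for (i in seq_len(plan$n_sections)) {
      w <- hann_weight(y, i, plan)
      sel <- which(w > 0)
      span <- as.integer(round(plan$dy_sec / stack$pitch[["y"]]))
      lo <- max(1L, min(sel) - span); hi <- min(d[2], max(sel) + span)
      sub <- image_stack(stack$data[, lo:hi, , drop = FALSE], stack$pitch)
      dsub <- dim(sub$data)
      pad <- fft_friendly_pad(dsub, pmin(c(floor(cache$lat_n[1] / 2),
                                           floor(cache$n_dy / 2),
                                           floor(cache$lat_n[2] / 2)), dsub))
      dims <- as.integer(dsub + 2 * pad)
      h <- section_psf_array(plan$y0[i], params, optics, dims, pitch, cache)
      filt <- build_wiener(h, pitch, plan$wiener_A, dims)
      dec <- apply_wiener_padded(sub$data, filt, pad)
      out[, sel, ] <- out[, sel, ] +
        dec[, sel - lo + 1L, , drop = FALSE] * rep(w[sel], each = d[1])
    }
  }
  if (clamp) out[out < 0] <- 0
  image_stack(out, stack$pitch)
}
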