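# Image stack container and TIFF I/O. Axis convention throughout the package:
# x = scan direction, y = detection depth (TIFF page axis), z = illumination
# propagation. Arrays are indexed [x, y, z]; voxel pitch is in micrometers.

#' Create a 3-D image stack
#'
#' @param data 3-D numeric array indexed `[x, y, z]` (x = scan, y = detection
#'   depth, z = illumination propagation).
#' @param pitch voxel pitch in micrometers, length 3 `(dx, dy, dz)`.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, pitch) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  pitch <- as.numeric(pitch)
  stopifnot(length(pitch) == 3, all(pitch > 0), all(is.finite(data)))
  structure(
    list(data = data, pitch = stats::setNames(pitch, c("x", "y", "z"))),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels (x,y,z), pitch %.4g x %.4g x %.4g um\n  extent %.3g x %.3g x %.3g um, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$pitch[1], x$pitch[2], x$pitch[3],
    d[1] * x$pitch[1], d[2] * x$pitch[2], d[3] * x$pitch[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Detection depths of the stack's planes
#'
#' Plane 1 sits nearest the detection objective (`y0 = 0`).
#' @param stack an [image_stack()].
#' @return numeric vector of depths in micrometers, one per xz-plane.
#' @export
stack_depths <- function(stack) {
  (seq_len(dim(stack$data)[2]) - 1) * stack$pitch[["y"]]
}

#' Extract one xz-plane
#' @param stack an [image_stack()].
#' @param i plane index along y (1 = nearest the detection objective).
#' @return matrix `[x, z]`.
#' @export
xz_slice <- function(stack, i) {
  stack$data[, i, , drop = TRUE]
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack as multi-page 32-bit float TIFF
#'
#' Pages run along the detection-depth axis y. Because TIFF floats are stored
#' in `[0, 1]`, intensities are mapped affinely to that range; the mapping and
#' the voxel pitch are recorded in a JSON sidecar (`<path>.json`) which
#' [read_stack()] uses to restore the original values.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(stack$data)
  hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack$data)[2]), function(i) {
    t((xz_slice(stack, i) - lo) / scale)  # page rows = z, cols = x
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(pitch = unname(stack$pitch), scale = scale, offset = lo,
         axes = "page=y, row=z, col=x"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Accepts 8/16/32-bit input; integer data are promoted losslessly to their
#' original count values. Voxel pitch is taken from the JSON sidecar written
#' by [write_stack()] or from the `pitch` override; with neither, reading
#' fails.
#'
#' @param path TIFF path.
#' @param pitch optional pitch override, micrometers `(dx, dy, dz)`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pitch = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(pitch)) {
    if (is.null(meta$pitch)) {
      stop("voxel pitch unavailable: no sidecar metadata and no `pitch` override")
    }
    pitch <- meta$pitch
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  d1 <- dim(pages[[1]])
  if (length(d1) != 2) stop("only single-channel grayscale stacks are supported")
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1)))) {
    stop("pages differ in size; refusing to assemble a stack")
  }
  arr <- array(0, c(d1[2], length(pages), d1[1]))  # [x, y, z]
  for (i in seq_along(pages)) {
    v <- pages[[i]]
    if (!is.null(bits) && bits %in% c(8L, 16L)) v <- v * (2^bits - 1)
    arr[, i, ] <- t(v)
  }
  if (!is.null(meta$scale) && (!is.null(bits) && bits == 32L)) {
    arr <- arr * meta$scale + meta$offset
  }
  image_stack(arr, pitch)
}
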