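#' Single-channel image plane with calibration
#'
#' Light container for one 2-D grayscale channel: a numeric matrix in
#' `[row, col]` orientation plus bit-depth semantics and the physical pixel
#' size. Integer planes (`bit_depth` 8 or 16) must hold intensities in
#' `[0, 2^bit_depth - 1]`; 32-bit float planes (`bit_depth = 32`) may hold
#' negative values, which arise after image subtraction.
#'
#' @param pixels numeric matrix of intensities, rows = image rows.
#' @param pixel_size physical calibration in micrometres per pixel (> 0).
#' @param bit_depth one of 8, 16 or 32 (32 means unbounded float).
#' @return An `ImagePlane` object.
#' @export
image_plane <- function(pixels, pixel_size = 0.31, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L, 32L))
    stop("`bit_depth` must be 8, 16 or 32", call. = FALSE)
  if (bit_depth < 32L) {
    rng <- range(pixels)
    if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
      stop(sprintf("intensities outside [0, %d] for bit_depth %d",
                   2^bit_depth - 1L, bit_depth), call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size, bit_depth = bit_depth),
    class = "ImagePlane"
  )
}

#' @export
print.ImagePlane <- function(x, ...) {
  cat(sprintf("<ImagePlane> %d x %d px, %s-bit, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels),
              if (x$bit_depth == 32L) "32-float" else x$bit_depth,
              x$pixel_size, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ImagePlane <- function(x) dim(x$pixels)

#' Binary mask with the shape contract of its source plane
#'
#' @param pixels logical matrix (foreground = `TRUE`).
#' @param pixel_size micrometres per pixel.
#' @return A `BinaryMask` object.
#' @export
binary_mask <- function(pixels, pixel_size = 0.31) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("<BinaryMask> %d x %d px, %.4g um/px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, sum(x$pixels)))
  invisible(x)
}

#' @export
dim.BinaryMask <- function(x) dim(x$pixels)

as_image_plane <- function(x) {
  if (inherits(x, "ImagePlane")) return(x)
  stop("expected an ImagePlane", call. = FALSE)
}

#' Read a single-plane grayscale TIFF as an ImagePlane
#'
#' Integer sample depths are read at native scale (an 8-bit file yields
#' intensities in 0..255, a 16-bit file 0..65535). Multi-plane or RGB files
#' are rejected: the pipelines operate on one channel per file.
#'
#' @param path path to the TIFF file.
#' @param pixel_size micrometres per pixel to attach (the format carries no
#'   trusted calibration).
#' @return An `ImagePlane`.
#' @export
read_image_plane <- function(path, pixel_size = 0.31) {
  if (!file.exists(path))
    stop(sprintf("unreadable file: %s", path), call. = FALSE)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE),
                  error = function(e)
                    stop(sprintf("unreadable file: %s (%s)", path,
                                 conditionMessage(e)), call. = FALSE))
  if (length(img) != 1L)
    stop(sprintf("expected single-plane TIFF, got %d planes: %s",
                 length(img), path), call. = FALSE)
  m <- img[[1]]
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] == 1L) m <- m[, , 1L]
    else stop(sprintf("expected single-plane grayscale, got %d channels: %s",
                      dim(m)[3], path), call. = FALSE)
  }
  # the declared sample depth, not the data range, decides 8- vs 16-bit
  # semantics (a dim 16-bit image must not be mistaken for 8-bit: the
  # droplet pipeline rescales 8-bit input)
  depth <- attr(img[[1]], "bits.per.sample")
  if (is.null(depth)) depth <- if (max(m) > 255) 16L else 8L
  depth <- as.integer(depth)
  if (!depth %in% c(8L, 16L)) depth <- 16L
  m <- matrix(as.numeric(m), nrow(m), ncol(m))   # strip metadata attributes
  image_plane(m, pixel_size = pixel_size, bit_depth = depth)
}

#' Write an ImagePlane or BinaryMask as a grayscale TIFF
#'
#' Integer planes are written at their native depth. Masks are written as
#' 8-bit images with foreground 255 and background 0.
#'
#' @param x an `ImagePlane` or `BinaryMask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_plane <- function(x, path) {
  if (inherits(x, "BinaryMask")) {
    m <- matrix(ifelse(x$pixels, 255, 0) / 255, nrow(x$pixels))
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
    return(invisible(path))
  }
  x <- as_image_plane(x)
  if (x$bit_depth == 32L) {
    tiff::writeTIFF(x$pixels, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    scale <- 2^x$bit_depth - 1
    tiff::writeTIFF(x$pixels / scale, path,
                    bits.per.sample = as.integer(x$bit_depth))
  }
  invisible(path)
}
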