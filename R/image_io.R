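#' Read an RGB raster image
#'
#' Loads a PNG, JPEG or TIFF file into the package's raster convention: a
#' numeric array of dimension height x width x 3 with intensities on
#' \code{[0, 255]} (8-bit scale). Grayscale images are replicated across the
#' three channels; an alpha channel, if present, is dropped. Pixel
#' coordinates used throughout the package are 0-based, with \code{x} the
#' column index and \code{y} the row index.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return A height x width x 3 numeric array with values in \code{[0, 255]}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else if (dim(a)[3] == 1L) {
    a <- array(rep(a[, , 1], 3L), dim = c(dim(a)[1:2], 3L))
  }
  # EBImage stores [x, y, c]; the package convention is [row, col, c]
  a <- aperm(a, c(2L, 1L, 3L)) * 255
  validate_image(a)
}

#' Write an RGB raster image
#'
#' Inverse of [read_image()]: clips to \code{[0, 255]}, rescales to
#' \code{[0, 1]} and writes in the format implied by the file extension
#' (png, jpg/jpeg, tif/tiff).
#'
#' @param image A height x width x 3 array on the \code{[0, 255]} scale.
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- validate_image(image)
  a <- pmin(pmax(image, 0), 255) / 255
  EBImage::writeImage(EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color"), path)
  invisible(path)
}

#' Validate the raster-image contract
#'
#' Checks (and where possible coerces to) the package's raster convention:
#' finite values in \code{[0, 255]}, three channels, at least one pixel.
#' A matrix input is replicated to three channels.
#'
#' @param image Matrix or 3-d array.
#' @return The validated height x width x 3 array.
#' @export
validate_image <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be a height x width x 3 array")
  if (d[1] < 1L || d[2] < 1L) stop("image must contain at least one pixel")
  if (any(!is.finite(image))) stop("image contains non-finite values")
  if (min(image) < -1e-9 || max(image) > 255 + 1e-9) {
    stop("image intensities must lie in [0, 255]")
  }
  image
}

#' Convert an RGB image to luminance
#'
#' Rec. 601 luma: 0.299 R + 0.587 G + 0.114 B. Feature extraction operates
#' on the luminance of the (optionally decorrelation-stretched) image.
#'
#' @param image height x width x 3 array.
#' @return height x width matrix on the same intensity scale.
#' @export
luminance <- function(image) {
  image <- validate_image(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Apply a per-channel illumination change
#'
#' Models an ambient-light shift (sunny vs. cloudy acquisition) as an affine
#' per-channel map \code{gain * I + offset}, clipped to \code{[0, 255]}.
#' Used by the robustness probes of the synthetic-fixture module.
#'
#' @param image height x width x 3 array.
#' @param gain Length-1 or length-3 multiplicative gain.
#' @param offset Length-1 or length-3 additive offset (intensity units).
#' @return The shifted image.
#' @export
apply_illumination <- function(image, gain = 1, offset = 0) {
  image <- validate_image(image)
  gain <- rep_len(gain, 3L)
  offset <- rep_len(offset, 3L)
  for (ch in 1:3) image[, , ch] <- image[, , ch] * gain[ch] + offset[ch]
  pmin(pmax(image, 0), 255)
}
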