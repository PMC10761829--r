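#' Load an 8-bit grayscale image
#'
#' Reads a PNG/JPEG/TIFF raster and returns an integer intensity matrix in
#' `[0, 255]` (rows = image rows, columns = image columns). RGB inputs are
#' converted to luminance with the ITU-R BT.601 weights (0.299, 0.587,
#' 0.114) before quantization to 8 bits.
#'
#' @param path Path to an image file.
#' @return Integer matrix of intensities in `[0, 255]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3L]
    if (nch >= 3L) {
      dat <- 0.299 * dat[, , 1L] + 0.587 * dat[, , 2L] + 0.114 * dat[, , 3L]
    } else {
      dat <- dat[, , 1L]
    }
  }
  if (length(dat) == 0L) stop("zero-sized image: ", path)
  # EBImage stores (x = column, y = row); transpose to row-major matrix.
  m <- t(dat)
  m <- pmin(pmax(m, 0), 1)
  out <- matrix(as.integer(floor(m * 255 + 0.5)), nrow(m), ncol(m))
  out
}

#' Linear-stretch contrast enhancement
#'
#' Maps the minimum intensity to 0 and the maximum to `2^bit_depth - 1`,
#' scaling linearly in between:
#' `I_c = round((I - I_min) / (I_max - I_min) * (2^k - 1))`
#' with round-half-up and clipping to the valid range. The mapping is
#' monotone, so tissue ordering (and hence grey/white ratios) is preserved.
#'
#' @param image Integer intensity matrix.
#' @param bit_depth Bits per pixel `k` (default 8).
#' @return Integer matrix spanning `[0, 2^k - 1]`. A constant input returns
#'   an all-zero image with a warning.
#' @export
linear_stretch <- function(image, bit_depth = 8L) {
  stopifnot(is.matrix(image), length(image) >= 1L)
  top <- 2^bit_depth - 1
  imin <- min(image)
  imax <- max(image)
  if (imax == imin) {
    warning("constant image: linear stretch returns all zeros")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  v <- (image - imin) / (imax - imin) * top
  v <- floor(v + 0.5)            # round half up
  v <- pmin(pmax(v, 0), top)
  matrix(as.integer(v), nrow(image), ncol(image))
}

#' Compute the brain mask of a contrast-enhanced slice
#'
#' Thresholds above the (pure black) background level, applies a binary
#' morphological closing, fills interior holes, and keeps the largest
#' connected component. Interior voids (ventricles, atrophic cavities) are
#' therefore *inside* the mask, which is what the shrinkage denominator
#' requires.
#'
#' @param image Integer intensity matrix (contrast enhanced).
#' @param threshold Background threshold; pixels strictly above it are
#'   foreground (default 0).
#' @param brush_size Side of the square closing structuring element
#'   (default 3).
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
compute_brain_mask <- function(image, threshold = 0L, brush_size = 3L) {
  stopifnot(is.matrix(image))
  fg <- image > threshold
  if (!any(fg)) stop("empty brain mask: image is entirely background")
  kern <- EBImage::makeBrush(brush_size, shape = "box")
  m <- EBImage::closing(fg * 1, kern)
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
    m <- (lab == keep) * 1
  }
  matrix(as.integer(m > 0), nrow(image), ncol(image))
}
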