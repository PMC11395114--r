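#' Median-filter denoising
#'
#' Replaces each pixel by the median of its odd square neighbourhood,
#' with image borders handled by symmetric reflection. This is the first
#' step of the standard well-image preprocessing chain; it suppresses
#' shot noise while preserving the worm's edges.
#'
#' @param image An 8-bit integer pixel matrix or a [well_image()].
#' @param kernel_size Odd integer window side, default 3.
#' @return The denoised image, same container and shape as the input.
#' @examples
#' img <- matrix(100L, 9, 9); img[5, 5] <- 255L
#' median_denoise(img)[5, 5]  # salt pixel removed
#' @export
median_denoise <- function(image, kernel_size = 3L) {
  stopifnot_odd_kernel(kernel_size)
  px <- pixels_of(image)
  storage.mode(px) <- "integer"
  rewrap(image, cpp_median_filter(px, as.integer(kernel_size)))
}

#' Histogram equalization
#'
#' Standard cumulative-histogram contrast enhancement for 8-bit images:
#' each grey level v is remapped to
#' `round((cdf(v) - cdf_min) / (n_pixels - cdf_min) * 255)`,
#' a monotone non-decreasing transform. A constant image maps to a
#' constant (zero).
#'
#' @param image An 8-bit integer pixel matrix or a [well_image()].
#' @return The equalized image, same container and shape.
#' @export
equalize_histogram <- function(image) {
  px <- pixels_of(image)
  if (min(px) < 0 || max(px) > 255) stop("equalize_histogram expects 8-bit input")
  n <- length(px)
  counts <- tabulate(as.vector(px) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  if (n == cdf_min) {
    # constant image: degenerate denominator, map to a constant
    lut <- rep(0L, 256L)
  } else {
    lut <- as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))
  }
  out <- matrix(lut[as.vector(px) + 1L], nrow(px), ncol(px))
  rewrap(image, out)
}

#' Convert an image to 8-bit grayscale
#'
#' Channel-averages multichannel input (3D array), then linearly rescales
#' intensities from `[min, max]` to `[0, 255]`. A constant image (min ==
#' max) maps to all zeros by convention.
#'
#' @param image A numeric matrix (any bit depth), a 3D array (H x W x C),
#'   or a [well_image()].
#' @return An 8-bit integer image, same container.
#' @export
to_8bit_grayscale <- function(image) {
  px <- pixels_of(image)
  if (length(px) == 0) stop("empty image")
  if (length(dim(px)) == 3L) {
    px <- apply(px, c(1, 2), mean)
  }
  px <- as.matrix(px)
  rng <- range(as.numeric(px))
  out <- if (rng[1] == rng[2]) {
    matrix(0L, nrow(px), ncol(px))
  } else {
    as_u8((px - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  rewrap(image, out, bit_depth = 8L)
}

#' Preprocess a well image
#'
#' The fixed preprocessing chain applied to every raw well image before
#' segmentation: median denoise, then histogram equalization, then 8-bit
#' grayscale conversion.
#'
#' @inheritParams median_denoise
#' @return The preprocessed 8-bit image.
#' @export
preprocess_image <- function(image, kernel_size = 3L) {
  to_8bit_grayscale(equalize_histogram(median_denoise(image, kernel_size)))
}
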