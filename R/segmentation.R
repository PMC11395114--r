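#' Inverted threshold binarization
#'
#' Isolates the (dark) worm from the (bright) well background by the
#' inverted threshold rule: output is 255 where `I(x, y) < t` and 0
#' otherwise, with a strict inequality. The default cutoff is the
#' mid-grey 128.
#'
#' @param image 8-bit integer pixel matrix or [well_image()].
#' @param t Threshold in `[0, 255]`, default 128.
#' @return A binary mask (0/255 integer matrix) of the same shape.
#' @export
threshold_binarize <- function(image, t = 128L) {
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]")
  px <- pixels_of(image)
  out <- matrix(ifelse(as.vector(px) < t, 255L, 0L), nrow(px), ncol(px))
  storage.mode(out) <- "integer"
  out
}

#' Binary dilation and erosion
#'
#' Set-theoretic binary morphology with an odd square structuring
#' element. Pixels outside the image are treated as background, so
#' erosion shrinks foreground touching the border.
#'
#' @param mask Binary mask (0/255 or 0/1 matrix).
#' @param kernel Odd side length of the square structuring element.
#' @return Binary 0/255 mask.
#' @export
binary_dilate <- function(mask, kernel = 3L) {
  stopifnot_odd_kernel(kernel)
  mask255(cpp_binary_dilate(mask01(mask), as.integer(kernel)))
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, kernel = 3L) {
  stopifnot_odd_kernel(kernel)
  mask255(cpp_binary_erode(mask01(mask), as.integer(kernel)))
}

#' Morphological cleaning of a binary mask
#'
#' Morphological closing (dilate then erode) followed by opening (erode
#' then dilate) with a square kernel, default 3x3. Closing bridges small
#' gaps in the worm body; opening removes isolated noise pixels.
#'
#' @inheritParams binary_dilate
#' @return Cleaned binary 0/255 mask.
#' @export
morphological_clean <- function(mask, kernel = 3L) {
  stopifnot_odd_kernel(kernel)
  m <- mask01(mask)  # rejects non-binary input
  k <- as.integer(kernel)
  closed <- cpp_binary_erode(cpp_binary_dilate(m, k), k)
  opened <- cpp_binary_dilate(cpp_binary_erode(closed, k), k)
  mask255(opened)
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected to the image border (e.g. holes left
#' by bright gut speckles after inverted thresholding) are flipped to
#' foreground.
#'
#' @inheritParams binary_dilate
#' @return Binary 0/255 mask with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- mask01(mask)
  bg <- 1L - m
  lab <- cpp_label_components(bg)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  hole <- bg == 1L & !(lab %in% border_labels)
  m[hole] <- 1L
  mask255(m)
}

#' Pixel-wise confusion counts between two binary masks
#'
#' Compares a predicted segmentation against ground truth pixel by pixel
#' (foreground = positive class) and returns the 2x2 confusion counts.
#'
#' @param predicted,truth Binary masks of identical shape.
#' @return A [confusion_counts()] object.
#' @export
pixel_confusion <- function(predicted, truth) {
  p <- mask01(predicted)
  g <- mask01(truth)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  confusion_counts(
    tp = sum(p == 1L & g == 1L),
    fp = sum(p == 1L & g == 0L),
    tn = sum(p == 0L & g == 0L),
    fn = sum(p == 0L & g == 1L)
  )
}
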