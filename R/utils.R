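# Internal helpers shared across modules.

# Clamp to [0,255], round half to even, return integer matrix.
as_u8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

# Accept a plain matrix or a well_image; return the pixel matrix.
pixels_of <- function(image) {
  if (inherits(image, "well_image")) image$pixels else image
}

# Rewrap pixels in the same container the caller supplied.
rewrap <- function(image, pixels, bit_depth = NULL) {
  if (inherits(image, "well_image")) {
    image$pixels <- pixels
    if (!is.null(bit_depth)) image$bit_depth <- bit_depth
    image
  } else {
    pixels
  }
}

# A mask is a 0/255 integer matrix; convert to 0/1 for morphology kernels.
mask01 <- function(mask) {
  m <- pixels_of(mask)
  v <- sort(unique(as.numeric(m)))
  if (!(all(v %in% c(0, 1)) || all(v %in% c(0, 255))))
    stop("mask must be binary (values 0/255 or 0/1)")
  matrix(as.integer(m > 0), nrow(m), ncol(m))
}

mask255 <- function(m01) {
  out <- m01 * 255L
  storage.mode(out) <- "integer"
  out
}

stopifnot_odd_kernel <- function(k) {
  if (length(k) != 1L || k < 3L || k %% 2L == 0L)
    stop("kernel size must be an odd integer >= 3")
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}
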