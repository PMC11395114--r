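#' Rotate coordinates
#'
#' The planar rotation `x' = x cos(theta) - y sin(theta)`,
#' `y' = x sin(theta) + y cos(theta)` used to align worm segments with
#' the global orientation. Length-preserving; vectorized over points.
#'
#' @param x,y Numeric coordinates.
#' @param theta Rotation angle in radians.
#' @return List with rotated `x` and `y`.
#' @export
rotate_coords <- function(x, y, theta) {
  list(x = x * cos(theta) - y * sin(theta),
       y = x * sin(theta) + y * cos(theta))
}

#' Extract perpendicular intensity profiles along the centerline
#'
#' For every centerline pixel, samples an intensity profile of length
#' `2 * half_width + 1` perpendicular to the body axis using bilinear
#' interpolation. In `"local"` mode (default) the perpendicular direction
#' comes from the local path tangent, which follows curved worms; in
#' `"global"` mode every segment is rotated by the single global
#' orientation angle, the behaviour implied by a whole-worm rotation and
#' kept for fidelity experiments (it degrades on strongly curved worms).
#'
#' Profiles that leave the image are padded with a background estimate
#' (median of the image border) and the result is flagged via the
#' `"clipped"` attribute.
#'
#' @param image 8-bit image matrix or [well_image()].
#' @param path Ordered centerline matrix (columns `x`, `y`, 0-based) from
#'   [order_skeleton_path()].
#' @param keypoints Optional keypoints for the global fit; defaults to
#'   [extract_keypoints()] of `path`.
#' @param half_width Half profile width in pixels (>= 1), default 15
#'   giving 31-pixel profiles ahead of the 30-pixel canonical strip.
#' @param mode `"local"` or `"global"` perpendicular direction.
#' @return Numeric matrix, one row per path pixel, one column per offset
#'   `-half_width..half_width`; attribute `"clipped"` reports padding.
#' @export
extract_segments <- function(image, path, keypoints = NULL, half_width = 15L,
                             mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (half_width < 1L) stop("half_width must be >= 1")
  px <- pixels_of(image)
  n <- nrow(path)
  xs <- as.numeric(path[, 1]); ys <- as.numeric(path[, 2])
  if (any(xs < 0 | xs > ncol(px) - 1 | ys < 0 | ys > nrow(px) - 1))
    stop("path must lie inside the image")
  if (mode == "global") {
    if (is.null(keypoints)) keypoints <- extract_keypoints(path)
    fit <- fit_global_orientation(keypoints)
    theta <- fit$theta
    nx <- rep(-sin(theta), n); ny <- rep(cos(theta), n)
  } else {
    # central differences over a +-3 px stencil smooth out single-pixel
    # kinks left by thinning
    k <- min(3L, n - 1L)
    ia <- pmax(seq_len(n) - k, 1L)
    ib <- pmin(seq_len(n) + k, n)
    tx <- xs[ib] - xs[ia]; ty <- ys[ib] - ys[ia]
    nrm <- sqrt(tx^2 + ty^2)
    nrm[nrm == 0] <- 1
    nx <- -ty / nrm; ny <- tx / nrm
  }
  offs <- seq(-half_width, half_width)
  # background estimate: median of border pixels
  border <- c(px[1, ], px[nrow(px), ], px[, 1], px[, ncol(px)])
  fill <- median(as.numeric(border))
  sx <- matrix(xs, n, length(offs)) + outer(nx, offs)
  sy <- matrix(ys, n, length(offs)) + outer(ny, offs)
  clipped <- any(sx < 0 | sx > ncol(px) - 1 | sy < 0 | sy > nrow(px) - 1)
  vals <- cpp_bilinear(matrix(as.numeric(px), nrow(px), ncol(px)),
                       as.numeric(sx), as.numeric(sy), fill)
  stack <- matrix(vals, n, length(offs))
  attr(stack, "clipped") <- clipped
  stack
}

#' Assemble the canonical straightened worm strip
#'
#' Stacks the perpendicular profiles into a rectangle (path position along
#' the long axis, profile offset along the short axis) and rescales it by
#' bilinear interpolation to the canonical shape, 600 (length) x 30
#' (width) by default, rounded back to 8-bit.
#'
#' @param stack Segment stack from [extract_segments()].
#' @param out_shape Output `(length, width)` in pixels, default
#'   `c(600, 30)`.
#' @param worm_id,age_days,source_day Optional metadata carried on the
#'   result.
#' @return A `straightened_worm`: list with integer `pixels` matrix of
#'   dim `out_shape` plus metadata fields.
#' @export
reconstruct_straightened <- function(stack, out_shape = c(600L, 30L),
                                     worm_id = NA_character_,
                                     age_days = NA_real_,
                                     source_day = NA_integer_) {
  if (is.null(dim(stack)) || nrow(stack) == 0L) stop("empty segment stack")
  out <- cpp_resize_bilinear(stack, as.integer(out_shape[1]),
                             as.integer(out_shape[2]))
  structure(list(pixels = as_u8(out), worm_id = worm_id,
                 age_days = age_days, source_day = source_day),
            class = "straightened_worm")
}

#' @export
print.straightened_worm <- function(x, ...) {
  cat(sprintf("straightened worm [%d x %d]", nrow(x$pixels), ncol(x$pixels)))
  if (!is.na(x$worm_id)) cat(sprintf("  id=%s", x$worm_id))
  if (!is.na(x$age_days)) cat(sprintf("  age=%.1f d", x$age_days))
  cat("\n")
  invisible(x)
}

#' Straighten a worm image given its mask
#'
#' Convenience wrapper running skeletonization, path ordering, keypoint
#' extraction and segment resampling to produce the canonical strip.
#'
#' @inheritParams extract_segments
#' @param mask Binary worm mask for `image`.
#' @param interval Keypoint spacing, see [extract_keypoints()].
#' @param prune Spur-pruning length, see [order_skeleton_path()].
#' @param out_shape Canonical output shape, see
#'   [reconstruct_straightened()].
#' @param worm_id,age_days,source_day Metadata carried to the result.
#' @return A `straightened_worm`.
#' @export
straighten_worm <- function(image, mask, half_width = 15L,
                            mode = c("local", "global"), interval = 10L,
                            prune = 5L, out_shape = c(600L, 30L),
                            worm_id = NA_character_, age_days = NA_real_,
                            source_day = NA_integer_) {
  skel <- skeletonize_mask(mask)
  path <- order_skeleton_path(skel, prune = prune)
  kp <- extract_keypoints(path, interval = interval)
  stack <- extract_segments(image, path, keypoints = kp,
                            half_width = half_width, mode = mode)
  reconstruct_straightened(stack, out_shape = out_shape, worm_id = worm_id,
                           age_days = age_days, source_day = source_day)
}
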