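#' Skeletonize a binary worm mask
#'
#' Thins the foreground to a one-pixel-wide medial representation
#' (Zhang-Suen two-subiteration thinning). If the mask has several
#' 8-connected components, only the largest is kept (with a warning);
#' an empty mask is rejected.
#'
#' @param mask Binary 0/255 (or 0/1) matrix with the worm as foreground.
#' @return Binary 0/255 matrix containing the skeleton pixels.
#' @export
skeletonize_mask <- function(mask) {
  m <- mask01(mask)
  if (sum(m) == 0L) stop("cannot skeletonize an empty mask")
  lab <- cpp_label_components(m)
  nlab <- max(lab)
  if (nlab > 1L) {
    warning(sprintf("mask has %d components; keeping the largest", nlab))
    sizes <- tabulate(lab[lab > 0L], nbins = nlab)
    m <- matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
  }
  mask255(cpp_thin(m))
}

# 8-neighbour count of every foreground pixel (matrix of counts).
neighbor_counts <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- m
  cnt <- matrix(0L, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    cnt <- cnt + p[(2:(H + 1L)) + di, (2:(W + 1L)) + dj]
  }
  cnt
}

# All foreground 8-neighbours of (i, j) as a 2-column matrix of (i, j).
nbrs_of <- function(m, i, j) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, 0L, 2L)
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0L && dj == 0L) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1L && ii <= H && jj >= 1L && jj <= W && m[ii, jj] == 1L)
      out <- rbind(out, c(ii, jj))
  }
  out
}

#' Order skeleton pixels into an endpoint-to-endpoint path
#'
#' Identifies endpoints (skeleton pixels with exactly one 8-neighbour),
#' prunes side branches shorter than `prune` pixels, and traverses the
#' remaining curve from one endpoint to the other. The start endpoint is
#' canonical: smallest x, ties broken by smallest y, so the ordering is
#' deterministic.
#'
#' @param skeleton Binary matrix from [skeletonize_mask()].
#' @param prune Branches shorter than this many pixels are removed
#'   before traversal (default 5).
#' @return Integer matrix with columns `x`, `y` (0-based, x = column,
#'   y = row), one row per skeleton pixel in path order.
#' @export
order_skeleton_path <- function(skeleton, prune = 5L) {
  m <- mask01(skeleton)
  npix <- sum(m)
  if (npix == 0L) stop("empty skeleton")
  if (npix == 1L) {
    ij <- which(m == 1L, arr.ind = TRUE)
    return(cbind(x = ij[1, 2] - 1L, y = ij[1, 1] - 1L))
  }
  # prune short spurs: while there are more than two endpoints, remove
  # the shortest endpoint-to-junction branch, provided it is shorter than
  # `prune`. Removing only the shortest branch per pass protects genuine
  # worm arms that happen to end near a junction.
  repeat {
    cnt <- neighbor_counts(m)
    ends <- which(m == 1L & cnt == 1L, arr.ind = TRUE)
    if (nrow(ends) <= 2L) break
    best_trail <- NULL
    best_len <- Inf
    for (e in seq_len(nrow(ends))) {
      i <- ends[e, 1]; j <- ends[e, 2]
      trail <- list(c(i, j))
      previ <- NA_integer_; prevj <- NA_integer_
      hit_junction <- FALSE
      while (length(trail) <= prune) {
        nb <- nbrs_of(m, i, j)
        if (!is.na(previ))
          nb <- nb[!(nb[, 1] == previ & nb[, 2] == prevj), , drop = FALSE]
        if (nrow(nb) == 0L) break
        if (nrow(nb) > 1L || cnt[nb[1, 1], nb[1, 2]] >= 3L) {
          hit_junction <- TRUE
          break
        }
        previ <- i; prevj <- j
        i <- nb[1, 1]; j <- nb[1, 2]
        trail[[length(trail) + 1L]] <- c(i, j)
      }
      if (hit_junction && length(trail) < prune &&
          length(trail) < best_len) {
        best_trail <- trail
        best_len <- length(trail)
      }
    }
    if (is.null(best_trail)) break
    for (t in best_trail) m[t[1], t[2]] <- 0L
  }
  cnt <- neighbor_counts(m)
  ends <- which(m == 1L & cnt == 1L, arr.ind = TRUE)
  if (nrow(ends) == 0L)
    stop("skeleton has no endpoints (closed loop); cannot order the path")
  if (nrow(ends) != 2L)
    stop(sprintf(paste("skeleton has %d endpoints after pruning;",
                       "increase `prune` to remove side branches"),
         nrow(ends)))
  # canonical start: smaller x (column), ties by smaller y (row)
  ord <- order(ends[, 2], ends[, 1])
  start <- ends[ord[1], ]
  goal <- ends[ord[2], ]
  visited <- matrix(FALSE, nrow(m), ncol(m))
  path <- matrix(0L, sum(m), 2L)
  i <- start[1]; j <- start[2]
  previ <- i; prevj <- j
  k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    visited[i, j] <- TRUE
    nb <- nbrs_of(m, i, j)
    nb <- nb[!visited[cbind(nb[, 1], nb[, 2])], , drop = FALSE]
    if (nrow(nb) == 0L) break
    if (nrow(nb) > 1L) {
      # prefer 4-connected steps over diagonal shortcuts; among those,
      # keep going in the incoming direction (skips 1-px bumps)
      d <- abs(nb[, 1] - i) + abs(nb[, 2] - j)
      dirdot <- (nb[, 1] - i) * (i - previ) + (nb[, 2] - j) * (j - prevj)
      nb <- nb[order(d, -dirdot), , drop = FALSE]
    }
    previ <- i; prevj <- j
    i <- nb[1, 1]; j <- nb[1, 2]
  }
  path <- path[seq_len(k), , drop = FALSE]
  if (!(path[k, 1] == goal[1] && path[k, 2] == goal[2]))
    warning("path traversal did not terminate at the opposite endpoint")
  cbind(x = path[, 2] - 1L, y = path[, 1] - 1L)
}

#' Select key points along a skeleton path
#'
#' Takes every `interval`-th pixel of the ordered centerline, always
#' including both endpoints.
#'
#' @param path Ordered path matrix from [order_skeleton_path()].
#' @param interval Spacing in path pixels (>= 1), default 10.
#' @return Subset of `path` rows, in order.
#' @export
extract_keypoints <- function(path, interval = 10L) {
  if (interval < 1L) stop("interval must be >= 1")
  n <- nrow(path)
  idx <- unique(c(seq(1L, n, by = as.integer(interval)), n))
  path[idx, , drop = FALSE]
}

#' Fit the worm's global orientation
#'
#' Ordinary least-squares fit of y on x through the key points, giving
#' slope `m`, intercept `b` and the global angle `theta = atan(m)` in
#' `(-pi/2, pi/2)`. A vertical worm (all x equal) cannot be regressed on
#' x; it is returned with `theta = pi/2`, `b = NA` and `vertical = TRUE`.
#' The RMS residual of the fit is reported so callers can flag strongly
#' bent (e.g. U-shaped) worms for which a single line is a poor summary.
#'
#' @param keypoints Matrix with columns `x`, `y` (at least 2 distinct
#'   points).
#' @return List with `m`, `b`, `theta` (radians), `vertical`, `rms`.
#' @export
fit_global_orientation <- function(keypoints) {
  x <- as.numeric(keypoints[, 1]); y <- as.numeric(keypoints[, 2])
  if (nrow(unique(cbind(x, y))) < 2L)
    stop("need at least 2 distinct keypoints")
  if (max(x) == min(x)) {
    return(list(m = Inf, b = NA_real_, theta = pi / 2, vertical = TRUE,
                rms = 0))
  }
  xb <- mean(x); yb <- mean(y)
  m <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  b <- yb - m * xb
  res <- y - (m * x + b)
  list(m = m, b = b, theta = atan(m), vertical = FALSE,
       rms = sqrt(mean(res^2)))
}
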