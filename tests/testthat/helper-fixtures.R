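# Shared fixtures: small worms that fit desk-scale canvases, and
# brute-force oracles used across geometry tests.

# Aging law scaled down so worms fit a 64x64 canvas.
small_law <- function(...) {
  aging_law(length0 = 40, length_sd = 3, curvature0 = 6, curvature_min = 1,
            ...)
}

make_small_sample <- function(age, seed, canvas = c(64L, 64L),
                              orientation = 0) {
  law <- if (min(canvas) < 64) {
    aging_law(w0 = 4, k = 0.25, length0 = 14, length_sd = 0.5,
              curvature0 = 2, curvature_min = 1)
  } else {
    small_law()
  }
  ph <- sample_phenotype(age, law, seed = seed)
  render_worm(ph, canvas, seed = seed + 1000L, orientation = orientation)
}

# Brute-force set-theoretic morphology on 0/1 matrices (outside = 0).
bf_dilate <- function(m, k = 3L) {
  h <- k %/% 2L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- max(1, i - h):min(nrow(m), i + h)
    jj <- max(1, j - h):min(ncol(m), j + h)
    out[i, j] <- as.integer(any(m[ii, jj] == 1L))
  }
  out
}

bf_erode <- function(m, k = 3L) {
  h <- k %/% 2L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- (i - h):(i + h); jj <- (j - h):(j + h)
    inside <- all(ii >= 1 & ii <= nrow(m)) && all(jj >= 1 & jj <= ncol(m))
    out[i, j] <- as.integer(inside && all(m[ii, jj] == 1L))
  }
  out
}

# Direct per-pixel median with reflected borders (oracle for the filter).
bf_median <- function(img, k = 3L) {
  h <- k %/% 2L
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n - i + 1
    }
    i
  }
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    vals <- numeric(0)
    for (di in -h:h) for (dj in -h:h)
      vals <- c(vals, img[refl(i + di, nrow(img)), refl(j + dj, ncol(img))])
    out[i, j] <- median(vals)
  }
  out
}

# Rotate a matrix by 90 degrees counterclockwise (image convention).
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Random thin 8-connected path on an n x n grid: a self-avoiding walk in
# which no two non-consecutive pixels touch, so the path is its own
# skeleton. Returns a 2-col (x, y) 0-based matrix or NULL on dead end.
random_thin_path <- function(n, len, seed) {
  set.seed(seed)
  occ <- matrix(FALSE, n, n)
  i <- sample(2:(n - 1), 1); j <- sample(2:(n - 1), 1)
  path <- matrix(c(i, j), 1, 2)
  occ[i, j] <- TRUE
  dirs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (s in seq_len(len - 1L)) {
    cand <- dirs[sample.int(8), , drop = FALSE]
    moved <- FALSE
    for (d in seq_len(8)) {
      ii <- i + cand[d, 1]; jj <- j + cand[d, 2]
      if (ii < 1 || ii > n || jj < 1 || jj > n || occ[ii, jj]) next
      # thinness: new pixel may touch only the current path end
      nb <- 0L
      for (di in -1:1) for (dj in -1:1) {
        ai <- ii + di; aj <- jj + dj
        if (ai >= 1 && ai <= n && aj >= 1 && aj <= n && occ[ai, aj])
          nb <- nb + 1L
      }
      if (nb == 1L) {
        i <- ii; j <- jj
        occ[i, j] <- TRUE
        path <- rbind(path, c(i, j))
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  if (nrow(path) < 3L) return(NULL)
  cbind(x = as.integer(path[, 2] - 1), y = as.integer(path[, 1] - 1))
}

path_to_mask <- function(path, n) {
  m <- matrix(0L, n, n)
  m[cbind(path[, "y"] + 1L, path[, "x"] + 1L)] <- 1L
  m * 255L
}
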