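# Numeric oracles for the network primitives: forward passes are checked
# against direct loop implementations, backward passes against central
# finite differences.

# direct same-padding 2D convolution, summing over input channels
bf_conv <- function(x, dims, W, b, k = 3L) {
  H <- dims[1]; W_ <- dims[2]; B <- dims[3]
  cin <- ncol(x); cout <- length(b)
  pad <- (k - 1) %/% 2
  out <- matrix(0, nrow(x), cout)
  for (bb in 0:(B - 1)) for (w in 0:(W_ - 1)) for (h in 0:(H - 1)) {
    r <- h + H * (w + W_ * bb) + 1
    for (co in seq_len(cout)) {
      acc <- b[co]
      for (ci in seq_len(cin)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
        hs <- h + di - pad; ws <- w + dj - pad
        if (hs >= 0 && hs < H && ws >= 0 && ws < W_) {
          wrow <- di + k * (dj + k * (ci - 1)) + 1
          acc <- acc + x[hs + H * (ws + W_ * bb) + 1, ci] * W[wrow, co]
        }
      }
      out[r, co] <- acc
    }
  }
  out
}

fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("im2col convolution equals the direct convolution oracle", {
  set.seed(1)
  dims <- c(5L, 4L, 2L)
  x <- matrix(rnorm(prod(dims) * 2), prod(dims), 2)  # 2 input channels
  lay <- wormaging:::conv_init(2L, 3L)
  got <- wormaging:::conv_fwd(x, dims, lay)$out
  want <- bf_conv(x, dims, lay$W, lay$b)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("convolution gradients match finite differences", {
  set.seed(2)
  dims <- c(4L, 3L, 1L)
  x <- matrix(rnorm(prod(dims) * 2), prod(dims), 2)
  lay <- wormaging:::conv_init(2L, 2L)
  dout <- matrix(rnorm(prod(dims) * 2), prod(dims), 2)
  fw <- wormaging:::conv_fwd(x, dims, lay)
  bw <- wormaging:::conv_bwd(dout, fw$cache, lay)
  # loss = <dout, conv(x)>
  expect_equal(bw$dx,
               fd_grad(function(xx) sum(dout * wormaging:::conv_fwd(
                 matrix(xx, nrow(x)), dims, lay)$out), x),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.numeric(bw$dW),
               as.numeric(fd_grad(function(ww) {
                 l2 <- lay; l2$W <- matrix(ww, nrow(lay$W))
                 sum(dout * wormaging:::conv_fwd(x, dims, l2)$out)
               }, lay$W)), tolerance = 1e-6)
})

test_that("batch normalization gradients match finite differences", {
  set.seed(3)
  x <- matrix(rnorm(24), 8, 3)
  lay <- list(gamma = runif(3, 0.5, 1.5), beta = rnorm(3))
  run <- wormaging:::bn_run_init(3L)
  dout <- matrix(rnorm(24), 8, 3)
  fw <- wormaging:::bn_fwd(x, lay, run, training = TRUE)
  bw <- wormaging:::bn_bwd(dout, fw$cache)
  f <- function(xx) sum(dout * wormaging:::bn_fwd(matrix(xx, 8), lay, run,
                                                  training = TRUE)$out)
  expect_equal(bw$dx, fd_grad(f, x), tolerance = 1e-5, ignore_attr = TRUE)
  fg <- function(gg) {
    l2 <- lay; l2$gamma <- gg
    sum(dout * wormaging:::bn_fwd(x, l2, run, training = TRUE)$out)
  }
  expect_equal(bw$dgamma, fd_grad(fg, lay$gamma), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("dense layer is a plain affine map with exact adjoints", {
  set.seed(4)
  X <- matrix(rnorm(12), 3, 4)
  lay <- wormaging:::dense_init(4L, 2L)
  fw <- wormaging:::dense_fwd(X, lay)
  expect_equal(fw$out, X %*% lay$W + rep(1, 3) %o% lay$b, tolerance = 1e-12)
  dout <- matrix(rnorm(6), 3, 2)
  bw <- wormaging:::dense_bwd(dout, fw$cache, lay)
  expect_equal(bw$dW, t(X) %*% dout, tolerance = 1e-12)
  expect_equal(bw$dx, dout %*% t(lay$W), tolerance = 1e-12)
})

test_that("pooling and upsampling are exact and mutually adjoint", {
  set.seed(5)
  dims <- c(4L, 4L, 2L)
  x <- matrix(rnorm(32), 32, 1)
  mp <- wormaging:::maxpool_fwd(x, dims)
  # forward oracle: block maxima
  for (b in 0:1) for (w2 in 0:1) for (h2 in 0:1) {
    rows <- as.vector(outer(2 * h2 + 0:1, 4 * (2 * w2 + 0:1) + 16 * b, "+")) + 1
    r2 <- h2 + 2 * (w2 + 2 * b) + 1
    expect_equal(mp$out[r2, 1], max(x[rows, 1]))
  }
  up <- wormaging:::upsample_fwd(x, dims)
  # every input value appears exactly 4 times
  expect_equal(sort(up$out[, 1]), sort(rep(x[, 1], each = 4)))
  # adjoint identity <u, Up(x)> == <Up^T(u), x>
  u <- matrix(rnorm(128), 128, 1)
  lhs <- sum(u * up$out)
  rhs <- sum(wormaging:::upsample_bwd(u, up$dims) * x)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # maxpool backward routes gradient to the argmax
  dpool <- matrix(rnorm(8), 8, 1)
  dx <- wormaging:::maxpool_bwd(dpool, mp$cache)
  expect_equal(sum(dx != 0), 8)
  expect_equal(sum(dx), sum(dpool))
})

test_that("activations follow their definitions", {
  expect_equal(relu(c(-3, 0, 2.5)), c(0, 0, 2.5))
  expect_equal(sigmoid(0), 0.5)
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)), tolerance = 1e-12)
  # overflow-safe far outside double exp range
  expect_equal(sigmoid(c(-800, 800)), c(0, 1))
})

test_that("global average pooling averages each feature map", {
  set.seed(6)
  dims <- c(4L, 4L, 3L)
  x <- matrix(rnorm(48 * 2), 48, 2)
  g <- wormaging:::gap_fwd(x, dims)
  want <- rbind(colMeans(x[1:16, ]), colMeans(x[17:32, ]),
                colMeans(x[33:48, ]))
  expect_equal(g$out, want, ignore_attr = TRUE)
  # constant map c pools to c; linearity
  xc <- matrix(3.25, 32, 2)
  expect_true(all(wormaging:::gap_fwd(xc, c(4L, 4L, 2L))$out == 3.25))
  g2 <- wormaging:::gap_fwd(2 * x, dims)$out
  expect_equal(g2, 2 * g$out)
})
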