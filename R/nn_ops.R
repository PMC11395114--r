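# Minimal CPU neural-network toolkit used by the U-Net and WormCNN.
#
# Activation tensors are N x C matrices with N = H*W*B and row index
# r = h + H*(w + W*b); the spatial dims travel alongside as c(H, W, B).
# Convolution is im2col + BLAS matmul; backward passes are the exact
# adjoints, so gradients are checked against finite differences in the
# test suite.

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`, the activation used throughout the
#' segmentation and age-prediction networks.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries zeroed.
#' @export
relu <- function(x) pmax(x, 0)

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, evaluated overflow-safely for large `|x|`.
#' Used as the pixel-probability output of the U-Net and the
#' elderly-probability output of the WormCNN classification head.
#'
#' @param x Numeric vector, matrix or array.
#' @return Values in `(0, 1)`, same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- stats::plogis(x)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# ---- layer initializers (draw from the current RNG stream) ----

conv_init <- function(cin, cout, k = 3L) {
  list(W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout))
}

bn_init <- function(ch) list(gamma = rep(1, ch), beta = rep(0, ch))

bn_run_init <- function(ch) list(mean = rep(0, ch), var = rep(1, ch))

dense_init <- function(fin, fout) {
  list(W = matrix(rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout),
       b = numeric(fout))
}

# ---- forward / backward primitives ----

conv_fwd <- function(X, dims, lay, k = 3L) {
  pad <- (k - 1L) %/% 2L
  cols <- cpp_im2col(X, dims[1], dims[2], dims[3], k, pad)
  out <- cols %*% lay$W
  out <- sweep(out, 2L, lay$b, "+")
  list(out = out, cache = list(cols = cols, dims = dims, k = k, pad = pad,
                               cin = ncol(X)))
}

conv_bwd <- function(dout, cache, lay) {
  dcols <- dout %*% t(lay$W)
  list(dx = cpp_col2im(dcols, cache$dims[1], cache$dims[2], cache$dims[3],
                       cache$k, cache$pad, cache$cin),
       dW = crossprod(cache$cols, dout),
       db = colSums(dout))
}

bn_fwd <- function(X, lay, run, training, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training && n > 1) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu, "-")
    va <- colMeans(xc * xc)
    istd <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2L, istd, "*")
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * va * n / max(n - 1, 1)
  } else {
    istd <- 1 / sqrt(run$var + eps)
    xhat <- sweep(sweep(X, 2L, run$mean, "-"), 2L, istd, "*")
  }
  out <- sweep(sweep(xhat, 2L, lay$gamma, "*"), 2L, lay$beta, "+")
  list(out = out, cache = list(xhat = xhat, istd = istd, gamma = lay$gamma),
       run = run)
}

bn_bwd <- function(dout, cache) {
  n <- nrow(dout)
  dbeta <- colSums(dout)
  dgamma <- colSums(dout * cache$xhat)
  gi <- cache$gamma * cache$istd
  dx <- sweep(dout, 2L, dbeta / n, "-") -
    sweep(cache$xhat, 2L, dgamma / n, "*")
  dx <- sweep(dx, 2L, gi, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_bwd <- function(dout, mask) dout * mask

maxpool_fwd <- function(X, dims) {
  r <- cpp_maxpool2(X, dims[1], dims[2], dims[3])
  list(out = r$out, cache = list(idx = r$idx, n = nrow(X)),
       dims = c(dims[1] %/% 2L, dims[2] %/% 2L, dims[3]))
}

maxpool_bwd <- function(dout, cache) cpp_maxpool2_backward(dout, cache$idx, cache$n)

upsample_fwd <- function(X, dims) {
  list(out = cpp_upsample2(X, dims[1], dims[2], dims[3]),
       dims = c(2L * dims[1], 2L * dims[2], dims[3]))
}

upsample_bwd <- function(dout, out_dims) {
  cpp_upsample2_backward(dout, out_dims[1], out_dims[2], out_dims[3])
}

gap_fwd <- function(X, dims) {
  hw <- dims[1] * dims[2]
  grp <- rep(seq_len(dims[3]), each = hw)
  list(out = rowsum(X, grp, reorder = FALSE) / hw, hw = hw, B = dims[3])
}

gap_bwd <- function(dout, hw, B) {
  dout[rep(seq_len(B), each = hw), , drop = FALSE] / hw
}

dense_fwd <- function(X, lay) {
  list(out = sweep(X %*% lay$W, 2L, lay$b, "+"), cache = X)
}

dense_bwd <- function(dout, cache, lay) {
  list(dx = dout %*% t(lay$W), dW = crossprod(cache, dout), db = colSums(dout))
}

# ---- losses ----

# Numerically stable binary cross-entropy on logits; returns mean loss,
# probabilities and the gradient wrt logits.
bce_from_logits <- function(z, y) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  p <- sigmoid(z)
  list(loss = loss, p = p, dz = (p - y) / n)
}

mse_loss <- function(yhat, y) {
  n <- length(yhat)
  list(loss = sum((yhat - y)^2) / n, dz = 2 * (yhat - y) / n)
}

# ---- Adam optimizer over nested parameter lists ----

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(res, `[[`, "p"),
           m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Total number of trainable scalars in a nested parameter list.
n_params <- function(params) {
  if (is.list(params)) sum(vapply(params, n_params, numeric(1))) else length(params)
}

# Convert a list of H x W matrices (single-channel images, values already
# scaled) into the stacked N x 1 activation matrix plus dims.
stack_images <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  X <- matrix(unlist(lapply(imgs, as.numeric), use.names = FALSE), ncol = 1L)
  list(X = X, dims = c(H, W, length(imgs)))
}
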