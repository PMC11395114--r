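#' U-Net configuration
#'
#' Hyperparameters for the encoder-decoder segmentation network: a
#' contracting path whose channel count doubles at each of `depth`
#' levels, a bottleneck, and an expansive path with skip connections.
#'
#' @param depth Number of pooling levels (>= 2).
#' @param base_channels Channels of the first encoder level; doubles per
#'   level down the contracting path.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed fixing initialization and batch shuffling.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 4L, base_channels = 16L, epochs = 30L,
                        learning_rate = 1e-3, batch_size = 8L, seed = 1L) {
  if (depth < 2L) stop("depth must be >= 2")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "unet_config")
}

unet_channels <- function(config) config$base_channels * 2L^(0:config$depth)

#' Build an untrained U-Net segmentation model
#'
#' Constructs the parameter set of a U-Net: per level two 3x3
#' convolution + batch-norm + ReLU blocks, 2x2 max pooling between
#' levels, nearest-neighbour upsampling with a channel-reducing
#' convolution and skip concatenation on the way up, and a final 1x1
#' convolution with sigmoid pixel output. Initialization is deterministic
#' given `config$seed`.
#'
#' @param config A [unet_config()].
#' @return A `worm_unet` model object.
#' @export
build_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  ch <- unet_channels(config)
  d <- config$depth
  cb_init <- function(cin, cmid) {
    list(k1 = list(c = conv_init(cin, cmid), b = bn_init(cmid)),
         k2 = list(c = conv_init(cmid, cmid), b = bn_init(cmid)))
  }
  cb_run <- function(cmid) list(k1 = bn_run_init(cmid), k2 = bn_run_init(cmid))
  params <- NULL
  with_seed(config$seed, {
    enc <- list(); dec <- list()
    cin <- 1L
    for (l in seq_len(d)) {
      enc[[l]] <- cb_init(cin, ch[l])
      cin <- ch[l]
    }
    bott <- cb_init(ch[d], ch[d + 1])
    for (l in rev(seq_len(d))) {
      up_in <- if (l == d) ch[d + 1] else ch[l + 1]
      dec[[l]] <- c(list(up = list(c = conv_init(up_in, ch[l]),
                                   b = bn_init(ch[l]))),
                    cb_init(2L * ch[l], ch[l]))
    }
    params <- list(enc = enc, bott = bott, dec = dec,
                   out = conv_init(ch[1], 1L, k = 1L))
  })
  running <- list(enc = lapply(seq_len(d), function(l) cb_run(ch[l])),
                  bott = cb_run(ch[d + 1]),
                  dec = lapply(seq_len(d), function(l)
                    c(list(up = bn_run_init(ch[l])), cb_run(ch[l]))))
  structure(list(config = config, params = params, running = running,
                 trained = FALSE, loss_history = numeric(0)),
            class = "worm_unet")
}

# conv -> bn -> relu block
cb_fwd <- function(X, dims, p, run, training) {
  cc <- conv_fwd(X, dims, p$c)
  bb <- bn_fwd(cc$out, p$b, run, training)
  rr <- relu_fwd(bb$out)
  list(out = rr$out,
       cache = list(c = cc$cache, b = bb$cache, r = rr$cache),
       run = bb$run)
}

cb_bwd <- function(dout, cache, p) {
  d <- relu_bwd(dout, cache$r)
  bb <- bn_bwd(d, cache$b)
  cbk <- conv_bwd(bb$dx, cache$c, p$c)
  list(dx = cbk$dx,
       g = list(c = list(W = cbk$dW, b = cbk$db),
                b = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

dcb_fwd <- function(X, dims, p, run, training) {
  r1 <- cb_fwd(X, dims, p$k1, run$k1, training)
  r2 <- cb_fwd(r1$out, dims, p$k2, run$k2, training)
  list(out = r2$out, cache = list(k1 = r1$cache, k2 = r2$cache),
       run = list(k1 = r1$run, k2 = r2$run))
}

dcb_bwd <- function(dout, cache, p) {
  b2 <- cb_bwd(dout, cache$k2, p$k2)
  b1 <- cb_bwd(b2$dx, cache$k1, p$k1)
  list(dx = b1$dx, g = list(k1 = b1$g, k2 = b2$g))
}

unet_fwd <- function(model, X, dims, training) {
  p <- model$params; run <- model$running
  d <- model$config$depth
  skips <- vector("list", d)
  skip_dims <- vector("list", d)
  caches <- list(enc = vector("list", d), dec = vector("list", d))
  for (l in seq_len(d)) {
    e <- dcb_fwd(X, dims, p$enc[[l]], run$enc[[l]], training)
    run$enc[[l]] <- e$run
    skips[[l]] <- e$out
    skip_dims[[l]] <- dims
    mp <- maxpool_fwd(e$out, dims)
    caches$enc[[l]] <- list(blk = e$cache, mp = mp$cache, dims = dims)
    X <- mp$out; dims <- mp$dims
  }
  bo <- dcb_fwd(X, dims, p$bott, run$bott, training)
  run$bott <- bo$run
  caches$bott <- list(blk = bo$cache, dims = dims)
  X <- bo$out
  for (l in rev(seq_len(d))) {
    us <- upsample_fwd(X, dims)
    low_dims <- dims
    dims <- us$dims
    up <- cb_fwd(us$out, dims, p$dec[[l]]$up, run$dec[[l]]$up, training)
    run$dec[[l]]$up <- up$run
    nsk <- ncol(skips[[l]])
    Xc <- cbind(skips[[l]], up$out)
    blk <- dcb_fwd(Xc, dims, p$dec[[l]][c("k1", "k2")],
                   run$dec[[l]][c("k1", "k2")], training)
    run$dec[[l]]$k1 <- blk$run$k1
    run$dec[[l]]$k2 <- blk$run$k2
    caches$dec[[l]] <- list(up = up$cache, blk = blk$cache,
                            nsk = nsk, low_dims = low_dims, dims = dims)
    X <- blk$out
  }
  oc <- conv_fwd(X, dims, p$out, k = 1L)
  caches$out <- oc$cache
  list(z = oc$out, caches = caches, running = run, dims = dims)
}

unet_bwd <- function(model, caches, dz) {
  p <- model$params
  d <- model$config$depth
  g <- list(enc = vector("list", d), bott = NULL, dec = vector("list", d),
            out = NULL)
  ob <- conv_bwd(dz, caches$out, p$out)
  g$out <- list(W = ob$dW, b = ob$db)
  dX <- ob$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {
    cc <- caches$dec[[l]]
    blk <- dcb_bwd(dX, cc$blk, p$dec[[l]][c("k1", "k2")])
    dskips[[l]] <- blk$dx[, seq_len(cc$nsk), drop = FALSE]
    dup <- blk$dx[, -seq_len(cc$nsk), drop = FALSE]
    ub <- cb_bwd(dup, cc$up, p$dec[[l]]$up)
    g$dec[[l]] <- c(list(up = ub$g), blk$g)
    dX <- upsample_bwd(ub$dx, cc$dims)
  }
  bb <- dcb_bwd(dX, caches$bott$blk, p$bott)
  g$bott <- bb$g
  dX <- bb$dx
  for (l in rev(seq_len(d))) {
    cc <- caches$enc[[l]]
    dpool <- maxpool_bwd(dX, cc$mp)
    dpool <- dpool + dskips[[l]]
    eb <- dcb_bwd(dpool, cc$blk, p$enc[[l]])
    g$enc[[l]] <- eb$g
    dX <- eb$dx
  }
  g
}

check_unet_shape <- function(model, H, W) {
  f <- 2L^model$config$depth
  if (H %% f != 0L || W %% f != 0L)
    stop(sprintf(paste("image shape %dx%d is not divisible by 2^depth = %d;",
                       "pad the image to a multiple of %d"), H, W, f, f))
}

#' Train a U-Net on paired images and masks
#'
#' Minimizes per-pixel binary cross-entropy with Adam over mini-batches.
#' Images are scaled to `[0, 1]`; masks may be 0/255 or 0/1. Training is
#' deterministic given the config seed.
#'
#' @param model A `worm_unet` from [build_unet()].
#' @param images List of 8-bit image matrices, all the same shape, with
#'   both sides divisible by `2^depth`.
#' @param masks List of binary ground-truth masks matching `images`.
#' @param config Optional [unet_config()] overriding the model's.
#' @return The trained model; `$loss_history` holds the mean per-epoch
#'   training loss.
#' @export
train_unet <- function(model, images, masks, config = model$config) {
  stopifnot(inherits(model, "worm_unet"))
  if (length(images) != length(masks) || length(images) == 0)
    stop("images and masks must be non-empty paired lists")
  shp <- dim(images[[1]])
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), shp) || !identical(dim(masks[[i]]), shp))
      stop(sprintf("image/mask pair %d has mismatched shape", i))
  }
  check_unet_shape(model, shp[1], shp[2])
  model$config <- config
  x_all <- lapply(images, function(m) m / 255)
  y_all <- lapply(masks, function(m) mask01(m))
  n <- length(images)
  bs <- max(1L, min(config$batch_size, n))
  state <- adam_init(model$params)
  losses <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        sel <- ord[start:min(start + bs - 1L, n)]
        st <- stack_images(x_all[sel])
        y <- unlist(lapply(y_all[sel], as.numeric), use.names = FALSE)
        fw <- unet_fwd(model, st$X, st$dims, training = TRUE)
        model$running <- fw$running
        lo <- bce_from_logits(as.numeric(fw$z), y)
        dz <- matrix(lo$dz, ncol = 1L)
        grads <- unet_bwd(model, fw$caches, dz)
        upd <- adam_step(model$params, grads, state, lr = config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lo$loss; nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
    }
  })
  model$loss_history <- losses
  model$trained <- TRUE
  model
}

#' Predict a binary mask with a trained U-Net
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' binarizes the sigmoid pixel probabilities.
#'
#' @param model A trained `worm_unet`.
#' @param image 8-bit image matrix whose sides are divisible by
#'   `2^depth`.
#' @param prob_threshold Pixels with probability >= this become
#'   foreground (255). Default 0.5.
#' @return Binary 0/255 mask of the image's shape.
#' @export
predict_mask <- function(model, image, prob_threshold = 0.5) {
  p <- predict(model, image, type = "prob")
  out <- matrix(ifelse(as.vector(p) >= prob_threshold, 255L, 0L),
                nrow(p), ncol(p))
  storage.mode(out) <- "integer"
  out
}

#' @rdname predict_mask
#' @param object A trained `worm_unet`.
#' @param type `"prob"` for the pixel probability map, `"mask"` for the
#'   thresholded 0/255 mask.
#' @param ... Unused.
#' @export
predict.worm_unet <- function(object, image, type = c("mask", "prob"),
                              prob_threshold = 0.5, ...) {
  type <- match.arg(type)
  if (!object$trained)
    warning("predicting with an untrained U-Net")
  px <- pixels_of(image)
  check_unet_shape(object, nrow(px), ncol(px))
  st <- stack_images(list(px / 255))
  fw <- unet_fwd(object, st$X, st$dims, training = FALSE)
  p <- matrix(sigmoid(as.numeric(fw$z)), nrow(px), ncol(px))
  if (type == "prob") p else predict_mask_from_prob(p, prob_threshold)
}

predict_mask_from_prob <- function(p, prob_threshold) {
  out <- matrix(ifelse(as.vector(p) >= prob_threshold, 255L, 0L),
                nrow(p), ncol(p))
  storage.mode(out) <- "integer"
  out
}

#' @export
print.worm_unet <- function(x, ...) {
  cfg <- x$config
  cat("U-Net segmentation model\n")
  cat(sprintf("  depth %d, base channels %d (%s)\n", cfg$depth,
              cfg$base_channels,
              paste(unet_channels(cfg), collapse = "-")))
  cat(sprintf("  parameters: %d\n", n_params(x$params)))
  cat(sprintf("  trained: %s", if (x$trained) sprintf(
    "yes (%d epochs, final loss %.4f)", length(x$loss_history),
    x$loss_history[length(x$loss_history)]) else "no"), "\n")
  invisible(x)
}

#' @export
plot.worm_unet <- function(x, ...) {
  if (!length(x$loss_history)) stop("model has no training history")
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training BCE loss",
                 main = "U-Net training loss", ...)
  invisible(x)
}
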