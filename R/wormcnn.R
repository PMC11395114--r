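#' WormCNN configuration
#'
#' Hyperparameters of the residual age-prediction network: a 3x3
#' convolution stem (32 filters by default, padding preserving spatial
#' dims), a stack of identity-shortcut residual blocks at the stem width,
#' global average pooling, a 64-unit fully connected layer with ReLU, and
#' a final 1-unit head — sigmoid for elderly/non-elderly classification,
#' linear for age regression.
#'
#' @param input_shape `(length, width)` of the input strips; inputs of a
#'   different size are bilinearly resized. Default the canonical
#'   `c(600, 30)`.
#' @param stem_filters Stem convolution filters (default 32).
#' @param n_residual_blocks Number of residual blocks (default 3).
#' @param fc_units Hidden units of the fully connected layer (default 64).
#' @param task `"classification"` or `"regression"`.
#' @param epochs Training epochs (default 64).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param validation_split Held-out fraction for per-epoch monitoring.
#' @param seed Integer seed fixing initialization, split and shuffling.
#' @return A `wormcnn_config` list.
#' @export
wormcnn_config <- function(input_shape = c(600L, 30L), stem_filters = 32L,
                           n_residual_blocks = 3L, fc_units = 64L,
                           task = c("classification", "regression"),
                           epochs = 64L, learning_rate = 1e-3,
                           batch_size = 8L, validation_split = 0.2,
                           seed = 1L) {
  task <- match.arg(task)
  structure(list(input_shape = as.integer(input_shape),
                 stem_filters = as.integer(stem_filters),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 fc_units = as.integer(fc_units), task = task,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 validation_split = validation_split,
                 seed = as.integer(seed)),
            class = "wormcnn_config")
}

#' Build an untrained WormCNN
#'
#' @param config A [wormcnn_config()].
#' @return A `wormcnn` model object.
#' @export
build_wormcnn <- function(config = wormcnn_config()) {
  stopifnot(inherits(config, "wormcnn_config"))
  f <- config$stem_filters
  params <- with_seed(config$seed, {
    list(stem = list(c = conv_init(1L, f), b = bn_init(f)),
         blocks = lapply(seq_len(config$n_residual_blocks), function(i)
           list(c1 = conv_init(f, f), b1 = bn_init(f),
                c2 = conv_init(f, f), b2 = bn_init(f))),
         fc1 = dense_init(f, config$fc_units),
         fc2 = dense_init(config$fc_units, 1L))
  })
  running <- list(stem = bn_run_init(f),
                  blocks = lapply(seq_len(config$n_residual_blocks),
                                  function(i) list(b1 = bn_run_init(f),
                                                   b2 = bn_run_init(f))))
  structure(list(config = config, params = params, running = running,
                 trained = FALSE, loss_history = numeric(0),
                 metrics_history = NULL, y_center = 0, y_scale = 1),
            class = "wormcnn")
}

# Residual block, Eq-style: res_out = ReLU(BN(Conv(ReLU(BN(Conv(x))))) + x)
resblock_fwd <- function(X, dims, p, run, training) {
  c1 <- conv_fwd(X, dims, p$c1)
  b1 <- bn_fwd(c1$out, p$b1, run$b1, training)
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, dims, p$c2)
  b2 <- bn_fwd(c2$out, p$b2, run$b2, training)
  ro <- relu_fwd(b2$out + X)
  list(out = ro$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, ro = ro$cache),
       run = list(b1 = b1$run, b2 = b2$run))
}

resblock_bwd <- function(dout, cache, p) {
  dsum <- relu_bwd(dout, cache$ro)
  b2 <- bn_bwd(dsum, cache$b2)
  c2 <- conv_bwd(b2$dx, cache$c2, p$c2)
  dr1 <- relu_bwd(c2$dx, cache$r1)
  b1 <- bn_bwd(dr1, cache$b1)
  c1 <- conv_bwd(b1$dx, cache$c1, p$c1)
  list(dx = c1$dx + dsum,  # branch + identity shortcut
       g = list(c1 = list(W = c1$dW, b = c1$db),
                b1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                c2 = list(W = c2$dW, b = c2$db),
                b2 = list(gamma = b2$dgamma, beta = b2$dbeta)))
}

wormcnn_fwd <- function(model, X, dims, training) {
  p <- model$params; run <- model$running
  st_c <- conv_fwd(X, dims, p$stem$c)
  st_b <- bn_fwd(st_c$out, p$stem$b, run$stem, training)
  st_r <- relu_fwd(st_b$out)
  run$stem <- st_b$run
  X <- st_r$out
  bcaches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    rb <- resblock_fwd(X, dims, p$blocks[[i]], run$blocks[[i]], training)
    run$blocks[[i]] <- rb$run
    bcaches[[i]] <- rb$cache
    X <- rb$out
  }
  gp <- gap_fwd(X, dims)
  f1 <- dense_fwd(gp$out, p$fc1)
  fr <- relu_fwd(f1$out)
  f2 <- dense_fwd(fr$out, p$fc2)
  list(z = f2$out,
       caches = list(stem = list(c = st_c$cache, b = st_b$cache,
                                 r = st_r$cache),
                     blocks = bcaches, gap = gp, f1 = f1$cache,
                     fr = fr$cache, f2 = f2$cache),
       running = run)
}

wormcnn_bwd <- function(model, caches, dz) {
  p <- model$params
  g <- list()
  f2 <- dense_bwd(dz, caches$f2, p$fc2)
  g$fc2 <- list(W = f2$dW, b = f2$db)
  dfr <- relu_bwd(f2$dx, caches$fr)
  f1 <- dense_bwd(dfr, caches$f1, p$fc1)
  g$fc1 <- list(W = f1$dW, b = f1$db)
  dX <- gap_bwd(f1$dx, caches$gap$hw, caches$gap$B)
  g$blocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    rb <- resblock_bwd(dX, caches$blocks[[i]], p$blocks[[i]])
    g$blocks[[i]] <- rb$g
    dX <- rb$dx
  }
  d <- relu_bwd(dX, caches$stem$r)
  bb <- bn_bwd(d, caches$stem$b)
  cb <- conv_bwd(bb$dx, caches$stem$c, p$stem$c)
  g$stem <- list(c = list(W = cb$dW, b = cb$db),
                 b = list(gamma = bb$dgamma, beta = bb$dbeta))
  g[c("stem", "blocks", "fc1", "fc2")]
}

# Normalize one strip to the model's input shape, scaled to [0, 1].
prep_strip <- function(worm, input_shape) {
  px <- if (inherits(worm, "straightened_worm")) worm$pixels else worm
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  if (!identical(dim(px), as.integer(input_shape)))
    px <- cpp_resize_bilinear(px, input_shape[1], input_shape[2])
  px / 255
}

wormcnn_logits <- function(model, strips, training = FALSE) {
  st <- stack_images(strips)
  fw <- wormcnn_fwd(model, st$X, st$dims, training)
  list(z = as.numeric(fw$z), fw = fw)
}

#' Train a WormCNN on straightened worms
#'
#' Classification minimizes binary cross-entropy on the elderly label;
#' regression minimizes mean squared error on (internally standardized)
#' age. Optimization is Adam over shuffled mini-batches, with a seeded
#' stratified train/validation split and per-epoch monitoring of train
#' loss plus validation loss and accuracy (classification) or RMSE
#' (regression).
#'
#' @param model A `wormcnn` from [build_wormcnn()].
#' @param worms List of `straightened_worm` objects or strip matrices.
#' @param labels Binary 0/1 labels (classification) or ages in days
#'   (regression).
#' @param config Optional [wormcnn_config()] override.
#' @return The trained model with `$loss_history` and
#'   `$metrics_history` (epoch, train_loss, val_loss, val_metric).
#' @export
train_wormcnn <- function(model, worms, labels, config = model$config) {
  stopifnot(inherits(model, "wormcnn"))
  n <- length(worms)
  if (n != length(labels) || n < 4L)
    stop("need matching worms/labels (at least 4)")
  y <- as.numeric(labels)
  if (config$task == "classification" && !all(y %in% c(0, 1)))
    stop("classification labels must be binary 0/1")
  if (config$task == "regression" && any(!is.finite(y)))
    stop("regression labels must be finite ages")
  model$config <- config
  strips <- lapply(worms, prep_strip, input_shape = config$input_shape)
  if (config$task == "regression") {
    model$y_center <- mean(y)
    model$y_scale <- max(sd(y), 1e-8)
  }
  yt <- if (config$task == "regression")
    (y - model$y_center) / model$y_scale else y
  state <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_metric = numeric(0))
  with_seed(config$seed + 1L, {
    # stratified 80/20 split (by label for classification, by age
    # quartile for regression)
    strata <- if (config$task == "classification") y else
      findInterval(y, quantile(y, c(0.25, 0.5, 0.75)))
    val_idx <- unlist(lapply(unique(strata), function(s) {
      idx <- which(strata == s)
      if (length(idx) < 2L) return(integer(0))
      sample(idx, max(1L, round(config$validation_split * length(idx))))
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)
    bs <- max(1L, min(config$batch_size, length(tr_idx)))
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = bs)) {
        sel <- ord[start:min(start + bs - 1L, length(ord))]
        lg <- wormcnn_logits(model, strips[sel], training = TRUE)
        model$running <- lg$fw$running
        if (config$task == "classification") {
          lo <- bce_from_logits(lg$z, yt[sel])
        } else {
          lo <- mse_loss(lg$z, yt[sel])
        }
        dz <- matrix(lo$dz, ncol = 1L)
        grads <- wormcnn_bwd(model, lg$fw$caches, dz)
        upd <- adam_step(model$params, grads, state,
                         lr = config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lo$loss; nb <- nb + 1L
      }
      # validation pass in inference mode
      if (length(val_idx) > 0L) {
        vz <- wormcnn_logits(model, strips[val_idx], training = FALSE)$z
        if (config$task == "classification") {
          vl <- bce_from_logits(vz, yt[val_idx])
          vm <- mean((sigmoid(vz) >= 0.5) == (yt[val_idx] == 1))
          val_loss <- vl$loss
        } else {
          val_loss <- mse_loss(vz, yt[val_idx])$loss
          vm <- sqrt(mean(((vz * model$y_scale + model$y_center) -
                             y[val_idx])^2))
        }
      } else {
        val_loss <- NA_real_; vm <- NA_real_
      }
      hist[ep, ] <- list(ep, ep_loss / nb, val_loss, vm)
    }
  })
  model$loss_history <- hist$train_loss
  model$metrics_history <- hist
  model$trained <- TRUE
  model
}

#' Predict elderly probability or biological age
#'
#' Runs the network in inference mode (running batch-norm statistics), so
#' predictions are deterministic and independent of batch composition.
#'
#' @param object A trained `wormcnn`.
#' @param worms List of `straightened_worm` objects or strip matrices.
#' @param ... Unused.
#' @return A data frame with `worm_id`, `true_age_days` (NA when the
#'   input carries no metadata) and `elderly_probability`
#'   (classification) or `predicted_age_days` (regression).
#' @export
predict.wormcnn <- function(object, worms, ...) {
  if (!object$trained) warning("predicting with an untrained WormCNN")
  if (inherits(worms, "straightened_worm") || is.matrix(worms))
    worms <- list(worms)
  strips <- lapply(worms, prep_strip, input_shape = object$config$input_shape)
  z <- wormcnn_logits(object, strips, training = FALSE)$z
  meta <- function(w, f, default) {
    if (inherits(w, "straightened_worm")) w[[f]] else default
  }
  out <- data.frame(
    worm_id = vapply(worms, meta, character(1), f = "worm_id",
                     default = NA_character_),
    true_age_days = vapply(worms, meta, numeric(1), f = "age_days",
                           default = NA_real_),
    stringsAsFactors = FALSE)
  if (object$config$task == "classification") {
    out$elderly_probability <- sigmoid(z)
  } else {
    out$predicted_age_days <- z * object$y_scale + object$y_center
  }
  out
}

#' @export
print.wormcnn <- function(x, ...) {
  cfg <- x$config
  cat("WormCNN residual age model\n")
  cat(sprintf("  task: %s, input %dx%d, stem %d filters, %d residual blocks, fc %d\n",
              cfg$task, cfg$input_shape[1], cfg$input_shape[2],
              cfg$stem_filters, cfg$n_residual_blocks, cfg$fc_units))
  cat(sprintf("  parameters: %d\n", n_params(x$params)))
  cat(sprintf("  trained: %s\n", if (x$trained) sprintf(
    "yes (%d epochs, final train loss %.4f)", length(x$loss_history),
    x$loss_history[length(x$loss_history)]) else "no"))
  invisible(x)
}

#' @export
plot.wormcnn <- function(x, ...) {
  h <- x$metrics_history
  if (is.null(h)) stop("model has no training history")
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "WormCNN training", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}
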