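# A toy strip generator with a direct width signal: darker band whose
# thickness grows with age, plus noise.
toy_strip <- function(age, seed, shape = c(60L, 10L)) {
  set.seed(seed)
  px <- matrix(200, shape[1], shape[2])
  half <- min(shape[2] %/% 2 - 1, round(1 + 0.35 * age))
  mid <- shape[2] / 2
  px[, max(1, floor(mid - half)):min(shape[2], ceiling(mid + half))] <- 60
  px <- px + matrix(rnorm(prod(shape), 0, 8), shape[1], shape[2])
  wormaging:::as_u8(px)
}

test_that("residual block follows its composition exactly", {
  cfg <- wormcnn_config(input_shape = c(4L, 4L), stem_filters = 2L,
                        n_residual_blocks = 1L, seed = 8)
  m <- build_wormcnn(cfg)
  p <- m$params$blocks[[1]]
  run <- m$running$blocks[[1]]
  set.seed(9)
  dims <- c(4L, 4L, 1L)
  x <- matrix(rnorm(32), 16, 2)
  got <- wormaging:::resblock_fwd(x, dims, p, run, training = FALSE)$out
  # independent composition via the (oracle-verified) primitives
  bnin <- function(z, lay, r) {
    xhat <- sweep(sweep(z, 2, r$mean, "-"), 2, sqrt(r$var + 1e-5), "/")
    sweep(sweep(xhat, 2, lay$gamma, "*"), 2, lay$beta, "+")
  }
  cv <- function(z, lay) {
    cols <- wormaging:::cpp_im2col(z, 4L, 4L, 1L, 3L, 1L)
    sweep(cols %*% lay$W, 2, lay$b, "+")
  }
  branch <- pmax(bnin(cv(pmax(bnin(cv(x, p$c1), p$b1, run$b1), 0), p$c2),
                      p$b2, run$b2) + x, 0)
  expect_equal(got, branch, tolerance = 1e-10)

  # zero-initialized convs with identity BN reduce to ReLU(x)
  p0 <- p
  p0$c1$W[] <- 0; p0$c1$b[] <- 0; p0$c2$W[] <- 0; p0$c2$b[] <- 0
  got0 <- wormaging:::resblock_fwd(x, dims, p0, run, training = FALSE)$out
  expect_equal(got0, pmax(x, 0), ignore_attr = TRUE)
})

test_that("heads output sigma(0) = 0.5 or 0 under zero weights", {
  cfg <- wormcnn_config(input_shape = c(8L, 4L), stem_filters = 2L,
                        n_residual_blocks = 1L, seed = 2)
  m <- build_wormcnn(cfg)
  m$params$fc1$W[] <- 0; m$params$fc1$b[] <- 0
  m$params$fc2$W[] <- 0; m$params$fc2$b[] <- 0
  strip <- matrix(128L, 8, 4)
  p <- suppressWarnings(predict(m, strip))
  expect_equal(p$elderly_probability, 0.5)
  m$config$task <- "regression"
  # zero head gives a zero logit; the reported age is the (zero) center
  z <- wormaging:::wormcnn_logits(m, list(strip / 255))$z
  expect_equal(z, 0)
})

test_that("model construction is deterministic and batch composition is irrelevant", {
  cfg <- wormcnn_config(input_shape = c(20L, 8L), stem_filters = 4L,
                        n_residual_blocks = 1L, seed = 13)
  expect_identical(build_wormcnn(cfg)$params, build_wormcnn(cfg)$params)
  m <- build_wormcnn(cfg)
  strips <- lapply(1:3, function(i) toy_strip(i * 3, seed = 40 + i,
                                              shape = c(20L, 8L)))
  batched <- suppressWarnings(predict(m, strips))$elderly_probability
  single <- vapply(strips, function(s)
    suppressWarnings(predict(m, s))$elderly_probability, numeric(1))
  expect_equal(batched, single, tolerance = 1e-12)
  expect_true(all(batched > 0 & batched < 1))
  # stem contract: 3x3 same-padding conv preserves spatial dims and emits
  # stem_filters feature maps
  st <- wormaging:::stack_images(list(toy_strip(2, 1, c(20L, 8L)) / 255))
  sc <- wormaging:::conv_fwd(st$X, st$dims, m$params$stem$c)
  expect_equal(dim(sc$out), c(20L * 8L, 4L))
})

test_that("WormCNN learns a width-coded age signal in both tasks", {
  ages <- rep(c(1, 2, 3, 9, 10, 11), each = 8)
  strips <- lapply(seq_along(ages), function(i)
    toy_strip(ages[i], seed = 100 + i))
  y <- as.integer(ages >= 9)
  cfg <- wormcnn_config(input_shape = c(60L, 10L), stem_filters = 4L,
                        n_residual_blocks = 1L, task = "classification",
                        epochs = 8, batch_size = 8, learning_rate = 2e-3,
                        seed = 21)
  m <- train_wormcnn(build_wormcnn(cfg), strips, y)
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])
  pr <- predict(m, strips)$elderly_probability
  expect_gt(mean((pr >= 0.5) == (y == 1)), 0.9)
  # determinism of the whole training loop
  m2 <- train_wormcnn(build_wormcnn(cfg), strips, y)
  expect_equal(tail(m$loss_history, 1), tail(m2$loss_history, 1))

  rcfg <- wormcnn_config(input_shape = c(60L, 10L), stem_filters = 4L,
                         n_residual_blocks = 1L, task = "regression",
                         epochs = 8, batch_size = 8, learning_rate = 2e-3,
                         seed = 22)
  mr <- train_wormcnn(build_wormcnn(rcfg), strips, ages)
  pa <- predict(mr, strips)$predicted_age_days
  expect_gt(pearson_r(pa, ages), 0.8)

  # label/task mismatches are rejected
  expect_error(train_wormcnn(build_wormcnn(cfg), strips, ages), "binary")
})
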