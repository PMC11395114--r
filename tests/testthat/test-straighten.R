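test_that("coordinate rotation is exact, length-preserving and invertible", {
  r <- rotate_coords(1, 0, pi / 2)
  expect_equal(r$x, 0, tolerance = 1e-12)
  expect_equal(r$y, 1, tolerance = 1e-12)
  expect_equal(rotate_coords(3.2, -1.5, 0), list(x = 3.2, y = -1.5))
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20); th <- runif(1, -pi, pi)
  f <- rotate_coords(x, y, th)
  b <- rotate_coords(f$x, f$y, -th)
  expect_equal(b$x, x, tolerance = 1e-12)
  expect_equal(b$y, y, tolerance = 1e-12)
  expect_equal(sqrt(f$x^2 + f$y^2), sqrt(x^2 + y^2), tolerance = 1e-12)
})

test_that("segments of a straight horizontal worm are vertical column slices", {
  img <- matrix(0L, 21, 30)
  img[, ] <- matrix(rep(seq(10L, 240L, length.out = 21), 30), 21, 30)
  path <- cbind(x = 5:24, y = rep(10L, 20))
  st <- extract_segments(img, path, half_width = 4)
  expect_identical(dim(st), c(20L, 9L))
  # theta = 0: profile k at offset s equals image[10 + s, x]
  for (k in c(1, 10, 20))
    expect_equal(st[k, ], as.numeric(img[7:15, path[k, "x"] + 1]),
                 tolerance = 1e-9)
  # constant image gives a constant stack
  stc <- extract_segments(matrix(99L, 21, 30), path, half_width = 4)
  expect_true(all(stc == 99))
})

test_that("profiles leaving the image are padded with background and flagged", {
  img <- matrix(200L, 12, 30)
  path <- cbind(x = 5:24, y = rep(2L, 20))  # near the top edge
  st <- extract_segments(img, path, half_width = 6)
  expect_true(attr(st, "clipped"))
  expect_true(all(st == 200))  # fill equals the border median here
})

test_that("reconstruction meets the canonical shape contract", {
  set.seed(8)
  stack <- matrix(runif(600 * 30, 0, 255), 600, 30)
  sw <- reconstruct_straightened(round(stack))
  expect_identical(dim(sw$pixels), c(600L, 30L))
  expect_equal(sw$pixels, wormaging:::as_u8(round(stack)))  # identity resize
  sw2 <- reconstruct_straightened(matrix(10, 40, 9))
  expect_identical(dim(sw2$pixels), c(600L, 30L))
  expect_error(reconstruct_straightened(matrix(0, 0, 0)), "empty")
})

test_that("straight worms round-trip to an axis-aligned crop", {
  s <- make_small_sample(6, seed = 50, canvas = c(96L, 96L))
  ph <- s$phenotype
  ph$curvature_amplitude <- 0
  s0 <- render_worm(ph, c(96L, 96L), seed = 51, orientation = 0)
  sw <- straighten_worm(s0$image, s0$mask, half_width = 8,
                        out_shape = c(200L, 17L))
  # direct axis-aligned crop spanning the same skeleton extent
  path <- order_skeleton_path(skeletonize_mask(s0$mask))
  yc <- round(median(path[, "y"])) + 1
  xr <- range(path[, "x"]) + 1
  crop <- s0$image[(yc - 8):(yc + 8), xr[1]:xr[2]]
  crop <- wormaging:::cpp_resize_bilinear(
    matrix(as.numeric(crop), nrow(crop)), 17L, 200L)
  r <- cor(as.numeric(t(sw$pixels)), as.numeric(crop))
  expect_gt(r, 0.95)
})

test_that("curved worms straighten into a centered horizontal band", {
  s <- make_small_sample(4, seed = 70, canvas = c(96L, 96L),
                         orientation = 0.5)
  sw <- straighten_worm(s$mask, s$mask, half_width = 10,
                        out_shape = c(300L, 21L))
  band <- sw$pixels > 128
  centers <- apply(band, 1, function(rr) if (any(rr)) mean(which(rr)) else NA)
  expect_gt(sum(!is.na(centers)), 250)
  # away from the thinning-eroded tips, the body center stays within
  # 3 px of the strip midline
  interior <- centers[16:285]
  expect_lt(max(abs(interior - 11), na.rm = TRUE), 3)
})

test_that("straightening is invariant to 90-degree image rotation", {
  # low background noise isolates the geometric error: with strong noise
  # a 1-px sampling shift already contributes ~noise_sigma per pixel
  ph <- sample_phenotype(5, small_law(noise_sigma = 3), seed = 90)
  s <- render_worm(ph, c(96L, 96L), seed = 91, orientation = 0.7)
  sw1 <- straighten_worm(s$image, s$mask, out_shape = c(200L, 21L))
  sw2 <- straighten_worm(rot90(s$image), rot90(s$mask) * 1L,
                         out_shape = c(200L, 21L))
  a <- matrix(as.numeric(sw1$pixels), 200, 21)
  b <- matrix(as.numeric(sw2$pixels), 200, 21)
  # head/tail canonicalization may flip under rotation
  d <- min(mean(abs(a - b)), mean(abs(a - b[200:1, 21:1])),
           mean(abs(a - b[200:1, ])), mean(abs(a - b[, 21:1])))
  expect_lt(d, 5)
})
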