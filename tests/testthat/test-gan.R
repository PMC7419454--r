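# GAN assembly: losses, network contracts, augmentation, smoke training.

test_that("loss closed forms and hand evaluations", {
  expect_equal(loss_discriminator(1, 0), 0, tolerance = 1e-6)
  expect_equal(loss_discriminator(0.5, 0.5), 2 * log(2), tolerance = 1e-9)
  ref <- -mean(log(c(0.9, 0.8))) - mean(log(1 - c(0.1, 0.3)))
  expect_equal(loss_discriminator(c(0.9, 0.8), c(0.1, 0.3)), ref,
               tolerance = 1e-9)
  expect_equal(loss_generator(1), 0, tolerance = 1e-6)
  expect_equal(loss_generator(c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(loss_generator(c(0.2, 0.9)), -mean(log(c(0.2, 0.9))),
               tolerance = 1e-9)
})

test_that("gan_config validates its fields", {
  expect_error(gan_config(image_size = 60), "4 \\* 2\\^k")
  expect_error(gan_config(image_size = 64, g_channels = c(16L, 8L)), "one entry")
  expect_error(gan_config(image_size = 64,
                          g_channels = c(32L, 16L, 8L, 4L)), "8 channels")
  expect_error(gan_config(d_init = c(10, 300)), "image_size")
  expect_error(gan_config(lr_milestones = c(5, 5)), "increasing")
})

make_small_gan <- function(seed = 1) {
  cfg <- smoke_gan_config(seed = seed)
  list(cfg = cfg,
       G = echosynth:::with_seed(seed, build_generator(cfg)),
       masks = lapply(1:2, function(i)
         sample_artery_mask(artery_mask_spec(image_size = 64, seed = i))))
}

test_that("generator contracts: shape, range, channel widths, stochasticity", {
  gg <- make_small_gan(1)
  pyr <- echosynth:::make_mask_pyramid(gg$masks, 64)
  z <- echosynth:::with_seed(2, matrix(rnorm(2 * 128), 2, 128))
  out <- gg$G$fwd(z, pyr, speckle_seed = 5)
  expect_equal(dim(out), c(64L, 64L, 1L, 2L))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(gg$G$bank$n_in, 8L)
  expect_equal(gg$G$bank$n_out, 32L)
  # same z + same speckle seed -> identical; fresh speckle seed -> different
  expect_identical(out, gg$G$fwd(z, pyr, speckle_seed = 5))
  out2 <- gg$G$fwd(z, pyr, speckle_seed = 6)
  expect_gt(mean(abs(out - out2) > 1e-12), 0.5)
})

test_that("changing the mask changes the generator output", {
  gg <- make_small_gan(3)
  z <- echosynth:::with_seed(4, matrix(rnorm(128), 1, 128))
  p1 <- echosynth:::make_mask_pyramid(gg$masks[1], 64)
  p2 <- echosynth:::make_mask_pyramid(gg$masks[2], 64)
  o1 <- gg$G$fwd(z, p1, speckle_seed = 9)
  o2 <- gg$G$fwd(z, p2, speckle_seed = 9)
  expect_gt(mean(abs(o1 - o2)), 0)
})

test_that("discriminator contracts: shape, range, stride-2 halving, determinism", {
  cfg <- smoke_gan_config(seed = 2)
  D <- echosynth:::with_seed(2, build_discriminator(cfg))
  img <- array(rand_image(64, 64, 1), dim = c(64, 64, 1, 2))
  img[, , , 2] <- rand_image(64, 64, 2)
  mask_oh <- one_hot_mask(array(disc_mask(64), dim = c(64, 64, 1, 2)))
  p <- D$fwd(img, mask_oh)
  expect_equal(dim(p), c(2L, 1L))
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, D$fwd(img, mask_oh))
  # each block halves the spatial size: 64 -> 4 over 4 blocks
  expect_equal(D$pool_dims[1:2], c(4L, 4L))
  x32 <- D$blocks[[1]]$fwd(array(rnorm(64 * 64 * cfg$d_channels[1] * 1),
                                 dim = c(64, 64, cfg$d_channels[1], 1)))
  expect_equal(dim(x32)[1:2], c(32L, 32L))
})

test_that("augment_pair: identity, involution, label preservation", {
  img <- rand_image(32, 32, 5)
  mask <- disc_mask(32)
  # zero rotation is the identity for both interpolators
  expect_equal(rotate_image(img, 0, "bilinear"), img, tolerance = 1e-12)
  expect_identical(rotate_image(mask, 0, "nearest"), mask)
  # rotating forth and back restores a nearest-neighbour mask exactly
  expect_identical(rotate_image(rotate_image(mask, 90, "nearest", fill = 2),
                                -90, "nearest", fill = 2), mask)
  # same seed gives the same joint transform; labels survive any draw
  a1 <- augment_pair(img, mask, seed = 3)
  a2 <- augment_pair(img, mask, seed = 3)
  expect_identical(a1, a2)
  for (s in 1:6) {
    out <- augment_pair(img, mask, seed = s)
    expect_true(all(out$mask %in% 0:2))
    expect_equal(dim(out$image), dim(img))
    expect_true(all(out$image >= -1e-9))
  }
})

test_that("smoke training run completes with checkpoint, log and determinism", {
  dir <- smoke_dataset_dir()
  out1 <- file.path(tempdir(), "run-a"); unlink(out1, recursive = TRUE)
  cfg <- smoke_gan_config(seed = 4, epochs = 2)
  res <- train_gan(dir, cfg, out1)
  expect_equal(nrow(res$log), 4)             # 8 pairs / batch 4 = 2 steps/epoch
  expect_true(file.exists(file.path(out1, "checkpoint_best.rds")))
  expect_true(file.exists(file.path(out1, "metrics.csv")))
  expect_true(any(!is.na(res$log$fid)))
  expect_true(all(is.finite(res$log$loss_g)))
  # bitwise-identical loss log under the same seed
  out2 <- file.path(tempdir(), "run-b"); unlink(out2, recursive = TRUE)
  res2 <- train_gan(dir, cfg, out2)
  expect_identical(res$log, res2$log)
  # checkpoint reload reproduces the generator
  ck <- load_generator(file.path(out1, "checkpoint_best.rds"))
  masks <- list(read_mask(file.path(dir, "mask_0001.png")))
  g1 <- generate_images(ck$generator, masks, seed = 3)
  g2 <- generate_images(res2$generator, masks, seed = 3)
  expect_equal(g1[[1]], g2[[1]], tolerance = 1e-12)
})

test_that("training validates its inputs before starting", {
  cfg <- smoke_gan_config(seed = 1, epochs = 1)
  expect_error(train_gan(list(), cfg, tempfile()), "at least 2")
  bad <- list(list(image = matrix(0.5, 32, 32), mask = matrix(0L, 32, 32)),
              list(image = matrix(0.5, 32, 32), mask = matrix(0L, 32, 32)))
  expect_error(train_gan(bad, cfg, tempfile()), "image_size")
})
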