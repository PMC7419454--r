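# Layer framework: spectral normalization against an SVD oracle, SPADE
# semantics, and finite-difference checks of the hand-written backward
# passes that everything else relies on.

test_that("spectral_normalize: identity, diagonal, SVD oracle", {
  sn <- spectral_normalize(diag(2), list(u = c(1, 0), n_power_iterations = 5))
  expect_equal(sn$weight, diag(2), tolerance = 1e-9)
  sn2 <- spectral_normalize(diag(c(3, 1)),
                            list(u = c(0.8, 0.6), n_power_iterations = 50))
  expect_equal(sn2$weight, diag(c(1, 1 / 3)), tolerance = 1e-6)
  set.seed(11)
  for (k in 1:5) {
    w <- matrix(rnorm(24), 4, 6)
    sn3 <- spectral_normalize(w, list(u = rnorm(4), n_power_iterations = 50))
    expect_equal(max(svd(sn3$weight)$d), 1, tolerance = 1e-3)
    expect_equal(sn3$sigma, max(svd(w)$d), tolerance = 1e-3)
    expect_equal(sqrt(sum(sn3$state$u^2)), 1, tolerance = 1e-9)
  }
})

test_that("SPADE with gamma == 1, beta == 0 is plain standardization", {
  set.seed(5)
  sp <- echosynth:::with_seed(1, spade_params(4, hidden = 8))
  # force the mask branch to emit gamma = 1, beta = 0
  sp$conv_gamma$params$w[] <- 0; sp$conv_gamma$params$b[] <- 1
  sp$conv_beta$params$w[] <- 0; sp$conv_beta$params$b[] <- 0
  x <- array(rnorm(16 * 16 * 4 * 3, mean = 2, sd = 3), dim = c(16, 16, 4, 3))
  mask_oh <- one_hot_mask(array(sample(0:2, 16 * 16 * 3, TRUE),
                                dim = c(16, 16, 1, 3)))
  y <- spade_normalize(x, mask_oh, sp)
  mu <- echosynth:::channel_mean(y)
  sd_c <- sqrt(echosynth:::channel_mean(y * y) - mu^2)
  expect_true(all(abs(mu) < 1e-6))
  expect_true(all(abs(sd_c - 1) < 1e-4))

  # gamma == 2, beta == 1 on the standardized signal
  sp$conv_gamma$params$b[] <- 2; sp$conv_beta$params$b[] <- 1
  y2 <- spade_normalize(x, mask_oh, sp)
  mu2 <- echosynth:::channel_mean(y2)
  sd2 <- sqrt(echosynth:::channel_mean(y2 * y2) - mu2^2)
  expect_true(all(abs(mu2 - 1) < 1e-6))
  expect_true(all(abs(sd2 - 2) < 1e-3))
})

test_that("SPADE tiny case matches the written-out formula", {
  sp <- echosynth:::with_seed(2, spade_params(1, hidden = 2, k = 1))
  x <- array(c(1, 2, 3, 4), dim = c(2, 2, 1, 1))
  mask_oh <- one_hot_mask(matrix(c(0L, 1L, 2L, 0L), 2, 2))
  y <- spade_normalize(x, mask_oh, sp)
  # reproduce by hand: BN stats over the single channel
  mu <- mean(x); sdv <- sqrt(mean((x - mu)^2) + 1e-5)
  xhat <- (x - mu) / sdv
  w_sh <- sp$conv_shared$params$w; b_sh <- sp$conv_shared$params$b
  h <- array(0, dim = c(2, 2, 2, 1))
  for (o in 1:2)
    h[, , o, 1] <- pmax(mask_oh[, , 1, 1] * w_sh[1, 1, 1, o] +
                        mask_oh[, , 2, 1] * w_sh[1, 1, 2, o] +
                        mask_oh[, , 3, 1] * w_sh[1, 1, 3, o] + b_sh[o], 0)
  gam <- h[, , 1, 1] * sp$conv_gamma$params$w[1, 1, 1, 1] +
         h[, , 2, 1] * sp$conv_gamma$params$w[1, 1, 2, 1] +
         sp$conv_gamma$params$b[1]
  bet <- h[, , 1, 1] * sp$conv_beta$params$w[1, 1, 1, 1] +
         h[, , 2, 1] * sp$conv_beta$params$w[1, 1, 2, 1] +
         sp$conv_beta$params$b[1]
  expect_equal(y[, , 1, 1], gam * xhat[, , 1, 1] + bet, tolerance = 1e-9)
})

fd_check <- function(fwd, bwd, x, n_probe = 4, h = 1e-5, tol = 1e-4) {
  y <- fwd(x)
  set.seed(99)
  gy <- array(rnorm(length(y)), dim = dim(y))
  gx <- bwd(gy)
  idx <- sample(length(x), n_probe)
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    num <- (sum(fwd(xp) * gy) - sum(fwd(xm) * gy)) / (2 * h)
    expect_equal(gx[i], num, tolerance = tol)
  }
}

test_that("conv2d backward agrees with finite differences (input and weights)", {
  cv <- echosynth:::with_seed(3, echosynth:::nn_conv(2, 3, 3, stride = 2))
  x <- echosynth:::with_seed(4, array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2)))
  fd_check(function(z) cv$fwd(z),
           function(gy) { echosynth:::zero_grads(cv); cv$bwd(gy) }, x)
  # weight gradient
  y <- cv$fwd(x)
  set.seed(98); gy <- array(rnorm(length(y)), dim = dim(y))
  echosynth:::zero_grads(cv); cv$bwd(gy)
  h <- 1e-5
  for (i in c(1, 17, 40)) {
    w0 <- cv$params$w
    cv$params$w[i] <- w0[i] + h; yp <- cv$fwd(x)
    cv$params$w[i] <- w0[i] - h; ym <- cv$fwd(x)
    cv$params$w <- w0
    expect_equal(cv$grads$w[i], (sum(yp * gy) - sum(ym * gy)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("batchnorm backward agrees with finite differences", {
  bn <- echosynth:::nn_batchnorm(3)
  x <- echosynth:::with_seed(6, array(rnorm(6 * 6 * 3 * 2), dim = c(6, 6, 3, 2)))
  fd_check(function(z) bn$fwd(z),
           function(gy) { echosynth:::zero_grads(bn); bn$bwd(gy) },
           x, tol = 1e-3)
})

test_that("speckle bank backward agrees with finite differences", {
  # keep d away from the [1, min(H, W)] clamp so central differences are valid
  bank <- echosynth:::with_seed(7,
    speckle_bank(n_in = 2, d_init = c(3, 5.5), softness = 0.5))
  x <- echosynth:::with_seed(8, array(rnorm(8 * 8 * 2 * 1), dim = c(8, 8, 2, 1)))
  fd_check(function(z) bank$fwd(z, seed = 123),
           function(gy) { echosynth:::zero_grads(bank); bank$bwd(gy) },
           x, n_probe = 5, tol = 1e-3)
  # learnable d gradient
  y <- bank$fwd(x, seed = 123)
  set.seed(97); gy <- array(rnorm(length(y)), dim = dim(y))
  echosynth:::zero_grads(bank); bank$bwd(gy)
  h <- 1e-4
  for (s in 1:2) {
    d0 <- bank$params$d
    bank$params$d[s] <- d0[s] + h; yp <- bank$fwd(x, seed = 123)
    bank$params$d[s] <- d0[s] - h; ym <- bank$fwd(x, seed = 123)
    bank$params$d <- d0
    expect_equal(bank$grads$d[s], (sum(yp * gy) - sum(ym * gy)) / (2 * h),
                 tolerance = 1e-3)
  }
})

test_that("polar-mode speckle bank backward stays consistent", {
  bank <- echosynth:::with_seed(9,
    speckle_bank(n_in = 1, d_init = 6, softness = 0.5, polar = TRUE))
  x <- echosynth:::with_seed(10, array(rnorm(16 * 16), dim = c(16, 16, 1, 1)))
  fd_check(function(z) bank$fwd(z, seed = 55),
           function(gy) { echosynth:::zero_grads(bank); bank$bwd(gy) },
           x, n_probe = 4, tol = 1e-3)
})
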