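# Speckle core: spectral window, phase sampling, FFT transform vs the
# explicit-convolution oracle, d-differentiability, grain-size estimation.

test_that("spectral window limits: full spectrum is all-ones, d = 1 keeps only DC", {
  w <- make_spectral_window(32, 32, 32, softness = 0)
  expect_true(all(w$mask == 1))
  w1 <- make_spectral_window(1, 32, 32, softness = 0)
  expect_equal(sum(w1$mask), 1)
  expect_equal(w1$mask[17, 17], 1)          # DC bin at floor(n/2) + 1
  expect_equal(w1$mask_shifted[1, 1], 1)    # native layout: DC first
})

test_that("soft window matches a per-bin evaluation of the logistic profile", {
  d <- 8.5; s <- 0.5; n <- 32
  w <- make_spectral_window(d, n, n, softness = s)
  u <- seq_len(n) - (floor(n / 2) + 1)
  ref <- outer(plogis((d / 2 - abs(u)) / s), plogis((d / 2 - abs(u)) / s))
  expect_equal(w$mask, ref, tolerance = 1e-12)
  # 180-degree rotational symmetry about the DC bin (Nyquist row/col aside)
  expect_equal(w$mask[2:n, 2:n], w$mask[n:2, n:2], tolerance = 1e-12)
  # softness -> 0 recovers the hard rectangle
  wh <- make_spectral_window(d, n, n, softness = 0)
  expect_true(all(wh$mask %in% c(0, 1)))
})

test_that("window domain errors", {
  expect_error(make_spectral_window(0, 16, 16), "positive")
  expect_error(make_spectral_window(17, 16, 16), "exceeds")
  expect_error(make_spectral_window(4, 16, 16, softness = -1), "non-negative")
})

test_that("phase field: seeded determinism, range, uniformity", {
  a <- sample_phase_field(32, 32, seed = 7)
  b <- sample_phase_field(32, 32, seed = 7)
  expect_identical(a, b)
  p <- sample_phase_field(2, 2, seed = 0)
  expect_true(all(p >= 0 & p < 2 * pi))
  # empirical mean of cos(phi) within 3 standard errors of 0
  ph <- sample_phase_field(64, 64, seed = 1)
  se <- sqrt(0.5 / length(ph))              # var(cos(U)) = 1/2
  expect_lt(abs(mean(cos(ph))), 3 * se)
  # seeded call does not disturb the global RNG stream
  set.seed(42); x1 <- runif(1)
  set.seed(42); invisible(sample_phase_field(8, 8, seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("apply_speckle: zero image, identity filter, shape errors", {
  w <- make_spectral_window(8, 32, 32, 0)
  ph <- sample_phase_field(32, 32, 1)
  expect_equal(apply_speckle(matrix(0, 32, 32), w, ph), matrix(0, 32, 32))
  img <- rand_image(32, 32, 2)
  wf <- make_spectral_window(32, 32, 32, 0)
  expect_equal(apply_speckle(img, wf, ph), img, tolerance = 1e-12)
  expect_error(apply_speckle(rand_image(16, 16), w, ph), "mismatch")
  expect_true(all(apply_speckle(img, w, ph) >= 0))
})

test_that("FFT path equals the explicit-convolution oracle (Eq.-equivalence)", {
  for (case in list(c(16, 16, 8), c(12, 20, 5), c(32, 32, 11))) {
    h <- case[1]; w <- case[2]; d <- case[3]
    img <- rand_image(h, w, seed = h + w + d)
    win <- make_spectral_window(d, h, w, softness = 0)
    ph <- sample_phase_field(h, w, seed = d)
    a <- apply_speckle(img, win, ph)
    b <- speckle_conv_oracle(img, win, ph)
    expect_lt(max(abs(a - b)) / max(abs(b)), 1e-6)
  }
})

test_that("oracle: delta image reproduces the window kernel magnitude", {
  h <- 8; d <- 4
  img <- matrix(0, h, h); img[3, 5] <- 1
  win <- make_spectral_window(d, h, h, 0)
  ph <- matrix(0, h, h)                     # zero phases: pure kernel shift
  out <- speckle_conv_oracle(img, win, ph)
  er <- exp(2i * pi * outer(0:(h - 1), 0:(h - 1)) / h)
  kernel <- (er %*% win$mask_shifted %*% t(er)) / h^2
  shifted <- Mod(kernel[((0:(h - 1) - 2) %% h) + 1, ((0:(h - 1) - 4) %% h) + 1])
  expect_equal(out, shifted, tolerance = 1e-12)
  expect_equal(speckle_conv_oracle(matrix(0, h, h), win, ph), matrix(0, h, h))
})

test_that("oracle refuses oversized input", {
  win <- make_spectral_window(8, 80, 80, 0)
  expect_error(
    speckle_conv_oracle(matrix(0, 80, 80), win, matrix(0, 80, 80)),
    "refused")
})

test_that("analytic d-gradient matches central finite differences", {
  img <- rand_image(32, 32, 5)
  ph <- sample_phase_field(32, 32, 9)
  for (d0 in c(6, 12, 24)) {
    g_an <- speckle_d_gradient(img, make_spectral_window(d0, 32, 32, 0.5), ph)
    h <- 1e-3
    fp <- mean(apply_speckle(img, make_spectral_window(d0 + h, 32, 32, 0.5), ph))
    fm <- mean(apply_speckle(img, make_spectral_window(d0 - h, 32, 32, 0.5), ph))
    g_fd <- (fp - fm) / (2 * h)
    expect_lt(abs(g_an - g_fd) / abs(g_fd), 1e-3)
  }
})

test_that("speckle grain size: white noise ~1 px, monotone in d, smoothing widens", {
  wn <- echosynth:::with_seed(3, matrix(rnorm(128 * 128), 128, 128))
  expect_lt(estimate_speckle_size(wn), 2.5)
  expect_gt(estimate_speckle_size(wn), 0.5)
  # smaller window -> larger grains (reduced-size version of the invariant)
  sizes <- sapply(c(8, 32), function(d) {
    mean(sapply(1:5, function(s) {
      estimate_speckle_size(apply_speckle(
        matrix(1, 128, 128), make_spectral_window(d, 128, 128, 0),
        sample_phase_field(128, 128, s)))
    }))
  })
  expect_gt(sizes[1], sizes[2])
  # Gaussian smoothing widens the autocorrelation peak
  k <- dnorm(-6:6, sd = 2); k <- k / sum(k)
  kw <- array(outer(k, k), dim = c(13, 13, 1, 1))
  sm <- echosynth:::.conv2d_fwd(array(wn, dim = c(128, 128, 1, 1)), kw, 0, 1L, 6L)
  expect_gt(estimate_speckle_size(matrix(sm, 128, 128)),
            estimate_speckle_size(wn))
  expect_error(estimate_speckle_size(matrix(1, 16, 16)), "constant")
})
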