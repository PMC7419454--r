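# Metric suite: embeddings, Frechet distance, histograms/JS, SSIM, Dice,
# contours, modified Hausdorff.

test_that("desk embedder is deterministic and non-degenerate", {
  emb <- desk_embedder()
  imgs <- list(matrix(0.5, 32, 32), rand_image(32, 32, 1))
  f1 <- embed_images(imgs, emb)
  f2 <- embed_images(imgs, emb)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(2L, 64L))
  expect_gt(sum(abs(f1[1, ] - f1[2, ])), 1e-6)
})

test_that("gaussian_stats: hand case, degenerate cases", {
  gs <- gaussian_stats(matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE))
  expect_equal(gs$mu, c(1, 1))
  expect_equal(gs$cov, matrix(2, 2, 2))
  expect_equal(gaussian_stats(matrix(1, 4, 3))$cov, matrix(0, 3, 3))
  expect_error(gaussian_stats(matrix(1, 1, 3)), "at least 2")
})

test_that("fid: identity, 1-D closed form, symmetry, eigen oracle", {
  set.seed(21)
  f <- matrix(rnorm(40), 8, 5)
  a <- gaussian_stats(f)
  expect_lt(fid(a, a), 1e-6)
  g1 <- structure(list(mu = 0, cov = matrix(1, 1, 1)), class = "gaussian_stats")
  g2 <- structure(list(mu = 3, cov = matrix(1, 1, 1)), class = "gaussian_stats")
  expect_equal(fid(g1, g2), 9, tolerance = 1e-9)
  b <- gaussian_stats(matrix(rnorm(40, sd = 2), 8, 5))
  expect_equal(fid(a, b), fid(b, a), tolerance = 1e-6)
  expect_gte(fid(a, b), 0)
  # independent dense evaluation: eigendecomposition of the plain product
  ev <- eigen(a$cov %*% b$cov, only.values = TRUE)$values
  ref <- sum((a$mu - b$mu)^2) + sum(diag(a$cov)) + sum(diag(b$cov)) -
    2 * sum(sqrt(pmax(Re(ev), 0)))
  expect_equal(fid(a, b), ref, tolerance = 1e-6)
  expect_error(fid(a, g1), "dimensions differ")
})

test_that("class histograms behave", {
  m <- disc_mask(32)
  img <- matrix(0.25, 32, 32)
  h <- class_gray_histogram(img, m, 0, 16)
  expect_equal(sum(h$probabilities), 1, tolerance = 1e-9)
  expect_equal(sum(h$probabilities > 0), 1)
  expect_error(class_gray_histogram(img, m, 3), "not present")
  u <- rand_image(64, 64, 2)
  hu <- class_gray_histogram(u, matrix(2L, 64, 64), 2, 256)
  expect_lt(max(hu$probabilities), 3 / 256)
})

test_that("JS divergence: identity, disjoint supports, hand case, symmetry", {
  p <- structure(list(bin_edges = c(0, .5, 1), probabilities = c(1, 0),
                      class_label = 0L), class = "class_histogram")
  q <- structure(list(bin_edges = c(0, .5, 1), probabilities = c(0, 1),
                      class_label = 0L), class = "class_histogram")
  expect_equal(js_divergence(p, p), 0, tolerance = 1e-9)
  expect_equal(js_divergence(p, q), log(2), tolerance = 1e-6)
  pv <- c(0.5, 0.5); qv <- c(0.9, 0.1)
  mref <- (pv + qv) / 2
  ref <- 0.5 * sum(pv * log(pv / mref)) + 0.5 * sum(qv * log(qv / mref))
  expect_equal(js_divergence(pv, qv), ref, tolerance = 1e-9)
  expect_equal(js_divergence(pv, qv), js_divergence(qv, pv))
  expect_error(js_divergence(c(1, 0), c(1, 0, 0)), "binnings")
})

test_that("ssim: identity, inversion, constant-offset closed form", {
  a <- rand_image(48, 48, 3)
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  hc <- (a > 0.5) * 1                   # high-contrast image
  expect_lt(ssim(hc, 1 - hc), 0.5)
  ca <- matrix(0.2, 32, 32); cb <- matrix(0.7, 32, 32)
  C1 <- 0.01^2
  ref <- (2 * 0.2 * 0.7 + C1) / (0.2^2 + 0.7^2 + C1)   # luminance-only
  expect_equal(ssim(ca, cb), ref, tolerance = 1e-6)
})

test_that("dice: identities and brute-force case", {
  m <- disc_mask(16)
  expect_equal(dice(m, m, 0), 1)
  a <- matrix(2L, 8, 8); b <- matrix(2L, 8, 8)
  a[1:2, 1] <- 0L; b[3:4, 1] <- 0L
  expect_equal(dice(a, b, 0), 0)
  a2 <- matrix(c(0L, 0L, 2L, 2L), 2, 2)
  b2 <- matrix(c(0L, 2L, 0L, 2L), 2, 2)
  expect_equal(dice(a2, b2, 0), 0.5)    # one shared pixel of two each
  expect_equal(dice(a, b, 1), 1)        # class absent from both
  expect_equal(dice(a, b, 0), dice(b, a, 0))
})

test_that("contour_points: isolated pixel, filled square, absence error", {
  m <- matrix(2L, 7, 7); m[4, 4] <- 0L
  expect_equal(contour_points(m, 0), cbind(row = 3L, col = 3L))
  sq <- matrix(2L, 7, 7); sq[3:5, 3:5] <- 1L
  cp <- contour_points(sq, 1)
  expect_equal(nrow(cp), 8)             # perimeter minus the centre
  expect_false(any(cp[, 1] == 3 & cp[, 2] == 3))
  expect_error(contour_points(m, 1), "not present")
})

test_that("modified Hausdorff: identity, hand case, symmetry", {
  A <- cbind(c(0, 0), c(0, 1))
  expect_equal(modified_hausdorff(A, A), 0)
  B <- cbind(2, 0)
  # directed means: ((2 + sqrt(5))/2) and 2; max is the MHD
  expect_equal(modified_hausdorff(A, B), max((2 + sqrt(5)) / 2, 2),
               tolerance = 1e-12)
  set.seed(31)
  P <- matrix(rnorm(20), 10, 2); Q <- matrix(rnorm(16), 8, 2)
  expect_equal(modified_hausdorff(P, Q), modified_hausdorff(Q, P))
})

test_that("fid discriminates matched from mismatched speckle size", {
  render_set <- function(d, seeds) {
    lapply(seeds, function(s) {
      mask <- sample_artery_mask(artery_mask_spec(image_size = 64, seed = s))
      tex <- phantom_texture_spec(speckle_d = rep(d, 3), seed = s)
      render_phantom(mask, tex)
    })
  }
  emb <- desk_embedder()
  ref <- render_set(40, 1:8)
  matched <- render_set(40, 11:18)
  mismatched <- render_set(8, 11:18)
  sr <- gaussian_stats(embed_images(ref, emb))
  expect_lt(fid(gaussian_stats(embed_images(matched, emb)), sr),
            fid(gaussian_stats(embed_images(mismatched, emb)), sr))
})
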