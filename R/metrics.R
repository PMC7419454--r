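## Evaluation metrics: Frechet distance between Gaussian fits of embedded
## image features, per-class gray-value histograms and Jensen-Shannon
## divergence, SSIM, Dice coefficient and modified Hausdorff distance.

#' Deterministic convolutional "desk" embedder
#'
#' A fixed-seed random three-layer strided convolutional projection
#' (1 -> 8 -> 16 -> 32 channels, stride 2, ReLU) followed by global average
#' pooling and a fixed random linear map to `feature_dim` features.  It
#' needs no downloaded weights and is deterministic; absolute Frechet
#' distances are embedder-dependent, so only comparisons sharing an
#' embedder are meaningful.  An externally supplied embedder (e.g. an
#' Inception adapter) can be used instead wherever an `embedder` argument
#' is accepted: any object with elements `feature_dim` and
#' `embed(image) -> numeric vector` qualifies.
#'
#' @param feature_dim embedding dimension (64)
#' @param seed fixed weight seed; changing it defines a different embedder
#' @return an object of class `embedder`
#' @export
desk_embedder <- function(feature_dim = 64L, seed = 20200618L) {
  layers <- with_seed(seed, {
    l <- list(nn_conv(1L, 8L, 3L, stride = 2L),
              nn_conv(8L, 16L, 3L, stride = 2L),
              nn_conv(16L, 32L, 3L, stride = 2L))
    proj <- matrix(rnorm(32L * feature_dim, sd = 1 / sqrt(32)),
                   32L, feature_dim)
    list(convs = l, proj = proj)
  })
  embed <- function(image) {
    x <- array(image, dim = c(nrow(image), ncol(image), 1L, 1L))
    for (cv in layers$convs) {
      x <- cv$fwd(x)
      x <- x * (x > 0)
    }
    d <- dim(x)
    pooled <- colMeans(matrix(x, d[1] * d[2], d[3]))
    drop(pooled %*% layers$proj)
  }
  structure(list(name = "desk", feature_dim = as.integer(feature_dim),
                 embed = embed), class = "embedder")
}

#' Embed a list of images into feature space
#'
#' @param images list of intensity matrices
#' @param embedder an [desk_embedder()]-style object
#' @return `length(images) x feature_dim` feature matrix
#' @export
embed_images <- function(images, embedder = desk_embedder()) {
  t(vapply(images, embedder$embed, numeric(embedder$feature_dim)))
}

#' Gaussian summary (mean and covariance) of a feature matrix
#'
#' @param features numeric matrix, one feature row per image (>= 2 rows)
#' @return list of class `gaussian_stats` with `mu` and `cov` (unbiased,
#'   divisor n - 1)
#' @export
gaussian_stats <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 2)
    stop("need at least 2 feature rows to estimate a covariance")
  structure(list(mu = colMeans(features), cov = cov(features)),
            class = "gaussian_stats")
}

# symmetric PSD square root by eigendecomposition, eigenvalues clipped at 0
sqrtm_psd <- function(C, jitter = 1e-6) {
  e <- tryCatch(eigen((C + t(C)) / 2, symmetric = TRUE),
                error = function(err) {
                  eigen((C + t(C)) / 2 + jitter * diag(nrow(C)),
                        symmetric = TRUE)
                })
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two Gaussian feature summaries
#'
#' `||mu1 - mu2||^2 + Tr(C1 + C2 - 2 (C1 C2)^{1/2})`, evaluated through the
#' symmetrized product `C1^{1/2} C2 C1^{1/2}` (same trace, numerically
#' PSD); tiny negative totals from rounding are clipped to 0.
#'
#' @param a,b [gaussian_stats()] objects of equal dimension
#' @return non-negative scalar distance
#' @export
fid <- function(a, b) {
  if (length(a$mu) != length(b$mu))
    stop("feature dimensions differ (", length(a$mu), " vs ", length(b$mu), ")")
  s1 <- sqrtm_psd(a$cov)
  inner <- s1 %*% b$cov %*% s1
  tr_sqrt <- sum(sqrt(pmax(eigen((inner + t(inner)) / 2,
                                 symmetric = TRUE)$values, 0)))
  val <- sum((a$mu - b$mu)^2) +
    sum(diag(a$cov)) + sum(diag(b$cov)) - 2 * tr_sqrt
  max(val, 0)
}

#' Gray-value histogram of one segmentation class
#'
#' @param image intensity matrix in `[0, 1]`
#' @param mask integer label matrix of the same shape
#' @param class_label class whose pixels are histogrammed (must be present)
#' @param n_bins number of equal-width bins on `[0, 1]`
#' @return object of class `class_histogram` with `bin_edges`,
#'   `probabilities` (summing to 1) and `class_label`
#' @export
class_gray_histogram <- function(image, mask, class_label, n_bins = 256L) {
  same_shape(image, mask, "image vs mask")
  v <- image[mask == class_label]
  if (length(v) == 0)
    stop("class ", class_label, " is not present in the mask")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, probabilities = counts / sum(counts),
                 class_label = as.integer(class_label)),
            class = "class_histogram")
}

#' Jensen-Shannon divergence between two histograms
#'
#' `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q) / 2`, natural
#' logarithm (so the value lies in `[0, log 2]`), with additive epsilon
#' smoothing before renormalization.
#'
#' @param p,q [class_gray_histogram()] objects (or bare probability
#'   vectors) over identical bins
#' @param eps smoothing constant
#' @return divergence in `[0, log(2)]`
#' @export
js_divergence <- function(p, q, eps = 1e-12) {
  pp <- if (inherits(p, "class_histogram")) p$probabilities else p
  qq <- if (inherits(q, "class_histogram")) q$probabilities else q
  if (length(pp) != length(qq)) stop("histograms use different binnings")
  if (inherits(p, "class_histogram") && inherits(q, "class_histogram") &&
      !isTRUE(all.equal(p$bin_edges, q$bin_edges)))
    stop("histograms use different bin edges")
  pp <- (pp + eps) / sum(pp + eps)
  qq <- (qq + eps) / sum(qq + eps)
  m <- (pp + qq) / 2
  0.5 * sum(pp * log(pp / m)) + 0.5 * sum(qq * log(qq / m))
}

#' Mean structural similarity (SSIM) between two images
#'
#' Standard windowed formulation: 11 x 11 Gaussian weights (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03`, data range 1, mean over the valid (fully
#' overlapping) window positions.
#'
#' @param a,b intensity matrices of identical shape, values in `[0, 1]`
#' @return mean SSIM in `[-1, 1]`
#' @export
ssim <- function(a, b) {
  a <- as_image(a, "a"); b <- as_image(b, "b")
  same_shape(a, b, "a vs b")
  win <- 11L; sigma <- 1.5
  if (min(dim(a)) < win)
    stop("images must be at least ", win, " px on each side")
  g <- dnorm(seq(-(win %/% 2), win %/% 2), sd = sigma)
  k <- outer(g, g); k <- k / sum(k)
  kw <- array(k, dim = c(win, win, 1L, 1L))
  filt <- function(x) {
    y <- .conv2d_fwd(array(x, dim = c(dim(x), 1L, 1L)), kw, 0, 1L, 0L)
    matrix(y, dim(y)[1], dim(y)[2])
  }
  C1 <- 0.01^2; C2 <- 0.03^2
  mua <- filt(a); mub <- filt(b)
  va <- filt(a * a) - mua^2
  vb <- filt(b * b) - mub^2
  vab <- filt(a * b) - mua * mub
  num <- (2 * mua * mub + C1) * (2 * vab + C2)
  den <- (mua^2 + mub^2 + C1) * (va + vb + C2)
  mean(num / den)
}

#' Dice coefficient for one class of two label masks
#'
#' `2 |A intersect B| / (|A| + |B|)` over the pixels carrying
#' `class_label`; defined as 1 when the class is absent from both masks.
#'
#' @param a,b integer label masks of identical shape
#' @param class_label class to score
#' @return value in `[0, 1]`
#' @export
dice <- function(a, b, class_label) {
  same_shape(a, b, "a vs b")
  pa <- a == class_label
  pb <- b == class_label
  denom <- sum(pa) + sum(pb)
  if (denom == 0) return(1)
  2 * sum(pa & pb) / denom
}

#' Boundary pixels of one segmentation class
#'
#' Coordinates (0-based row, col) of class pixels having at least one
#' 4-neighbour of a different class; pixels on the image border count their
#' missing neighbours as different.
#'
#' @param mask integer label matrix
#' @param class_label class whose contour is extracted (must be present)
#' @return two-column matrix of (row, col) coordinates
#' @export
contour_points <- function(mask, class_label) {
  inside <- mask == class_label
  if (!any(inside)) stop("class ", class_label, " is not present in the mask")
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- inside
  core <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  idx <- which(inside & !core, arr.ind = TRUE)
  cbind(row = unname(idx[, 1]) - 1L, col = unname(idx[, 2]) - 1L)
}

#' Modified Hausdorff distance between two point sets
#'
#' Dubuisson-Jain variant: the maximum of the two directed mean
#' nearest-neighbour Euclidean distances.
#'
#' @param A,B two-column coordinate matrices (non-empty)
#' @return non-negative distance in pixels
#' @export
modified_hausdorff <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("point sets must be non-empty")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  max(mean(apply(d, 1, min)), mean(apply(d, 2, min)))
}

#' Relative improvement between two scores where smaller is better
#'
#' `(reference - improved) / improved`, reported in percent: the factor by
#' which the improved score undercuts the reference, relative to the
#' improved score.
#'
#' @param improved score of the better model (e.g. its FID)
#' @param reference score of the baseline model
#' @return improvement in percent
#' @export
relative_improvement <- function(improved, reference) {
  stopifnot_scalar_number(improved, "improved", positive = TRUE)
  stopifnot_scalar_number(reference, "reference", positive = TRUE)
  (reference - improved) / improved * 100
}
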