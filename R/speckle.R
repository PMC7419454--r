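## Speckle core: spectral-window speckle transform and its convolution oracle.
##
## A coherent imaging system with a square aperture maps an object I(x, y)
## carrying i.i.d. random phases phi(x, y) to
##
##     I_sp = | F^-1{ F{ I . e^{j phi} } . rect_d } |
##
## where rect_d is a d x d window centred on the DC bin of the spectrum.
## Smaller windows pass fewer spatial frequencies and therefore produce
## larger speckle grains.  The window is optionally softened with logistic
## edges so that d can receive gradients.

# centred frequency-offset vector for an axis of length n (DC at index
# floor(n/2) + 1, matching an fftshift-ed spectrum)
freq_offsets <- function(n) seq_len(n) - (floor(n / 2) + 1L)

# permutation taking a DC-centred layout to the FFT's native layout
ifftshift_index <- function(n) ((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L

#' Build a (soft) square spectral window
#'
#' Constructs the d-by-d window applied to the shifted spectrum.  With
#' `softness = 0` the window is the ideal 0/1 rectangle (1 exactly when both
#' centred frequency offsets have magnitude at most d/2).  With
#' `softness > 0` each axis profile is a logistic ramp
#' `plogis((d/2 - |u|) / softness)` and the mask is the outer product of the
#' two axis profiles, which makes it differentiable in `d`.
#'
#' @param d window edge length in frequency bins, `0 < d <= min(height, width)`
#' @param height,width spectrum dimensions
#' @param softness non-negative edge steepness; 0 gives the hard rectangle
#' @return an object of class `spectral_window` with elements `edge_length_d`,
#'   `softness`, `mask` (DC-centred), `mask_shifted` (native FFT layout) and
#'   `dmask_shifted` (derivative of the native-layout mask with respect to d;
#'   all-zero for the hard window)
#' @examples
#' w <- make_spectral_window(8, 32, 32, softness = 0)
#' sum(w$mask)  # 64 bins pass
#' @export
make_spectral_window <- function(d, height, width, softness = 0) {
  stopifnot_scalar_number(d, "d", positive = TRUE)
  stopifnot_scalar_number(softness, "softness")
  if (softness < 0) stop("`softness` must be non-negative")
  if (d > min(height, width))
    stop("window edge length d = ", d, " exceeds spectrum extent ",
         min(height, width))
  u <- freq_offsets(height)
  v <- freq_offsets(width)
  if (softness == 0) {
    pr <- as.numeric(abs(u) <= d / 2)
    pc <- as.numeric(abs(v) <= d / 2)
    dpr <- numeric(height)
    dpc <- numeric(width)
  } else {
    pr <- plogis((d / 2 - abs(u)) / softness)
    pc <- plogis((d / 2 - abs(v)) / softness)
    dpr <- dlogis((d / 2 - abs(u)) / softness) / (2 * softness)
    dpc <- dlogis((d / 2 - abs(v)) / softness) / (2 * softness)
  }
  mask <- outer(pr, pc)
  dmask <- outer(dpr, pc) + outer(pr, dpc)
  ir <- ifftshift_index(height)
  ic <- ifftshift_index(width)
  structure(list(edge_length_d = d, softness = softness, mask = mask,
                 mask_shifted = mask[ir, ic, drop = FALSE],
                 dmask_shifted = dmask[ir, ic, drop = FALSE]),
            class = "spectral_window")
}

#' Sample a uniform random phase field
#'
#' Fully developed speckle assumes i.i.d. phases uniform on `[0, 2*pi)`.
#' The global RNG state is preserved when a seed is given.
#'
#' @param height,width field dimensions
#' @param seed integer seed, or `NULL` to consume the current RNG stream
#' @return `height x width` matrix of phases in radians
#' @export
sample_phase_field <- function(height, width, seed = NULL) {
  if (height < 1 || width < 1) stop("dimensions must be positive")
  with_seed(seed, matrix(runif(height * width, 0, 2 * pi), height, width))
}

#' Apply the spectral-window speckle transform
#'
#' Computes `|F^-1{ F{ image . exp(j phases) } . window }|` with paired
#' forward/inverse FFTs (the inverse carries the 1/N factor; the magnitude
#' output is invariant to this pairing).  A full-spectrum hard window makes
#' the transform the identity on non-negative images.
#'
#' @param image real matrix
#' @param window a [make_spectral_window()] result of matching shape
#' @param phases phase matrix of matching shape (radians)
#' @return speckled magnitude image, same shape, non-negative
#' @export
apply_speckle <- function(image, window, phases) {
  image <- as_image(image)
  same_shape(image, window$mask_shifted, "image vs window")
  same_shape(image, phases, "image vs phases")
  a <- image * exp(1i * phases)
  z <- fft(fft(a) * window$mask_shifted, inverse = TRUE) / length(a)
  Mod(z)
}

#' Explicit-convolution oracle for the speckle transform
#'
#' The spectral filtering above is, by the convolution theorem, a circular
#' convolution of `image . exp(j phases)` with the inverse DFT of the window
#' (a discrete sinc kernel for the hard rectangle).  This reference path
#' evaluates that convolution by explicit summation with the kernel obtained
#' from explicit DFT matrices -- no FFT is involved -- and exists purely to
#' cross-check [apply_speckle()].  Cost is O(n^4), so inputs are capped.
#'
#' @inheritParams apply_speckle
#' @param max_side refuse images with a side longer than this (default 64)
#' @return speckled magnitude image
#' @export
speckle_conv_oracle <- function(image, window, phases, max_side = 64L) {
  image <- as_image(image)
  same_shape(image, window$mask_shifted, "image vs window")
  same_shape(image, phases, "image vs phases")
  H <- nrow(image); W <- ncol(image)
  if (max(H, W) > max_side)
    stop("oracle refused: image side exceeds the ", max_side, " px limit")
  # kernel = inverse DFT of the native-layout window, via explicit matrices
  er <- exp(2i * pi * outer(0:(H - 1), 0:(H - 1)) / H)
  ec <- exp(2i * pi * outer(0:(W - 1), 0:(W - 1)) / W)
  kernel <- (er %*% window$mask_shifted %*% t(ec)) / (H * W)
  a <- image * exp(1i * phases)
  out <- matrix(0i, H, W)
  for (p in 0:(H - 1)) {
    rows <- ((0:(H - 1) - p) %% H) + 1L
    for (q in 0:(W - 1)) {
      cols <- ((0:(W - 1) - q) %% W) + 1L
      out <- out + a[p + 1L, q + 1L] * kernel[rows, cols, drop = FALSE]
    }
  }
  Mod(out)
}

#' Analytic gradient of the mean speckled intensity with respect to d
#'
#' For a soft window (softness > 0) the transform is differentiable in the
#' window edge length.  Writing Z = F^-1{ W(d) . F{I e^{j phi}} }, the
#' derivative of `mean(|Z|)` is `mean(Re(conj(Z)/|Z| . F^-1{ dW/dd . FA }))`.
#' Used by the training code and validated against finite differences.
#'
#' @inheritParams apply_speckle
#' @param eps magnitude guard against division by zero
#' @return scalar gradient `d mean(apply_speckle) / d d`
#' @export
speckle_d_gradient <- function(image, window, phases, eps = 1e-12) {
  image <- as_image(image)
  same_shape(image, window$mask_shifted, "image vs window")
  same_shape(image, phases, "image vs phases")
  n <- length(image)
  fa <- fft(image * exp(1i * phases))
  z <- fft(fa * window$mask_shifted, inverse = TRUE) / n
  dz <- fft(fa * window$dmask_shifted, inverse = TRUE) / n
  mean(Re(Conj(z) / (Mod(z) + eps) * dz))
}

#' Estimate the mean speckle grain size of an image
#'
#' Returns the full width at half maximum (pixels) of the central peak of
#' the normalized spatial autocorrelation of the mean-subtracted image,
#' averaged over the row and column axes.  White noise gives roughly 1 px;
#' coarser texture gives larger values.  Smaller spectral windows (small d)
#' yield larger speckle grains, so this estimate decreases as d grows.
#'
#' @param image non-constant real matrix
#' @return estimated grain size in pixels
#' @export
estimate_speckle_size <- function(image) {
  image <- as_image(image)
  x <- image - mean(image)
  if (max(abs(x)) < 1e-12)
    stop("speckle size is undefined for a constant image")
  n <- length(x)
  ac <- Re(fft(Mod(fft(x))^2, inverse = TRUE)) / n
  ac <- ac / ac[1, 1]
  half_width <- function(profile) {
    # profile[1] is lag 0 (== 1); find the first 0.5 crossing
    below <- which(profile < 0.5)
    if (length(below) == 0) return(length(profile) - 1)
    k <- below[1]                       # first index below half max
    hi <- profile[k - 1]; lo <- profile[k]
    (k - 2) + (hi - 0.5) / (hi - lo)    # linear interpolation, in lags
  }
  H <- nrow(x); W <- ncol(x)
  fw_row <- half_width(ac[seq_len(floor(H / 2) + 1L), 1])
  fw_col <- half_width(ac[1, seq_len(floor(W / 2) + 1L)])
  fw_row + fw_col                        # 2 * mean half-width
}
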