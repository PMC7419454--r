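## Spatially-adaptive normalization (SPADE): batch normalization without an
## affine part, followed by a pixelwise affine modulation whose gamma/beta
## maps are produced from the (resized, one-hot) segmentation mask by a
## shared 3x3 convolution + ReLU and two head convolutions.

#' Create a SPADE normalization module
#'
#' @param C number of feature channels to normalize
#' @param mask_channels channels of the one-hot mask input (3 classes)
#' @param hidden output channels of the shared first convolution (64 by
#'   default, the value used throughout the generator)
#' @param k kernel size of all three convolutions
#' @return a SPADE module usable with [spade_normalize()]
#' @export
spade_params <- function(C, mask_channels = 3L, hidden = 64L, k = 3L) {
  m <- new_module("spade")
  m$bn <- nn_batchnorm(C, affine = FALSE)
  m$conv_shared <- nn_conv(mask_channels, hidden, k)
  m$relu <- nn_relu()
  # gamma head biased at 1 so the block starts close to plain standardization
  m$conv_gamma <- nn_conv(hidden, C, k, bias_init = 1)
  m$conv_beta <- nn_conv(hidden, C, k)
  m$children <- list(m$bn, m$conv_shared, m$conv_gamma, m$conv_beta)
  m$fwd <- function(x, mask_oh) {
    xhat <- m$bn$fwd(x)
    h <- m$relu$fwd(m$conv_shared$fwd(mask_oh))
    gamma <- m$conv_gamma$fwd(h)
    beta <- m$conv_beta$fwd(h)
    m$xhat <- xhat; m$gamma <- gamma
    gamma * xhat + beta
  }
  m$bwd <- function(gy) {
    gh <- m$conv_gamma$bwd(gy * m$xhat) + m$conv_beta$bwd(gy)
    m$conv_shared$bwd(m$relu$bwd(gh))   # mask input needs no gradient
    m$bn$bwd(gy * m$gamma)
  }
  m
}

#' Apply SPADE normalization to a feature batch
#'
#' Standardizes each channel with its batch statistics (mean and standard
#' deviation over sample, height and width; epsilon-guarded), then applies
#' `x_out = gamma * xhat + beta` where the `gamma`/`beta` maps are computed
#' from the mask by the module's convolutions.  The mask must already be
#' one-hot encoded and resized (nearest neighbour) to the feature map's
#' spatial size.
#'
#' @param features `(H, W, C, N)` feature tensor
#' @param mask_oh `(H, W, mask_channels, N)` one-hot mask tensor
#' @param params a [spade_params()] module
#' @return normalized feature tensor, same shape as `features`
#' @export
spade_normalize <- function(features, mask_oh, params) {
  d <- tdim(features)
  dm <- tdim(mask_oh)
  if (!identical(d[c(1, 2, 4)], dm[c(1, 2, 4)]))
    stop("mask and features disagree in spatial size or batch size")
  params$fwd(features, mask_oh)
}

#' One-hot encode a batch of label masks
#'
#' @param masks `(H, W, 1, N)` integer tensor or a single `H x W` matrix with
#'   labels in `{0, ..., n_classes - 1}`
#' @param n_classes number of classes (3 for lumen / intima-media /
#'   adventitia-background)
#' @return `(H, W, n_classes, N)` tensor of 0/1 indicators
#' @export
one_hot_mask <- function(masks, n_classes = 3L) {
  if (is.matrix(masks)) masks <- array(masks, dim = c(dim(masks), 1L, 1L))
  d <- tdim(masks)
  out <- array(0, dim = c(d[1], d[2], n_classes, d[4]))
  for (k in seq_len(n_classes))
    out[, , k, ] <- (masks[, , 1, ] == (k - 1L)) * 1
  out
}

# nearest-neighbour resize of a label mask matrix to h x w
resize_mask_nearest <- function(mask, h, w) {
  ri <- floor((seq_len(h) - 0.5) * nrow(mask) / h) + 1L
  ci <- floor((seq_len(w) - 0.5) * ncol(mask) / w) + 1L
  mask[ri, ci, drop = FALSE]
}
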