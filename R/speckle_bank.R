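## Multi-size speckle bank: adds speckle at S different window sizes to each
## of the n_in input feature maps (n_in * S output maps, 8 -> 32 with the
## defaults), weights the outputs with channel-attention coefficients, and
## optionally runs the speckle transform in the polar domain with a
## subsequent polar -> Cartesian warp (centric-view pipeline).  The window
## edge lengths d are learnable parameters of the layer.

#' Channel attention coefficients
#'
#' Global sum pooling over each input feature map followed by two linear
#' layers (ReLU between, sigmoid output, squeeze-excitation style) produces
#' one coefficient in (0, 1) per (input channel, speckle size) combination.
#'
#' @param features `(H, W, n_in, N)` feature tensor
#' @param params list with `w1` (`n_in x hidden`), `b1`, `w2`
#'   (`hidden x n_out`), `b2`
#' @return `N x n_out` matrix of coefficients in (0, 1)
#' @export
channel_attention <- function(features, params) {
  d <- tdim(features)
  if (d[3] != nrow(params$w1))
    stop("channel_attention expects ", nrow(params$w1),
         " input channels, got ", d[3])
  pooled <- t(matrix(colSums(matrix(features, d[1] * d[2], d[3] * d[4])),
                     d[3], d[4]))                     # N x n_in
  h <- pmax(sweep(pooled %*% params$w1, 2, params$b1, "+"), 0)
  plogis(sweep(h %*% params$w2, 2, params$b2, "+"))
}

#' Create a speckle bank layer
#'
#' @param n_in input feature channels (8 in the reference architecture)
#' @param d_init initial window edge lengths, one per speckle size; the
#'   default spreads the sizes evenly over 28--48 px
#' @param softness soft-window edge steepness (> 0 so d stays learnable)
#' @param att_hidden hidden width of the attention head
#' @param polar if `TRUE`, features are warped to a polar grid, speckled
#'   there, and warped back (speckle grains then curve around the centre)
#' @return speckle bank module; `n_out = n_in * length(d_init)`
#' @export
speckle_bank <- function(n_in = 8L, d_init = seq(28, 48, length.out = 4),
                         softness = 0.5, att_hidden = 8L, polar = FALSE) {
  S <- length(d_init)
  if (S < 1L) stop("need at least one window size")
  if (any(d_init <= 0)) stop("window sizes must be strictly positive")
  m <- new_module("speckle_bank")
  m$n_in <- as.integer(n_in); m$S <- as.integer(S)
  m$n_out <- m$n_in * m$S
  m$softness <- softness
  m$polar <- polar
  m$params$d <- as.numeric(d_init)
  m$l1 <- nn_linear(n_in, att_hidden, gain = 1)
  m$l2 <- nn_linear(att_hidden, m$n_out, gain = 1)
  m$relu <- nn_relu(); m$sig <- nn_sigmoid()
  m$children <- list(m$l1, m$l2)
  m$warp <- NULL

  ensure_warp <- function(H, W) {
    if (!m$polar) return(invisible(NULL))
    if (!is.null(m$warp) && identical(m$warp$hw, c(H, W))) return(invisible(NULL))
    spec <- default_polar_spec(H, W)
    co <- polar_sample_coords(spec)
    m$warp <- list(hw = c(H, W), spec = spec,
                   cp = bilinear_sample_matrix(co$rr, co$cc, H, W),
                   pc = polar_to_cartesian_matrix(spec, H, W))
    m$warp$cp_t <- Matrix::t(m$warp$cp)
    m$warp$pc_t <- Matrix::t(m$warp$pc)
    invisible(NULL)
  }

  m$fwd <- function(x, seed = NULL) {
    d <- tdim(x)
    if (d[3] != m$n_in)
      stop("speckle bank expects ", m$n_in, " channels, got ", d[3])
    H <- d[1]; W <- d[2]; N <- d[4]
    ensure_warp(H, W)
    maxd <- min(H, W)
    m$params$d <- pmin(pmax(m$params$d, 1), maxd)   # keep d in its domain
    windows <- lapply(m$params$d, make_spectral_window,
                      height = H, width = W, softness = m$softness)
    eiphi <- exp(1i * with_seed(seed,
      array(runif(H * W * m$n_out * N, 0, 2 * pi),
            dim = c(H, W, m$n_out, N))))
    pooled <- t(matrix(colSums(matrix(x, H * W, m$n_in * N)), m$n_in, N))
    coeff <- m$sig$fwd(m$l2$fwd(m$relu$fwd(m$l1$fwd(pooled))))
    Z <- array(0i, dim = c(H, W, m$n_out, N))
    FA <- array(0i, dim = c(H, W, m$n_out, N))
    mag <- array(0, dim = c(H, W, m$n_out, N))
    out <- array(0, dim = c(H, W, m$n_out, N))
    for (n in seq_len(N)) for (ci in seq_len(m$n_in)) {
      src <- x[, , ci, n]
      if (m$polar)
        src <- matrix(as.numeric(m$warp$cp %*% as.vector(src)), H, W)
      for (s in seq_len(m$S)) {
        k <- (ci - 1L) * m$S + s
        a <- src * eiphi[, , k, n]
        fa <- fft(a)
        z <- fft(fa * windows[[s]]$mask_shifted, inverse = TRUE) / (H * W)
        FA[, , k, n] <- fa
        Z[, , k, n] <- z
        mg <- Mod(z)
        mag[, , k, n] <- mg
        map <- if (m$polar)
          matrix(as.numeric(m$warp$pc %*% as.vector(mg)), H, W) else mg
        out[, , k, n] <- coeff[n, k] * map
      }
    }
    m$cache <- list(x = x, eiphi = eiphi, coeff = coeff, windows = windows,
                    Z = Z, FA = FA, mag = mag, dims = d)
    out
  }

  m$bwd <- function(gy) {
    cc <- m$cache
    d <- cc$dims; H <- d[1]; W <- d[2]; N <- d[4]
    gx <- array(0, dim = d)
    gcoeff <- matrix(0, N, m$n_out)
    gd <- numeric(m$S)
    for (n in seq_len(N)) for (ci in seq_len(m$n_in)) {
      gsrc <- matrix(0, H, W)
      for (s in seq_len(m$S)) {
        k <- (ci - 1L) * m$S + s
        mg <- cc$mag[, , k, n]
        map <- if (m$polar)
          matrix(as.numeric(m$warp$pc %*% as.vector(mg)), H, W) else mg
        g <- gy[, , k, n]
        gcoeff[n, k] <- sum(g * map)
        gmap <- cc$coeff[n, k] * g
        gmag <- if (m$polar)
          matrix(as.numeric(m$warp$pc_t %*% as.vector(gmap)), H, W) else gmap
        gbar <- gmag * cc$Z[, , k, n] / (mg + 1e-12)
        ga <- Conj(cc$eiphi[, , k, n]) *
          (fft(cc$windows[[s]]$mask_shifted * fft(gbar), inverse = TRUE) / (H * W))
        gsrc <- gsrc + Re(ga)
        dz <- fft(cc$windows[[s]]$dmask_shifted * cc$FA[, , k, n],
                  inverse = TRUE) / (H * W)
        gd[s] <- gd[s] + sum(Re(Conj(gbar) * dz))
      }
      gx[, , ci, n] <- if (m$polar)
        matrix(as.numeric(m$warp$cp_t %*% as.vector(gsrc)), H, W) else gsrc
    }
    accumulate_grad(m, "d", gd)
    # attention path
    gpooled <- m$l1$bwd(m$relu$bwd(m$l2$bwd(m$sig$bwd(gcoeff))))   # N x n_in
    for (ci in seq_len(m$n_in))
      gx[, , ci, ] <- gx[, , ci, ] + rep(gpooled[, ci], each = H * W)
    gx
  }
  m
}

# attention parameters of a bank, in the functional layout used by
# channel_attention()
bank_attention_params <- function(bank) {
  list(w1 = bank$l1$params$w, b1 = bank$l1$params$b,
       w2 = bank$l2$params$w, b2 = bank$l2$params$b)
}

#' Run a speckle bank forward pass
#'
#' Output channel `(c - 1) * S + s` equals the attention coefficient for
#' that (channel, size) pair times the speckle transform of input channel
#' `c` at window size `d[s]`, with phases drawn fresh per call unless a
#' seed fixes them.
#'
#' @param features `(H, W, n_in, N)` feature tensor
#' @param bank a [speckle_bank()] module
#' @param seed integer seed for the phase fields, or `NULL` for fresh phases
#' @return `(H, W, n_in * S, N)` tensor
#' @export
speckle_bank_forward <- function(features, bank, seed = NULL) {
  bank$fwd(features, seed = seed)
}
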